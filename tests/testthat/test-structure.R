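# Conformer generation, charge assignment, scaffold alignment.

test_that("embedding the same record twice gives identical coordinates", {
  rec <- list(id = "7h", smiles = fx_library()$smiles[fx_library()$id == "7h"])
  m1 <- embed_conformer(rec)
  m2 <- embed_conformer(rec)
  expect_identical(coords(m1), coords(m2))
})

test_that("embedded benzene ring is planar and methane has standard bonds", {
  benz <- fx_molecule("c1ccccc1", "benzene")
  ring <- coords(benz, heavy_only = TRUE)
  cen <- colMeans(ring)
  normal <- svd(sweep(ring, 2, cen))$v[, 3]
  dev <- abs(sweep(ring, 2, cen) %*% normal)
  expect_lt(max(dev), 0.05)

  meth <- fx_molecule("C", "methane")
  xyz <- coords(meth)
  c_idx <- which(meth$atoms$element == "C")
  h_idx <- which(meth$atoms$element == "H")
  d <- sqrt(rowSums(sweep(xyz[h_idx, , drop = FALSE], 2, xyz[c_idx, ])^2))
  expect_true(all(abs(d - 1.09) < 0.05))
})

test_that("Gasteiger charges conserve charge and respect symmetry", {
  purine <- fx_molecule(fx_library()$smiles[fx_library()$id == "7h"], "7h")
  expect_lt(abs(sum(purine$atoms$charge)), 1e-3)
  expect_equal(purine$net_charge, 0L)

  benz <- fx_molecule("c1ccccc1", "benzene")
  qc <- benz$atoms$charge[benz$atoms$element == "C"]
  expect_lt(diff(range(qc)), 1e-6)

  nitro <- fx_molecule("C[N+](=O)[O-]", "nitromethane")
  # nitrogen of the nitro group carries positive partial charge
  qn <- nitro$atoms$charge[nitro$atoms$element == "N"]
  expect_gt(qn, 0)
})

test_that("charges are attached without moving the conformer", {
  rec <- list(id = "4a", smiles = fx_library()$smiles[fx_library()$id == "4a"])
  bare <- embed_conformer(rec)
  charged <- assign_charges(bare)
  expect_identical(coords(bare), coords(charged))
  expect_gt(stats::sd(charged$atoms$charge), 0)
})

test_that("alignment is exact for the template and rigid copies of it", {
  m <- fx_molecule(fx_library()$smiles[fx_library()$id == "7h"], "7h")
  self <- align_to_scaffold(list(m))
  expect_lt(self$rmsd[[1]], 1e-9)

  moved <- rigid_transform(m)
  moved$id <- "7h-moved"
  al <- align_to_scaffold(list(m, moved))
  expect_lt(al$rmsd[["7h-moved"]], 1e-6)
  expect_equal(coords(al$molecules[["7h-moved"]]), coords(m),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("alignment result is invariant to rigid pre-transformations", {
  lib <- fx_library()
  a <- fx_molecule(lib$smiles[lib$id == "7h"], "7h")
  b <- fx_molecule(lib$smiles[lib$id == "7e"], "7e")
  al1 <- align_to_scaffold(list(a, b))
  b2 <- rigid_transform(b, angle = 1.2, axis = c(1, 2, 0), shift = c(-5, 1, 9))
  al2 <- align_to_scaffold(list(a, b2))
  expect_equal(al1$rmsd[["7e"]], al2$rmsd[["7e"]], tolerance = 1e-6)
  expect_equal(coords(al1$molecules[["7e"]]), coords(al2$molecules[["7e"]]),
               tolerance = 1e-5)
})

test_that("all 31 purines align onto the purine core below 0.5 A RMSD", {
  run <- fx_run("HL-60") # 20 molecules, prepared once for the whole suite
  expect_true(all(run$aligned$rmsd < 0.5))
  expect_named(run$aligned$mappings[[1]],
               c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"))
})

test_that("molecules without the scaffold are reported by id", {
  eth <- fx_molecule("CCO", "ethanol")
  expect_error(align_to_scaffold(list(eth)), "ethanol")
})

test_that("substituent centroids sit on the correct side of the core", {
  run <- fx_run("HL-60")
  al <- run$aligned
  id <- al$template_id
  c2 <- substituent_centroid(al, id, "C2")
  n9 <- substituent_centroid(al, id, "N9")
  c6 <- substituent_centroid(al, id, "C6")
  core_c2 <- coords(al$molecules[[id]])[al$mappings[[id]][["C2"]], ]
  core_n9 <- coords(al$molecules[[id]])[al$mappings[[id]][["N9"]], ]
  # each substituent centroid is nearer its own attachment atom
  expect_lt(sum((c2 - core_c2)^2), sum((c2 - core_n9)^2))
  expect_lt(sum((n9 - core_n9)^2), sum((n9 - core_c2)^2))
  expect_false(isTRUE(all.equal(c6, c2)))
})
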