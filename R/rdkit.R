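# Seeded 3D embedding through RDKit (system Python). ETKDG distance
# geometry with an explicit random seed is the only embedding route in the
# toolchain that is reproducible bit-for-bit across processes; Open Babel's
# rotor search is time-seeded and therefore not.

.python_path <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no 'python' on PATH (needed for 3D embedding)")
  p
}

.rdkit_script <- '
import sys
from rdkit import Chem
from rdkit.Chem import AllChem
smi, seed = sys.stdin.read().rsplit("\\t", 1)
m = Chem.MolFromSmiles(smi.strip())
if m is None:
    sys.exit(3)
m = Chem.AddHs(m)
ps = AllChem.ETKDGv3()
ps.randomSeed = int(seed)
if AllChem.EmbedMolecule(m, ps) != 0:
    ps.useRandomCoords = True
    if AllChem.EmbedMolecule(m, ps) != 0:
        sys.exit(4)
AllChem.MMFFOptimizeMolecule(m, maxIters=2000)
conf = m.GetConformer()
for a in m.GetAtoms():
    p = conf.GetAtomPosition(a.GetIdx())
    print("A\\t%s\\t%.6f\\t%.6f\\t%.6f\\t%d" %
          (a.GetSymbol(), p.x, p.y, p.z, a.GetFormalCharge()))
for b in m.GetBonds():
    print("B\\t%d\\t%d\\t%g" % (b.GetBeginAtomIdx() + 1,
                                b.GetEndAtomIdx() + 1,
                                b.GetBondTypeAsDouble()))
'

.rdkit_embed <- function(smiles, seed) {
  out <- suppressWarnings(system2(
    .python_path(), c("-c", shQuote(.rdkit_script)),
    stdout = TRUE, stderr = FALSE,
    input = paste0(smiles, "\t", as.integer(seed))
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(if (identical(status, 3L)) "unparsable SMILES" else "embedding failed")
  }
  f <- strsplit(out, "\t", fixed = TRUE)
  arec <- f[vapply(f, `[[`, "", 1) == "A"]
  brec <- f[vapply(f, `[[`, "", 1) == "B"]
  if (!length(arec)) stop("no atoms returned")
  atoms <- data.frame(
    element = vapply(arec, `[[`, "", 2),
    x = as.numeric(vapply(arec, `[[`, "", 3)),
    y = as.numeric(vapply(arec, `[[`, "", 4)),
    z = as.numeric(vapply(arec, `[[`, "", 5)),
    charge = 0,
    fcharge = as.integer(vapply(arec, `[[`, "", 6)),
    stringsAsFactors = FALSE
  )
  order <- vapply(brec, `[[`, "", 4)
  bonds <- data.frame(
    from = as.integer(vapply(brec, `[[`, "", 2)),
    to = as.integer(vapply(brec, `[[`, "", 3)),
    order = ifelse(order == "1.5", "ar", order),
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, bonds = bonds)
}
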