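id,smiles,series,formula,name
4a,CCn1cnc2c1nc(NC3CCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C19H20F3N5O,N-cyclopentyl-9-ethyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4b,CCn1cnc2c1nc(NC3CCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C20H22F3N5O,N-cyclohexyl-9-ethyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4c,CCn1cnc2c1nc(NCC3CCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C21H24F3N5O,N-(cyclohexylmethyl)-9-ethyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4d,CCn1cnc2c1nc(NC3CCCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C21H24F3N5O,N-cycloheptyl-9-ethyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4e,CCCn1cnc2c1nc(NC3CCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C20H22F3N5O,N-cyclopentyl-9-propyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4f,CCCn1cnc2c1nc(NC3CCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C21H24F3N5O,N-cyclohexyl-9-propyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4g,CCCn1cnc2c1nc(NCC3CCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C22H26F3N5O,N-(cyclohexylmethyl)-9-propyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4h,CCCn1cnc2c1nc(NC3CCCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C22H26F3N5O,N-cycloheptyl-9-propyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4i,CCCCn1cnc2c1nc(NC3CCCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C23H28F3N5O,9-butyl-N-cycloheptyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4j,CCCCCn1cnc2c1nc(NC3CCCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C24H30F3N5O,N-cycloheptyl-9-pentyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4k,CCCCCCn1cnc2c1nc(NC3CCCCCC3)nc2-c1ccc(OC(F)(F)F)cc1,I,C25H32F3N5O,N-cycloheptyl-9-hexyl-6-(4-(trifluoromethoxy)phenyl)-9H-purin-2-amine
4l,CCCCCCn1cnc2c1nc(N3CCN(CC3)c3ccc([N+](=O)[O-])cn3)nc2-c1ccc(OC(F)(F)F)cc1,II,C27H29F3N8O3,9-hexyl-2-(4-(5-nitropyridin-2-yl)piperazin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4m,CCCCCCn1cnc2c1nc(N3CCN(CC3)c3ccccn3)nc2-c1ccc(OC(F)(F)F)cc1,II,C27H30F3N7O,9-hexyl-2-(4-(pyridin-2-yl)piperazin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4n,CCCCCCn1cnc2c1nc(N3CCN(CC3)c3ccc(C(F)(F)F)cn3)nc2-c1ccc(OC(F)(F)F)cc1,II,C28H29F6N7O,9-hexyl-2-(4-(5-(trifluoromethyl)pyridin-2-yl)piperazin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4o,CCCCCCn1cnc2c1nc(N3CCN(CC3)c3cnccn3)nc2-c1ccc(OC(F)(F)F)cc1,II,C26H29F3N8O,9-hexyl-2-(4-(pyrazin-2-yl)piperazin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4p,CCCCCCn1cnc2c1nc(N3CCC(CC3)c3ccccc3)nc2-c1ccc(OC(F)(F)F)cc1,II,C29H32F3N5O,9-hexyl-2-(4-phenylpiperidin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4q,CCCCCn1cnc2c1nc(N3CCN(CC3)c3ccc([N+](=O)[O-])cn3)nc2-c1ccc(OC(F)(F)F)cc1,II,C26H27F3N8O3,9-pentyl-2-(4-(5-nitropyridin-2-yl)piperazin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4r,CCCCCn1cnc2c1nc(N3CCN(CC3)c3ccccn3)nc2-c1ccc(OC(F)(F)F)cc1,II,C26H28F3N7O,9-pentyl-2-(4-(pyridin-2-yl)piperazin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4s,CCCCCn1cnc2c1nc(N3CCN(CC3)c3ccc(C(F)(F)F)cn3)nc2-c1ccc(OC(F)(F)F)cc1,II,C27H27F6N7O,9-pentyl-2-(4-(5-(trifluoromethyl)pyridin-2-yl)piperazin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4t,CCCCCn1cnc2c1nc(N3CCC(CC3)c3ccccc3)nc2-c1ccc(OC(F)(F)F)cc1,II,C28H30F3N5O,9-pentyl-2-(4-phenylpiperidin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
4u,CCCCCn1cnc2c1nc(N3CCN(CC3)c3cnccn3)nc2-c1ccc(OC(F)(F)F)cc1,II,C25H27F3N8O,9-pentyl-2-(4-(pyrazin-2-yl)piperazin-1-yl)-6-(4-(trifluoromethoxy)phenyl)-9H-purine
7a,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3ccc([N+](=O)[O-])cn3,III,C19H21ClN8O2,2-chloro-9-cyclopentyl-6-(4-(5-nitropyridin-2-yl)piperazin-1-yl)-9H-purine
7b,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3ccccn3,III,C19H22ClN7,2-chloro-9-cyclopentyl-6-(4-(pyridin-2-yl)piperazin-1-yl)-9H-purine
7c,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3ccc(C(F)(F)F)cn3,III,C20H21ClF3N7,2-chloro-9-cyclopentyl-6-(4-(5-(trifluoromethyl)pyridin-2-yl)piperazin-1-yl)-9H-purine
7d,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3cnccn3,III,C18H21ClN8,2-chloro-9-cyclopentyl-6-(4-(pyrazin-2-yl)piperazin-1-yl)-9H-purine
7e,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCC(CC3)c3ccccc3,III,C21H24ClN5,2-chloro-9-cyclopentyl-6-(4-phenylpiperidin-1-yl)-9H-purine
7f,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3ccccc3,III,C20H23ClN6,2-chloro-9-cyclopentyl-6-(4-phenylpiperazin-1-yl)-9H-purine
7g,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3ccc(Cl)cc3,III,C20H22Cl2N6,2-chloro-6-(4-(4-chlorophenyl)piperazin-1-yl)-9-cyclopentyl-9H-purine
7h,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3ccc([N+](=O)[O-])cc3,III,C20H22ClN7O2,2-chloro-9-cyclopentyl-6-(4-(4-nitrophenyl)piperazin-1-yl)-9H-purine
7i,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3ccncc3,III,C19H22ClN7,2-chloro-9-cyclopentyl-6-(4-(pyridin-4-yl)piperazin-1-yl)-9H-purine
7j,C3CCC(C3)n1cnc2c1nc(Cl)nc2N3CCN(CC3)c3ccc(OC)cc3,III,C21H25ClN6O,2-chloro-9-cyclopentyl-6-(4-(4-methoxyphenyl)piperazin-1-yl)-9H-purine
2a,CCn1cnc2c1nc(F)nc2Cl,intermediate,C7H6ClFN4,6-chloro-9-ethyl-2-fluoro-9H-purine
2b,CCCn1cnc2c1nc(F)nc2Cl,intermediate,C8H8ClFN4,6-chloro-2-fluoro-9-propyl-9H-purine
2c,CCCCn1cnc2c1nc(F)nc2Cl,intermediate,C9H10ClFN4,9-butyl-6-chloro-2-fluoro-9H-purine
2d,CCCCCn1cnc2c1nc(F)nc2Cl,intermediate,C10H12ClFN4,6-chloro-2-fluoro-9-pentyl-9H-purine
2e,CCCCCCn1cnc2c1nc(F)nc2Cl,intermediate,C11H14ClFN4,6-chloro-2-fluoro-9-hexyl-9H-purine
6a,C3CCC(C3)n1cnc2c1nc(Cl)nc2Cl,intermediate,C10H10Cl2N4,"2,6-dichloro-9-cyclopentyl-9H-purine"
3a,CCn1cnc2c1nc(F)nc2-c1ccc(OC(F)(F)F)cc1,intermediate,C14H10F4N4O,9-ethyl-2-fluoro-6-(4-(trifluoromethoxy)phenyl)-9H-purine
3b,CCCn1cnc2c1nc(F)nc2-c1ccc(OC(F)(F)F)cc1,intermediate,C15H12F4N4O,2-fluoro-9-propyl-6-(4-(trifluoromethoxy)phenyl)-9H-purine
3c,CCCCn1cnc2c1nc(F)nc2-c1ccc(OC(F)(F)F)cc1,intermediate,C16H14F4N4O,9-butyl-2-fluoro-6-(4-(trifluoromethoxy)phenyl)-9H-purine
3d,CCCCCn1cnc2c1nc(F)nc2-c1ccc(OC(F)(F)F)cc1,intermediate,C17H16F4N4O,2-fluoro-9-pentyl-6-(4-(trifluoromethoxy)phenyl)-9H-purine
3e,CCCCCCn1cnc2c1nc(F)nc2-c1ccc(OC(F)(F)F)cc1,intermediate,C18H18F4N4O,2-fluoro-9-hexyl-6-(4-(trifluoromethoxy)phenyl)-9H-purine
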