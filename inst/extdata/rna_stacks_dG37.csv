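# Turner-style nearest-neighbor stack free energies, Delta-G at 37 C (kcal/mol).
# A stack is the motif 5'XY3' / 3'WZ5' with base pairs (X.W) and (Y.Z);
# pair1 = X.W, pair2 = Y.Z. Only one representative per symmetry class is
# listed; the full 6x6 table is completed via E[p1][p2] = E[rev(p2)][rev(p1)].
# Watson-Crick entries are the published Xia/Turner 37 C values; G.U entries
# are a simplified Turner-style wobble set (see package documentation).
pair1,pair2,dG
AU,AU,-0.93
AU,UA,-1.10
UA,AU,-1.33
CG,UA,-2.08
CG,AU,-2.11
GC,UA,-2.24
GC,AU,-2.35
CG,GC,-2.36
GC,GC,-3.26
GC,CG,-3.42
AU,GU,-0.55
AU,UG,-1.36
UA,GU,-1.27
UA,UG,-1.00
CG,GU,-1.41
CG,UG,-2.11
GC,GU,-1.53
GC,UG,-2.51
GU,GU,-0.50
GU,UG,1.29
UG,GU,-0.30
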