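# GLYCAM-style nonbonded parameters for cellulose (anhydroglucose) atoms.
#
# charge : partial charge, units of the elementary charge e.  The charges of
#          the non-neutral atoms of a central glucose unit are the published
#          cellulose charge set; aliphatic hydrogens and all atoms not in
#          that set carry charge 0, so a central glucose unit is exactly
#          neutral.  Terminal-cap values (O1, HO1, HO4) are standard
#          carbohydrate hydroxyl values; chain termini are re-neutralized in
#          code before any energy calculation.
# radius : vdW radius R_i in Angstrom.  R_min of a pair is (R_i + R_j)/2,
#          so R_i is the pair-minimum distance of a homoatomic pair
#          (3.442 A for the hydroxyl oxygens O2/O3/O6, 3.3674 A for the
#          ring/glycosidic oxygens).
# eps    : Lennard-Jones well depth in kcal/mol (geometric-mean combination).
#          Radii and well depths are externally sourced GLYCAM06 atom-type
#          values (Oh, Os, Cg, H1, Ho); hydroxyl hydrogens have eps = 0 and
#          a nominal radius (they contribute no vdW interaction).
#
# name   charge   radius   eps
C1      0.384    3.8160   0.1094
C2      0.310    3.8160   0.1094
C3      0.284    3.8160   0.1094
C4      0.276    3.8160   0.1094
C5      0.225    3.8160   0.1094
C6      0.282    3.8160   0.1094
O2     -0.718    3.4420   0.2104
O3     -0.709    3.4420   0.2104
O5     -0.471    3.3674   0.1700
O6     -0.688    3.4420   0.2104
O4     -0.468    3.3674   0.1700
HO2     0.437    1.0000   0.0000
HO3     0.432    1.0000   0.0000
HO6     0.424    1.0000   0.0000
H1      0.000    2.7740   0.0157
H2      0.000    2.7740   0.0157
H3      0.000    2.7740   0.0157
H4      0.000    2.7740   0.0157
H5      0.000    2.7740   0.0157
H61     0.000    2.7740   0.0157
H62     0.000    2.7740   0.0157
O1     -0.639    3.4420   0.2104
HO1     0.445    1.0000   0.0000
HO4     0.445    1.0000   0.0000
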