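CCO ethanol
c1ccccc1 benzene
Oc1ccccc1 phenol
CC(=O)Oc1ccccc1C(=O)O aspirin
CN1C=NC2=C1C(=O)N(C)C(=O)N2C caffeine
CC(C)(c1ccc(O)cc1)c1ccc(O)cc1 bisphenol_a
C1=CC(=CC=C1C2=COC3=CC(=CC(=C3C2=O)O)O)O genistein
CC/C(=C(\CC)c1ccc(O)cc1)c1ccc(O)cc1 diethylstilbestrol
CC(=O)[O-].[Na+] sodium_acetate
Cl.NCCc1ccccc1 phenethylamine_hcl
C[C@H](N)C(=O)O l_alanine
C[C@@H](N)C(=O)O d_alanine
C/C=C/C trans_2_butene
C/C=C\C cis_2_butene
C[N+](=O)[O-] nitromethane_charged
CN(=O)=O nitromethane_neutral
O=S(=O)(O)O sulfuric_acid
[Na+].[Cl-] sodium_chloride
CC[Sn](CC)CC tetraethyltin
C[Al](C)C trimethylaluminum
CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC octacontane
C[Si](C)(C)O trimethylsilanol
C=C(O)C propen2ol
CC(=O)C acetone
C[N+](C)(C)CCO.[Cl-] choline_chloride
[O-]C(=O)c1ccccc1 benzoate
OC(=O)c1ccccc1 benzoic_acid
Cc1ccccc1 toluene
c1ccc2ccccc2c1 naphthalene
c1ccncc1 pyridine
CCNc1nc(Cl)nc(NC(C)C)n1 atrazine
Clc1ccc(cc1)C(c1ccc(Cl)cc1)C(Cl)(Cl)Cl ddt
COc1ccc(cc1)C(c1ccc(OC)cc1)C(Cl)(Cl)Cl methoxychlor
CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-] parathion
CC1(OC(=O)N(C1=O)c1cc(Cl)cc(Cl)c1)C=C vinclozolin
CCCCCCCCCc1ccc(O)cc1 nonylphenol
CCCCCCCCc1ccc(O)cc1 octylphenol
CCCCOC(=O)c1ccc(O)cc1 butylparaben
CCOC(=O)c1ccc(O)cc1 ethylparaben
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
CN1CCC[C@H]1c1cccnc1 nicotine
CN1CCCC1c1cccnc1 nicotine_flat
CN=N=N methyl_azide_neutral
CN=[N+]=[N-] methyl_azide_charged
Br.CCN ethylamine_hbr
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O glucose
CN1C=NC2=C1C(=O)N(C)C(=O)N2C caffeine_dup
O=C1CC[C@@H]2[C@H]3CCc4cc(O)ccc4[C@H]3CC[C@]12C estrone
CC/C(=C(\c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1 tamoxifen
C=Cc1ccccc1 styrene
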