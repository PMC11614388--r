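# Reference two-group summary from a published targeted metabolomics screen
# of cerebrospinal fluid: mice fed 3 days of high-fat diet (HFD_3d) vs
# control diet (CT), n = 10 per group. Columns: printed fold change
# (HFD_3d over CT) and printed two-sided p-value (Student's t). The
# glutarylcarnitine p-value is reconstructed from its printed -log10(p) of
# 2.40 because the p column itself printed as 0.00.
metabolite,fc,p_value
Kynurenic acid,3.56,0.24
Hexadecanoic acid,2.27,0.01
Nicotinamide-N-oxide,0.45,0.02
Octadecanoic acid,2.17,0.02
Serotonin,0.51,0.95
N-Methyl-4-pyridone-3-carboxamide,1.81,0.06
Methylmalonate,1.80,0.01
Tetradecanoic acid,1.78,0.29
Octanoylcarnitine,0.60,0.99
Propionylcarnitine,1.65,0.45
Isovalerylcarnitine,1.65,0.02
Nicotinic acid,1.60,0.04
Glutarylcarnitine,1.60,0.004
Nicotinamide,0.63,0.07
1-Methylnicotinamide,0.66,0.31
Ophthalmic acid,0.68,0.24
N-Methylserotonin,1.41,0.17
O-Acetylcarnitine,1.38,0.62
Tryptophan,1.35,0.10
3-Hydroxyanthranillic acid,1.34,0.20
Butyrylcarnitine,1.33,0.28
Nudifloramide,1.27,0.04
Quinolinic acid,1.21,0.22
S-Adenosyl-L-homocysteine,0.84,0.44
Isobutyrylcarnitine,1.15,0.62
2-Methylbutyrylcarnitine,1.15,0.64
Nicotinic acid mononucleotide,0.90,0.33
Hexanoylcarnitine,1.10,0.69
Nicotinamide mononucleotide,1.10,0.95
Carnitine,1.06,0.88
S-Adenosyl-L-methionine,1.06,0.61
3-Hydroxykynurenine,1.04,0.87
Nicotinuric acid,0.96,0.64
Anthranillic acid,1.04,0.96
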