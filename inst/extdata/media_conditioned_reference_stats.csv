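# Reference per-group summary statistics (mean, SD; n = 6 per group) from a
# published conditioned-media metabolomics screen: media from BSA-treated
# (control) vs palmitate-treated (PA) primary glial cultures. The ten
# most-significant rows by printed Wilcoxon rank-sum p-value.
metabolite,n_bsa,mean_bsa,sd_bsa,n_pa,mean_pa,sd_pa,p_printed
DL-Lactic acid,6,7315358105.8,237880097.3,6,8220829758.2,398345524.3,0.002
D-Glutamine,6,99910567.8,6363882.4,6,85119189.7,5084875.9,0.002
Acetyl-L-carnitine,6,25486005.2,4313399.0,6,17582727.8,1401821.0,0.004
L-Serine,6,10439581.3,1620380.1,6,7416283.5,827833.2,0.009
4-Oxoproline,6,6584223.3,1496000.9,6,3733172.0,1589279.7,0.026
3-Hydroxy-2-methyl-4-pyrone,6,122558080.8,13194171.3,6,102091630.2,19173036.1,0.065
Adipic acid,6,0.0,0.0,6,927108.7,1359286.8,0.074
D-Pyroglutamic acid,6,302927531.8,25661286.0,6,272228383.5,32600385.7,0.093
L-Arabinose,6,437653974.3,18029045.8,6,418339243.5,15611025.3,0.093
L-Tyrosine,6,345898.5,293093.1,6,171511968.0,418627435.0,0.13
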