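probe_id	chr	pos	delta_meth	p_value	gene	feature	direction
cg02068164	chr5	33439794	-0.059	1.01e-01	TARS	TSS	Hypomethylation
cg20088245	chr8	1321375	-0.087	2.77e-02	DLGAP2	TSS	Hypomethylation
cg08735705	chr7	1003645	0.038	2.54e-01	ADAP1	Enhancer	Hypermethylation
cg22243260	chr3	126946036	-0.069	2.93e-02	NA	NA	Hypomethylation
cg10279314	chr6	27185896	0.069	1.61e-02	PRSS16	Intron	Hypermethylation
cg25210835	chr1	110254828	-0.060	1.35e-01	GSTM5	Promoter	Hypomethylation
cg17422692	chr16	420245	0.079	2.23e-02	MRPL28	Promoter	Hypermethylation
cg03128011	chr8	1321333	-0.077	3.38e-02	DLGAP2	Promoter	Hypomethylation
cg05571310	chr17	72350354	-0.077	1.03e-02	KIF19	Intron	Hypomethylation
cg20540428	chr3	73045686	-0.064	4.53e-02	PPP4R2	Promoter	Hypomethylation
cg15247329	chr7	2764246	0.035	2.38e-01	GNA12;AMZ1	Intron	Hypermethylation
cg02613380	chr10	99330076	0.075	4.14e-02	UBTD1	Promoter	Hypermethylation
cg09419670	chr9	123605666	-0.097	9.50e-04	PSMD5	Intron	Hypomethylation
cg20561509	chr13	49427965	0.058	9.06e-02	FNDC3A	Promoter	Hypermethylation
cg27572370	chr10	14002394	-0.073	3.25e-02	FRMD4A	Intron	Hypomethylation
cg09978860	chr4	56023921	-0.053	7.98e-02	KDR	Intron	Hypomethylation
cg00274965	chr21	34405681	0.105	1.90e-02	OLIG1	Intron	Hypermethylation
cg11939300	chr2	132584904	0.066	5.58e-02	CCDC74A	Intron	Hypermethylation
cg14178589	chr6	168726836	0.102	5.94e-03	NA	NA	Hypermethylation
cg11480278	chr17	83580	0.108	4.56e-04	RPH3AL	Unknown	Hypermethylation
cg09817162	chr6	27185676	0.121	1.44e-03	PRSS16	Enhancer	Hypermethylation
cg11553311	chr5	66541588	-0.083	7.08e-03	CD180;MAST4	Unknown	Hypomethylation
cg21048050	chr15	51912957	0.156	7.52e-05	DMXL2	Promoter	Hypermethylation
cg13831575	chr15	48834416	0.105	9.33e-04	FBN1	Promoter	Hypermethylation
cg11744538	chr17	42646995	0.089	4.27e-02	NA	NA	Hypermethylation
cg02408697	chr10	1416920	0.089	6.05e-03	ADARB2	Intron	Hypermethylation
cg16113156	chr18	76266265	-0.075	2.01e-02	SALL3	Unknown	Hypomethylation
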