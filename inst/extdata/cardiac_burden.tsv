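# Rare-variant burden table for inherited cardiac condition genes.
# Burdens are proportions (0-1) of individuals carrying a rare
# (allele frequency < 0.0005) variant of the stated class group.
# Sources: prospective diagnostic case series (five LQTS genes) and
# literature yields of diagnostic testing; controls from population
# exome sequencing. For the eight literature-only LQTS genes the
# per-class case burdens are RECONSTRUCTED (synthetic) to be consistent
# with the published control burdens and prior odds (0.92 for KCNJ2
# non-radical, 4 for CAV3 non-radical, 0.2 elsewhere); control burdens
# for those genes are as published. HCM and BrS rows carry a single
# combined literature case burden; the control burden is fixed at 0.01
# by policy and left empty here.
gene	syndrome	class_group	case_burden	control_burden	source
KCNQ1	LQTS	non_radical	0.1784	0.0039	case_series
KCNQ1	LQTS	radical	0.0384	0.0002	case_series
KCNH2	LQTS	non_radical	0.1256	0.0048	case_series
KCNH2	LQTS	radical	0.0392	0	case_series
SCN5A	LQTS	non_radical	0.0584	0.0112	case_series
SCN5A	LQTS	radical	0.0028	0.0002	case_series
KCNE1	LQTS	non_radical	0.0124	0.0014	case_series
KCNE1	LQTS	radical	0.0020	0	case_series
KCNE2	LQTS	non_radical	0.0052	0.0011	case_series
KCNE2	LQTS	radical	0.0004	0.0002	case_series
ANK2	LQTS	non_radical	0.0386	0.0386	literature
ANK2	LQTS	radical	0.0002	0	literature
KCNJ2	LQTS	non_radical	0.0074	0.0026	literature
KCNJ2	LQTS	radical	0.0002	0	literature
CACNA1C	LQTS	non_radical	0.0112	0.0112	literature
CACNA1C	LQTS	radical	0.0002	0	literature
CAV3	LQTS	non_radical	0.0099	0.0011	literature
CAV3	LQTS	radical	0.0002	0.0002	literature
SCN4B	LQTS	non_radical	0.0017	0.0017	literature
SCN4B	LQTS	radical	0.0006	0.0006	literature
AKAP9	LQTS	non_radical	0.0393	0.0393	literature
AKAP9	LQTS	radical	0.0005	0.0005	literature
SNTA1	LQTS	non_radical	0.0043	0.0043	literature
SNTA1	LQTS	radical	0.0003	0.0003	literature
KCNJ5	LQTS	non_radical	0.0045	0.0045	literature
KCNJ5	LQTS	radical	0.0002	0	literature
MYBPC3	HCM	non_radical	0.375		literature
MYH7	HCM	non_radical	0.250		literature
TNNT2	HCM	non_radical	0.060		literature
TNNI3	HCM	non_radical	0.060		literature
SCN5A	BrS	non_radical	0.300		literature
CACNA1C	BrS	non_radical	0.010		literature
CACNA2D1	BrS	non_radical	0.010		literature
CACNB2	BrS	non_radical	0.010		literature
GPD1L	BrS	non_radical	0.010		literature
KCND3	BrS	non_radical	0.010		literature
KCNE3	BrS	non_radical	0.010		literature
SCN1B	BrS	non_radical	0.010		literature
SCN3B	BrS	non_radical	0.010		literature
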