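Hugo_Symbol	Chromosome	Start_Position	Reference_Allele	Tumor_Seq_Allele2	Variant_Classification	HGVSc	HGVSp	Codon	t_alt_count	VAF	Tumor_Sample_Barcode	Timepoint	FATHMM	CLINVAR_CLASS	POP_AF	IN_PON
NFE2L2	chr2	100137	A	T	missense	c.(181-183)Gat>Cat	p.D77H	77	20	12.1	case001	diagnosis	0.995	likely_oncogenic	NA	FALSE
NFE2L2	chr2	100274	A	T	inframe_ins	c.52_53ins	p.S18ins	18	20	2.1	case002	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	100411	A	T	missense	c.832C>G	p.P278A	278	20	5.5	case003	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	100548	A	T	missense	c.425C>T	p.S142F	142	20	5.5	case003	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	100685	A	T	missense	c.1826_1827CC>AA	p.T609K	609	20	10.5	case004	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	100822	A	T	missense	c.967_968AA>GC	p.K323A	323	20	3	case005	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	100959	A	T	missense	c.967_968AA>GC	p.F190S	190	20	2.9	case006	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	101096	A	T	missense	c.1438G>T	p.G480W	480	20	7.6	case007	diagnosis	0.995	likely_oncogenic	NA	FALSE
CUL3	chr2	101233	A	T	nonsense	c.2251A>T	p.R751*	751	20	1.9	case008	diagnosis	0.995	likely_oncogenic	NA	FALSE
NFE2L2	chr2	101370	A	T	missense	c.22T>C	p.W24R	24	20	7.7	case009	diagnosis	0.995	likely_oncogenic	NA	FALSE
NFE2L2	chr2	101507	A	T	missense	c.181G>C	p.D77H	77	20	5.4	case010	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	101644	A	T	missense	c.439A>G	p.M147V	147	20	NA	case011	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	101781	A	T	nonsense	c.646A>T	p.K216*	216	20	2.1	case012	diagnosis	0.995	likely_oncogenic	NA	FALSE
KEAP1	chr19	101918	A	T	frameshift	c.1237delC	p.R413fs	413	20	30	case013	diagnosis	0.995	likely_oncogenic	NA	FALSE
NFE2L2	chr2	102055	A	T	frameshift	c.41_44del	p.I28fs	28	20	4.1	case014	diagnosis	0.995	likely_oncogenic	NA	FALSE
NFE2L2	chr2	102192	A	T	frameshift	c.33_34ins	p.L30fs	30	20	4	case014	diagnosis	0.995	likely_oncogenic	NA	FALSE
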