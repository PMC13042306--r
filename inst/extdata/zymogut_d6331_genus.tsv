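# ZymoGut D6331 gut-standard genus-level comparison.
# truth_n: contig-derived ground-truth counts (535 contigs total);
# pred_n: predicted counts (534 contigs classified). Percentage columns
# as printed (counts / total * 100, rounded to 2 decimals); diff_pp is
# predicted minus truth in percentage points, rounded after subtraction
# of the unrounded percentages.
genus	truth_n	pred_n	truth_pct	pred_pct	diff_pp
Escherichia	184	176	34.39	32.96	-1.43
Candida	165	165	30.84	30.90	0.06
Saccharomyces	155	154	28.97	28.84	-0.13
Clostridioides	10	0	1.87	0.00	-1.87
Methanobrevibacter	8	8	1.50	1.50	0.00
Prevotella	4	3	0.75	0.56	-0.19
Bifidobacterium	2	2	0.37	0.37	0.00
Akkermansia	1	1	0.19	0.19	0.00
Bacteroides	1	1	0.19	0.19	0.00
Faecalibacterium	1	1	0.19	0.19	0.00
Fusobacterium	1	2	0.19	0.37	0.19
Veillonella	1	1	0.19	0.19	0.00
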