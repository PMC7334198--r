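term	rank
transcript_ablation	1
splice_acceptor_variant	2
splice_donor_variant	3
stop_gained	4
frameshift_variant	5
stop_lost	6
start_lost	7
transcript_amplification	8
inframe_insertion	9
inframe_deletion	10
missense_variant	11
protein_altering_variant	12
splice_region_variant	13
incomplete_terminal_codon_variant	14
stop_retained_variant	15
synonymous_variant	16
coding_sequence_variant	17
mature_miRNA_variant	18
5_prime_UTR_variant	19
3_prime_UTR_variant	20
non_coding_transcript_exon_variant	21
intron_variant	22
NMD_transcript_variant	23
non_coding_transcript_variant	24
upstream_gene_variant	25
downstream_gene_variant	26
TFBS_ablation	27
TFBS_amplification	28
TF_binding_site_variant	29
regulatory_region_ablation	30
regulatory_region_amplification	31
feature_elongation	32
regulatory_region_variant	33
feature_truncation	34
intergenic_variant	35
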