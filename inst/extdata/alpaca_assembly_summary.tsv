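metric	value
total_bases	20060146
contig_count	652
n50	288719
l50	21
largest	1433950
smallest	1142
msy_bases	4485668
msy_contigs	18
par_bases	3740000
par_contigs	13
estimated_par_bases	7000000
mean_pacbio_read_length	8034
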