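marker_id	chrom	pos	source_scan
gga1_168m	chr1	168200669	gwas
gga1_171m	chr1	170731384	gwas
gga1_171v	chr1	170613341	vgwas
gga1_172v	chr1	171761454	vgwas
gga1_174v	chr1	174370270	vgwas
gga1_178v	chr1	177940599	vgwas
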