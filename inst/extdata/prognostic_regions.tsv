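label	chrom	start	end
9p21.3-21.1	9	24450001	28650000
10q25.2-qter	10	112950001	135435000
11p15.5-15.2	11	1950011	4250000
13q12.1-31.3	13	19500001	92550000
22q12.3-13.3	22	23435001	51180000
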