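# Predicted newly discovered D. pseudoobscura copies of two
# D. melanogaster microRNAs that have two genomic copies in
# D. pseudoobscura (one-to-many), with the Muller element of both
# species' copies.
mirna	chromosome	start	end	muller_dmel	muller_dpse
dme_393	NC_046679.1	21527631	21527726	E	E
dme_393	NC_046679.1	21530842	21530915	E	E
dme-mir-4948	NC_046679.1	1526563	1526662	E	E
dme-mir-4948	NC_046679.1	2671493	2671578	E	E
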