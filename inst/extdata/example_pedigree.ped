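fam1 M1 0 0 1 3|1 5|1
fam1 F1 0 0 2 1|1 5|5
fam1 O1 M1 F1 2 1|1 5|5
fam1 O2 M1 F1 1 3|1 5|1
fam1 O3 M1 F1 1 3|1 5|1
fam1 O4 M1 F1 2 1|1 5|5
fam1 O5 M1 F1 2 0 0
fam1 F2 0 0 2 3|3 1|1
fam1 P1 O2 F2 1 3|1 5|1
fam1 P2 O2 F2 2 3|3 1|1
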