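Gene	CHR	Start	Stop	Build
BBS1	11	66278121	66301084	hg19
ACTN3	11	66313866	66330841	hg19
CTSF	11	66330328	66335717	hg19
ZDHHC24	11	66250155	66255534	hg19
RCE1	11	66610745	66613855	hg19
BBS1	11	66510646	66533616	hg38
ACTN3	11	66546395	66563329	hg38
CTSF	11	66562851	66568240	hg38
ZDHHC24	11	66482684	66488063	hg38
RCE1	11	66843274	66846384	hg38
GENE1	11	1100000	1199000	hg19
GENE1	11	1100000	1199000	hg38
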