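gene_id	cytoband	direction
TTTY10	Yq11.221	up_in_males
PRKY	Yp11.2	up_in_males
TBL1Y	Yp11.2	up_in_males
KDM5D	Yq11	up_in_males
DDX3Y	Yq11	up_in_males
UTY	Yq11	up_in_males
ARSE	Xp22.3	up_in_males
PRDM7	16q24.3	up_in_males
DDX43	6q13	up_in_males
CRISP2	6p12.3	up_in_males
SMC1A	Xp11.22-p11.21	up_in_females
DDX3X	Xp11.3-p11.23	up_in_females
STS	Xp22.32	up_in_females
RIBC1	Xp11.22	up_in_females
ZFX	Xp21.3	up_in_females
EFHC2	Xp11.3	up_in_females
KDM6A	Xp11.2	up_in_females
JPX	Xq13.2	up_in_females
ZRSR2	Xp22.1	up_in_females
PNPLA4	Xp22.3	up_in_females
ARSD	Xp22.3	up_in_females
GEMIN8	Xp22.2	up_in_females
C3orf79	3q25.2	up_in_females
NLRP2	19q13.42	up_in_females
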