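raw	token
COX1	cox1
COI	cox1
CO1	cox1
COXI	cox1
CYTOCHROMECOXIDASESUBUNITI	cox1
CYTOCHROMECOXIDASESUBUNIT1	cox1
CYTOCHROMEOXIDASESUBUNITI	cox1
MTCO1	cox1
COX2	cox2
COII	cox2
CO2	cox2
COXII	cox2
CYTOCHROMECOXIDASESUBUNITII	cox2
CYTOCHROMECOXIDASESUBUNIT2	cox2
CYTOCHROMEOXIDASESUBUNITII	cox2
MTCO2	cox2
COX3	cox3
COIII	cox3
CO3	cox3
COXIII	cox3
CYTOCHROMECOXIDASESUBUNITIII	cox3
CYTOCHROMECOXIDASESUBUNIT3	cox3
CYTOCHROMEOXIDASESUBUNITIII	cox3
MTCO3	cox3
COB	cob
CYTB	cob
CYB	cob
CB	cob
CYTOCHROMEB	cob
CYTOCHROMEBAPOENZYME	cob
MTCYB	cob
NAD1	nad1
ND1	nad1
NADH1	nad1
NADHDEHYDROGENASESUBUNIT1	nad1
MTND1	nad1
NAD2	nad2
ND2	nad2
NADH2	nad2
NADHDEHYDROGENASESUBUNIT2	nad2
MTND2	nad2
NAD3	nad3
ND3	nad3
NADH3	nad3
NADHDEHYDROGENASESUBUNIT3	nad3
MTND3	nad3
NAD4	nad4
ND4	nad4
NADH4	nad4
NADHDEHYDROGENASESUBUNIT4	nad4
MTND4	nad4
NAD5	nad5
ND5	nad5
NADH5	nad5
NADHDEHYDROGENASESUBUNIT5	nad5
MTND5	nad5
NAD6	nad6
ND6	nad6
NADH6	nad6
NADHDEHYDROGENASESUBUNIT6	nad6
MTND6	nad6
NAD4L	nad4L
ND4L	nad4L
NADH4L	nad4L
NADHDEHYDROGENASESUBUNIT4L	nad4L
MTND4L	nad4L
ATP6	atp6
ATPASE6	atp6
ATPASESUBUNIT6	atp6
ATPSYNTHASEF0SUBUNIT6	atp6
ATPSYNTHASESUBUNIT6	atp6
MTATP6	atp6
A6	atp6
ATP8	atp8
ATPASE8	atp8
ATPASESUBUNIT8	atp8
ATPSYNTHASEF0SUBUNIT8	atp8
ATPSYNTHASESUBUNIT8	atp8
MTATP8	atp8
A8	atp8
RRNS	rrnS
RNS	rrnS
12S	rrnS
12SRRNA	rrnS
12SRIBOSOMALRNA	rrnS
SRRNA	rrnS
SSURRNA	rrnS
SMALLSUBUNITRIBOSOMALRNA	rrnS
MTRNR1	rrnS
RRN12	rrnS
RRNL	rrnL
RNL	rrnL
16S	rrnL
16SRRNA	rrnL
16SRIBOSOMALRNA	rrnL
LRRNA	rrnL
LSURRNA	rrnL
LARGESUBUNITRIBOSOMALRNA	rrnL
MTRNR2	rrnL
RRN16	rrnL
MNCR	MNCR
DLOOP	MNCR
CONTROLREGION	MNCR
MAJORNONCODINGREGION	MNCR
PUTATIVECONTROLREGION	MNCR
NONCODINGREGION	MNCR
ATRICHREGION	MNCR
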