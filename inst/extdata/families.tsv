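family	core_domain	system	role	refinement
Ub	ubiquitin	Ub	label
SUMO	Rad60-SLD	SUMO	label
Ufm1	Ufm1	Ufm1	label
ThiF	ThiF	shared	E1	thif_exclusion
UQ_con	UQ_con	shared	E2
zf-C3HC4	zf-C3HC4	Ub	E3
zf-RING_2	zf-RING_2	Ub	E3
RINGv	RINGv	Ub	E3
U-box	U-box	Ub	E3
IBR	IBR	Ub	E3
HECT	HECT	Ub	E3
Sina	Sina	Ub	E3
Cullin	Cullin	Ub	CRL-subunit
Skp1	Skp1	Ub	CRL-subunit
F-box	F-box	Ub	CRL-subunit
BTB	BTB	Ub	CRL-subunit
SOCS-box	SOCS_box	Ub	CRL-subunit
DCAF	WD40	Ub	CRL-subunit	dcaf_dwd
UCH	Peptidase_C12	Ub	peptidase
USP	UCH	Ub	peptidase
OTU	OTU	Ub	peptidase
Josephin	Josephin	Ub	peptidase
JAB	JAB	Ub	peptidase
zf-MIZ	zf-MIZ	SUMO	E3	zf_miz_pinit_sap
IR1-M	IR1-M	SUMO	E3
ULP	Peptidase_C48	SUMO	peptidase
WLM	WLM	SUMO	peptidase
C97	Peptidase_C97	SUMO	peptidase
DUF2042	DUF2042	Ufm1	E3
C78	Peptidase_C78	Ufm1	peptidase
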