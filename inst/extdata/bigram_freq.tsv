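bigram	count_per_million
AA	0
BA	5777.78
CA	8000
DA	4000
EA	20888.89
FA	5333.33
GA	1777.78
HA	6222.22
IA	444.44
JA	0
KA	0
LA	10222.22
MA	4888.89
NA	1777.78
OA	7111.11
PA	6222.22
QA	0
RA	8444.44
SA	5333.33
TA	5333.33
UA	444.44
VA	1333.33
WA	7111.11
XA	0
YA	1333.33
ZA	0
AB	2222.22
BB	0
CB	0
DB	0
EB	444.44
FB	0
GB	0
HB	0
IB	888.89
JB	0
KB	0
LB	0
MB	2222.22
NB	0
OB	1333.33
PB	0
QB	0
RB	1333.33
SB	0
TB	0
UB	1333.33
VB	0
WB	0
XB	0
YB	0
ZB	0
AC	4888.89
BC	0
CC	0
DC	0
EC	888.89
FC	0
GC	0
HC	0
IC	3111.11
JC	0
KC	0
LC	0
MC	0
NC	888.89
OC	1777.78
PC	0
QC	0
RC	0
SC	888.89
TC	0
UC	2222.22
VC	0
WC	0
XC	0
YC	0
ZC	0
AD	5333.33
BD	0
CD	0
DD	0
ED	4444.44
FD	0
GD	0
HD	0
ID	5333.33
JD	0
KD	0
LD	4444.44
MD	0
ND	7111.11
OD	4444.44
PD	0
QD	0
RD	4000
SD	0
TD	0
UD	444.44
VD	0
WD	0
XD	0
YD	0
ZD	0
AE	0
BE	6222.22
CE	3555.56
DE	10666.67
EE	10222.22
FE	4000
GE	4444.44
HE	8888.89
IE	888.89
JE	0
KE	6666.67
LE	11555.56
ME	8888.89
NE	13333.33
OE	1777.78
PE	6222.22
QE	0
RE	14666.67
SE	11111.11
TE	10666.67
UE	2222.22
VE	9777.78
WE	4000
XE	0
YE	1333.33
ZE	888.89
AF	1777.78
BF	0
CF	0
DF	0
EF	888.89
FF	444.44
GF	0
HF	0
IF	1777.78
JF	0
KF	0
LF	2666.67
MF	0
NF	0
OF	1333.33
PF	0
QF	0
RF	0
SF	0
TF	0
UF	444.44
VF	0
WF	0
XF	0
YF	0
ZF	0
AG	3555.56
BG	0
CG	0
DG	444.44
EG	0
FG	0
GG	0
HG	0
IG	1777.78
JG	0
KG	0
LG	0
MG	0
NG	4888.89
OG	888.89
PG	0
QG	0
RG	0
SG	0
TG	0
UG	1777.78
VG	0
WG	0
XG	0
YG	0
ZG	0
AH	444.44
BH	0
CH	4888.89
DH	0
EH	0
FH	0
GH	888.89
HH	0
IH	0
JH	0
KH	0
LH	0
MH	0
NH	0
OH	0
PH	0
QH	0
RH	0
SH	7111.11
TH	5777.78
UH	0
VH	0
WH	1777.78
XH	0
YH	0
ZH	0
AI	8000
BI	2222.22
CI	1333.33
DI	4000
EI	888.89
FI	4444.44
GI	1333.33
HI	5333.33
II	0
JI	0
KI	3555.56
LI	6666.67
MI	4000
NI	1777.78
OI	1777.78
PI	2222.22
QI	0
RI	7111.11
SI	4000
TI	3555.56
UI	1777.78
VI	1333.33
WI	6666.67
XI	444.44
YI	0
ZI	0
AJ	0
BJ	0
CJ	0
DJ	0
EJ	0
FJ	0
GJ	0
HJ	0
IJ	0
JJ	0
KJ	0
LJ	0
MJ	0
NJ	0
OJ	0
PJ	0
QJ	0
RJ	0
SJ	0
TJ	0
UJ	0
VJ	0
WJ	0
XJ	0
YJ	0
ZJ	0
AK	4444.44
BK	0
CK	7111.11
DK	0
EK	888.89
FK	0
GK	0
HK	0
IK	1333.33
JK	0
KK	0
LK	2666.67
MK	0
NK	3111.11
OK	2666.67
PK	0
QK	0
RK	3555.56
SK	3555.56
TK	0
UK	0
VK	0
WK	444.44
XK	0
YK	0
ZK	0
AL	13333.33
BL	1777.78
CL	2666.67
DL	0
EL	8888.89
FL	2222.22
GL	1777.78
HL	0
IL	12000
JL	0
KL	0
LL	13333.33
ML	0
NL	444.44
OL	10666.67
PL	2666.67
QL	0
RL	888.89
SL	4000
TL	0
UL	4444.44
VL	0
WL	444.44
XL	0
YL	0
ZL	0
AM	7555.56
BM	0
CM	0
DM	0
EM	2666.67
FM	0
GM	0
HM	0
IM	3555.56
JM	0
KM	0
LM	1333.33
MM	0
NM	0
OM	5333.33
PM	0
QM	0
RM	4444.44
SM	0
TM	0
UM	3111.11
VM	0
WM	0
XM	0
YM	0
ZM	0
AN	10222.22
BN	0
CN	0
DN	0
EN	9333.33
FN	0
GN	444.44
HN	0
IN	17777.78
JN	0
KN	2666.67
LN	0
MN	0
NN	0
ON	9777.78
PN	0
QN	0
RN	4888.89
SN	888.89
TN	0
UN	4888.89
VN	0
WN	2666.67
XN	0
YN	0
ZN	0
AO	0
BO	6666.67
CO	8888.89
DO	4444.44
EO	0
FO	4000
GO	4000
HO	7111.11
IO	444.44
JO	888.89
KO	0
LO	9333.33
MO	3555.56
NO	4888.89
OO	11555.56
PO	6666.67
QO	0
RO	9333.33
SO	7111.11
TO	5777.78
UO	0
VO	444.44
WO	3555.56
XO	0
YO	444.44
ZO	888.89
AP	4888.89
BP	0
CP	0
DP	0
EP	2222.22
FP	0
GP	0
HP	0
IP	5777.78
JP	0
KP	0
LP	444.44
MP	4000
NP	0
OP	4888.89
PP	0
QP	0
RP	0
SP	1333.33
TP	0
UP	888.89
VP	0
WP	0
XP	0
YP	444.44
ZP	0
AQ	0
BQ	0
CQ	0
DQ	0
EQ	0
FQ	0
GQ	0
HQ	0
IQ	0
JQ	0
KQ	0
LQ	0
MQ	0
NQ	0
OQ	0
PQ	0
QQ	0
RQ	0
SQ	0
TQ	0
UQ	0
VQ	0
WQ	0
XQ	0
YQ	0
ZQ	0
AR	17777.78
BR	0
CR	1777.78
DR	3111.11
ER	6222.22
FR	1333.33
GR	4000
HR	0
IR	5777.78
JR	0
KR	0
LR	0
MR	0
NR	0
OR	11555.56
PR	888.89
QR	0
RR	0
SR	0
TR	2666.67
UR	6666.67
VR	0
WR	444.44
XR	0
YR	0
ZR	0
AS	8888.89
BS	444.44
CS	0
DS	0
ES	4444.44
FS	0
GS	0
HS	0
IS	5777.78
JS	0
KS	0
LS	888.89
MS	0
NS	444.44
OS	6666.67
PS	0
QS	0
RS	0
SS	4000
TS	444.44
US	5777.78
VS	0
WS	444.44
XS	0
YS	888.89
ZS	0
AT	9777.78
BT	444.44
CT	444.44
DT	0
ET	1777.78
FT	1777.78
GT	0
HT	0
IT	5777.78
JT	0
KT	0
LT	3555.56
MT	0
NT	6222.22
OT	4888.89
PT	444.44
QT	0
RT	3555.56
ST	13777.78
TT	0
UT	1333.33
VT	0
WT	0
XT	888.89
YT	0
ZT	0
AU	444.44
BU	3111.11
CU	3111.11
DU	4000
EU	0
FU	1333.33
GU	444.44
HU	2666.67
IU	0
JU	1333.33
KU	0
LU	4000
MU	1333.33
NU	444.44
OU	4444.44
PU	1777.78
QU	888.89
RU	3111.11
SU	2222.22
TU	1333.33
UU	0
VU	0
WU	0
XU	0
YU	0
ZU	0
AV	2666.67
BV	0
CV	0
DV	0
EV	1333.33
FV	0
GV	0
HV	0
IV	1777.78
JV	0
KV	0
LV	0
MV	0
NV	0
OV	2666.67
PV	0
QV	0
RV	0
SV	0
TV	0
UV	0
VV	0
WV	0
XV	0
YV	0
ZV	0
AW	3111.11
BW	0
CW	0
DW	0
EW	4000
FW	0
GW	0
HW	0
IW	0
JW	0
KW	0
LW	0
MW	0
NW	0
OW	5777.78
PW	0
QW	0
RW	0
SW	1333.33
TW	888.89
UW	0
VW	0
WW	0
XW	0
YW	0
ZW	0
AX	0
BX	0
CX	0
DX	0
EX	1333.33
FX	0
GX	0
HX	0
IX	0
JX	0
KX	0
LX	0
MX	0
NX	0
OX	0
PX	0
QX	0
RX	0
SX	0
TX	0
UX	0
VX	0
WX	0
XX	0
YX	0
ZX	0
AY	4000
BY	444.44
CY	0
DY	888.89
EY	1777.78
FY	0
GY	0
HY	0
IY	0
JY	0
KY	0
LY	1777.78
MY	444.44
NY	1777.78
OY	0
PY	444.44
QY	0
RY	1333.33
SY	888.89
TY	1333.33
UY	0
VY	444.44
WY	0
XY	0
YY	0
ZY	444.44
AZ	444.44
BZ	0
CZ	0
DZ	0
EZ	0
FZ	0
GZ	0
HZ	0
IZ	888.89
JZ	0
KZ	0
LZ	0
MZ	0
NZ	0
OZ	0
PZ	0
QZ	0
RZ	0
SZ	0
TZ	0
UZ	0
VZ	0
WZ	0
XZ	0
YZ	0
ZZ	0
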