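label	x	y	z
PreCG.L	-17.79	-71.79	38.7
PreCG.R	17.79	-71.79	38.7
SFGdor.L	-44.38	40.23	36.95
SFGdor.R	44.38	40.23	36.95
ORBsup.L	-11.58	14.33	18.28
ORBsup.R	11.58	14.33	18.28
MFG.L	-50.27	-44.11	-1.42
MFG.R	50.27	-44.11	-1.42
ORBmid.L	-45.82	22.96	49
ORBmid.R	45.82	22.96	49
IFGoperc.L	-38.18	-44.13	22.55
IFGoperc.R	38.18	-44.13	22.55
IFGtriang.L	-54.45	-10.91	60.26
IFGtriang.R	54.45	-10.91	60.26
ORBinf.L	-34.8	-79	59.04
ORBinf.R	34.8	-79	59.04
ROL.L	-25.54	-15.24	63.36
ROL.R	25.54	-15.24	63.36
SMA.L	-10.1	29.2	-38.82
SMA.R	10.1	29.2	-38.82
OLF.L	-14.52	-37.21	-9.75
OLF.R	14.52	-37.21	-9.75
SFGmed.L	-19.68	-45.23	35.6
SFGmed.R	19.68	-45.23	35.6
ORBsupmed.L	-34.39	-90.38	41.58
ORBsupmed.R	34.39	-90.38	41.58
REC.L	-8.63	29.16	52.23
REC.R	8.63	29.16	52.23
INS.L	-30.53	-26.01	-14.52
INS.R	30.53	-26.01	-14.52
ACG.L	-33.16	-0.24	-31.07
ACG.R	33.16	-0.24	-31.07
DCG.L	-16.29	-88.95	19.91
DCG.R	16.29	-88.95	19.91
PCG.L	-33.18	58.23	60.26
PCG.R	33.18	58.23	60.26
HIP.L	-22.48	-56.75	52.3
HIP.R	22.48	-56.75	52.3
PHG.L	-41.27	4.53	-20.88
PHG.R	41.27	4.53	-20.88
AMYG.L	-10.76	-32.95	28.31
AMYG.R	10.76	-32.95	28.31
CAL.L	-29.48	-14.4	31.78
CAL.R	29.48	-14.4	31.78
CUN.L	-51.89	54.69	63.05
CUN.R	51.89	54.69	63.05
LING.L	-23.76	-40.69	-30.08
LING.R	23.76	-40.69	-30.08
SOG.L	-36.5	-10.86	1.12
SOG.R	36.5	-10.86	1.12
MOG.L	-15.5	-34.63	53.42
MOG.R	15.5	-34.63	53.42
IOG.L	-24	-92.51	-1.68
IOG.R	24	-92.51	-1.68
FFG.L	-32.59	-18.64	9.8
FFG.R	32.59	-18.64	9.8
PoCG.L	-59.02	-65.17	42.62
PoCG.R	59.02	-65.17	42.62
SPG.L	-45.43	1.94	38.69
SPG.R	45.43	1.94	38.69
IPL.L	-6.21	33.58	-8.23
IPL.R	6.21	33.58	-8.23
SMG.L	-13.88	51.34	-21.73
SMG.R	13.88	51.34	-21.73
ANG.L	-30.75	-58.43	-1.61
ANG.R	30.75	-58.43	-1.61
PCUN.L	-60.34	10.88	44.61
PCUN.R	60.34	10.88	44.61
PCL.L	-17.8	-35.21	6.67
PCL.R	17.8	-35.21	6.67
CAU.L	-29.82	-89.21	-22.84
CAU.R	29.82	-89.21	-22.84
PUT.L	-21.12	-3.37	-11.79
PUT.R	21.12	-3.37	-11.79
PAL.L	-41.67	-87.02	-14.24
PAL.R	41.67	-87.02	-14.24
THA.L	-56.21	50.04	11.17
THA.R	56.21	50.04	11.17
HES.L	-27.6	47.12	63.37
HES.R	27.6	47.12	63.37
STG.L	-45.98	27.89	1.68
STG.R	45.98	27.89	1.68
TPOsup.L	-58.38	26.35	-5.29
TPOsup.R	58.38	26.35	-5.29
MTG.L	-45.03	63.7	13.09
MTG.R	45.03	63.7	13.09
TPOmid.L	-11.23	-19.26	0.76
TPOmid.R	11.23	-19.26	0.76
ITG.L	-39.31	-43.59	-33.79
ITG.R	39.31	-43.59	-33.79
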