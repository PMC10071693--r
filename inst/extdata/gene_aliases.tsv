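alias	canonical
GITR	TNFRSF18
TNFRSF18	TNFRSF18
CD141	THBD
BDCA3	THBD
BDCA-3	THBD
THBD	THBD
B7-H3	CD276
B7H3	CD276
CD276	CD276
FRP2	FPR2
FPR2	FPR2
DC-LAMP	LAMP3
DCLAMP	LAMP3
CD208	LAMP3
LAMP3	LAMP3
C1INH	SERPING1
C1-INH	SERPING1
SERPING1	SERPING1
NFKB1	NFKB1
NFkb1	NFKB1
CTLA-4	CTLA4
CTLA4	CTLA4
PD-L1	CD274
PDL1	CD274
B7-H1	CD274
CD274	CD274
PD-L2	PDCD1LG2
PDL2	PDCD1LG2
PDCD1LG2	PDCD1LG2
CD137	TNFRSF9
4-1BB	TNFRSF9
41BB	TNFRSF9
TNFRSF9	TNFRSF9
TIM3	HAVCR2
TIM-3	HAVCR2
HAVCR2	HAVCR2
IP-10	CXCL10
CXCL10	CXCL10
MIG	CXCL9
CXCL9	CXCL9
I-TAC	CXCL11
CXCL11	CXCL11
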