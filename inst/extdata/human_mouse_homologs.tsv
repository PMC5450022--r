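human	mouse
CDH2	Cdh2
FN1	Fn1
SNAI2	Snai2
ZEB1	Zeb1
ZEB2	Zeb2
EPCAM	Epcam
OCLN	Ocln
STAT3	Stat3
SOX2	Sox2
MAP1B	Map1b
RELN	Reln
ROBO1	Robo1
TUBB3	Tubb3
VIM	Vim
TWIST1	Twist1
SNAI1	Snai1
MMP2	Mmp2
MMP9	Mmp9
CDH1	Cdh1
CLDN3	Cldn3
CLDN4	Cldn4
CLDN7	Cldn7
DSP	Dsp
KRT8	Krt8
KRT18	Krt18
KRT19	Krt19
COL1A1	Col1a1
SPARC	Sparc
TNC	Tnc
GAPDH	Gapdh
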