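EMT_UP_SYNTHETIC	synthetic stand-in for the up-regulated half of an EMT signature	Cdh2	Fn1	Slug	Zeb1	Zeb2	Vim	Twist1	Snai1	Mmp2	Mmp9	Col1a1	Col5a2	Sparc	Tnc	Itgb1
EMT_DOWN_SYNTHETIC	synthetic stand-in for the down-regulated half of an EMT signature	Cdh1	Epcam	Ocln	Cldn3	Cldn4	Cldn7	Dsp	Krt8	Krt18	Krt19	Esrp1	Grhl2	Rab25	Spint1	St14
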