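alias	official
Snai2	Slug
Snail	Snai1
Krt-18	Krt18
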