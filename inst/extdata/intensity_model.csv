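"entity","mean","sd"
"mitral_valve",266,25
"la_wall",100,38
"la_cavity",357,14
"lv_myocardium",75,8
"lv_cavity",344,23
"ra_wall",88,32
"ra_cavity",405,26
"rv_wall",71,25
"rv_cavity",356,15
"aorta",330,22
"bones",157,72
"liver",119,47
"kidney",126,14
"lung",8,4
"bronchi",389,42
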