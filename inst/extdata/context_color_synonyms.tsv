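term	class
white	white
pure white	white
white to light buff	white
light buff	buff
cream	buff
buff	buff
light brown	buff
pink-buff	buff
pinkish-buff	buff
pinkish buff	buff
pink buff	buff
cinnamon-buff	buff
cinnamon buff	buff
pink-buff to cinnamon buff	buff
pink-buff to cinnamon-buff	buff
pinkish-buff to cinnamon-buff	buff
cream to light buff	buff
cinnamon brown	dark_brown
dark brown	dark_brown
dark cinnamon brown	dark_brown
cinnamon brown to black	dark_brown
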