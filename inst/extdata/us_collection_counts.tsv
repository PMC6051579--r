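species	count
G. curtisii	142
G. curtisii f.sp. meredithiae	10
G. lucidum	5
G. martinicense	18
G. oregonense	13
G. polychromum	12
G. ravenelii	14
G. sessile	149
G. tsugae	37
G. tuberculosum	26
G. cf. weberianum	5
G. zonatum	71
T. colossus	5
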