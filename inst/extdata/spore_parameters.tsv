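species	mean_length	min_length	max_length	mean_width	min_width	max_width	printed_ssi	printed_q
G. curtisii	10.6	8.3	12.1	6.4	5.4	7.5	60.4	1.7
G. curtisii f.sp. meredithiae	10.8	9.5	11.5	6.8	6.4	7.3	62.6	1.6
G. lucidum	10.7	8.2	12.1	7.1	4.8	8.9	66.2	1.5
G. martinicense	11.1	9.0	13.6	6.9	5.3	8.3	62.6	1.6
G. oregonense	12.9	11.6	14.9	8.0	6.7	9.3	62.2	1.6
G. polychromum	12.2	10.8	13.2	6.8	6.0	7.4	55.5	1.8
G. ravenelii	11.2	9.1	13.6	5.2	4.2	6.8	46.5	2.2
G. sessile	11.4	9.7	14.0	6.6	5.2	8.4	58.1	1.7
G. tsugae	9.9	8.9	11.5	6.5	5.2	7.7	65.2	1.5
G. tuberculosum	10.5	9.2	12.0	7.3	6.2	8.6	69.3	1.4
G. cf. weberianum	8.4	7.7	9.5	5.6	4.7	7.3	67.0	1.5
G. zonatum	11.8	10.3	13.7	5.9	5.0	6.6	49.5	2.0
T. colossus	16.1	14.6	17.3	10.4	9.5	11.3	64.8	1.5
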