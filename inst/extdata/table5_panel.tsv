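patient	cohort	ph	call_A	call_P
B02	benign	normal	positive	negative
B04	benign	normal	negative	negative
B05	benign	normal	negative	negative
B09	benign	normal	negative	negative
B24	benign	normal	negative	negative
B25	benign	high	positive	negative
B26	benign	high	negative	positive
B27	benign	high	positive	positive
B30	benign	normal	negative	negative
B32	benign	high	positive	negative
EC06	cancer	high	positive	positive
EC10	cancer	high	positive	positive
EC11	cancer	high	positive	positive
EC12	cancer	high	positive	positive
EC13	cancer	normal	positive	positive
EC14	cancer	normal	positive	positive
EC15	cancer	normal	positive	positive
EC19	cancer	high	positive	positive
EC22	cancer	normal	positive	positive
EC28	cancer	high	positive	positive
EC31	cancer	high	positive	negative
EC42	cancer	high	positive	negative
EC54	cancer	high	positive	positive
EC62	cancer	unknown	negative	positive
EC65	cancer	high	positive	negative
H07	hyperplasia	high	negative	negative
H08	hyperplasia	high	negative	negative
H63	hyperplasia	normal	negative	positive
H72	hyperplasia	normal	positive	negative
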