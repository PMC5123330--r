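sample	subject	cohort	site	collection_method	vaginal_ph
B02_V	B02	benign	vagina	swab	normal
B04_V	B04	benign	vagina	swab	normal
B05_V	B05	benign	vagina	swab	normal
B09_V	B09	benign	vagina	swab	normal
B24_V	B24	benign	vagina	swab	normal
B25_V	B25	benign	vagina	swab	high
B26_V	B26	benign	vagina	swab	high
B27_V	B27	benign	vagina	swab	high
B30_V	B30	benign	vagina	swab	normal
B32_V	B32	benign	vagina	swab	high
EC06_V	EC06	cancer	vagina	swab	high
EC10_V	EC10	cancer	vagina	swab	high
EC11_V	EC11	cancer	vagina	swab	high
EC12_V	EC12	cancer	vagina	swab	high
EC13_V	EC13	cancer	vagina	swab	normal
EC14_V	EC14	cancer	vagina	swab	normal
EC15_V	EC15	cancer	vagina	swab	normal
EC19_V	EC19	cancer	vagina	swab	high
EC22_V	EC22	cancer	vagina	swab	normal
EC28_V	EC28	cancer	vagina	swab	high
EC31_V	EC31	cancer	vagina	swab	high
EC42_V	EC42	cancer	vagina	swab	high
EC54_V	EC54	cancer	vagina	swab	high
EC62_V	EC62	cancer	vagina	swab	unknown
EC65_V	EC65	cancer	vagina	swab	high
H07_V	H07	hyperplasia	vagina	swab	high
H08_V	H08	hyperplasia	vagina	swab	high
H63_V	H63	hyperplasia	vagina	swab	normal
H72_V	H72	hyperplasia	vagina	swab	normal
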