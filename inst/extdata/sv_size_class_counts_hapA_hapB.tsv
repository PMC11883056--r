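type	size_class	count
inversion	100 to <1 kb	40
inversion	1 to <10 kb	18
inversion	10 to <100 kb	29
inversion	100 kb to <1 Mb	14
inversion	>=1 Mb	2
translocation	100 to <1 kb	241
translocation	1 to <10 kb	912
translocation	10 to <100 kb	173
translocation	100 kb to <1 Mb	5
translocation	>=1 Mb	0
insertion	100 to <1 kb	3621
insertion	1 to <10 kb	1093
insertion	10 to <100 kb	46
insertion	100 kb to <1 Mb	0
insertion	>=1 Mb	0
deletion	100 to <1 kb	3730
deletion	1 to <10 kb	1077
deletion	10 to <100 kb	51
deletion	100 kb to <1 Mb	0
deletion	>=1 Mb	0
duplicated region	100 to <1 kb	170
duplicated region	1 to <10 kb	595
duplicated region	10 to <100 kb	38
duplicated region	100 kb to <1 Mb	0
duplicated region	>=1 Mb	0
inverted duplicate	100 to <1 kb	138
inverted duplicate	1 to <10 kb	431
inverted duplicate	10 to <100 kb	83
inverted duplicate	100 kb to <1 Mb	0
inverted duplicate	>=1 Mb	0
tandem repeat	100 to <1 kb	12
tandem repeat	1 to <10 kb	3
tandem repeat	10 to <100 kb	0
tandem repeat	100 kb to <1 Mb	0
tandem repeat	>=1 Mb	0
copy gain	100 to <1 kb	61
copy gain	1 to <10 kb	54
copy gain	10 to <100 kb	16
copy gain	100 kb to <1 Mb	3
copy gain	>=1 Mb	0
copy loss	100 to <1 kb	84
copy loss	1 to <10 kb	49
copy loss	10 to <100 kb	18
copy loss	100 kb to <1 Mb	1
copy loss	>=1 Mb	0
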