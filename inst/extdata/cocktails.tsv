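# The ten published SM reprogramming cocktails; member names as printed
# in the source listings (variant spellings resolved by canonicalize()).
cocktail	label	member
Cocktail 1	VC6TF + TTNPB + DZNep	Valproic acid
Cocktail 1	VC6TF + TTNPB + DZNep	CHIR99021
Cocktail 1	VC6TF + TTNPB + DZNep	RepSox
Cocktail 1	VC6TF + TTNPB + DZNep	Parnate
Cocktail 1	VC6TF + TTNPB + DZNep	Forskolin
Cocktail 1	VC6TF + TTNPB + DZNep	DZNep
Cocktail 1	VC6TF + TTNPB + DZNep	TTNPB
Cocktail 2	NLS	NaB
Cocktail 2	NLS	LiCl
Cocktail 2	NLS	SB431542
Cocktail 3	VCR	Valproic acid
Cocktail 3	VCR	CHIR99021
Cocktail 3	VCR	RepSox
Cocktail 4	TLT	TSA
Cocktail 4	TLT	Li2CO3
Cocktail 4	TLT	Tranilast
Cocktail 5	BrdUC6F	BrdU
Cocktail 5	BrdUC6F	CHIR99021
Cocktail 5	BrdUC6F	RepSox
Cocktail 5	BrdUC6F	Forskolin
Cocktail 6	VC6TF + AM 580 + EPZ004777	VPA
Cocktail 6	VC6TF + AM 580 + EPZ004777	CHIR99021
Cocktail 6	VC6TF + AM 580 + EPZ004777	RepSox
Cocktail 6	VC6TF + AM 580 + EPZ004777	Parnate
Cocktail 6	VC6TF + AM 580 + EPZ004777	Forskolin
Cocktail 6	VC6TF + AM 580 + EPZ004777	AM 580
Cocktail 6	VC6TF + AM 580 + EPZ004777	EPZ004777
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	VPA
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	CHIR99021
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	RepSox
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	Parnate
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	Forskolin
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	AM580
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	DZNep
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	5-aza-dC
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	SGC0946
Cocktail 7	VC6TF + AM580 + DZNep + 5-aza-dC + SGC0946 + EPZ004777	EPZ004777
Cocktail 8	VC6TF + DZNep	VPA
Cocktail 8	VC6TF + DZNep	CHIR99021
Cocktail 8	VC6TF + DZNep	RepSOX
Cocktail 8	VC6TF + DZNep	Parnate
Cocktail 8	VC6TF + DZNep	Forskolin
Cocktail 8	VC6TF + DZNep	DZNep
Cocktail 9	VC6TF + AM 580 + DZNep	VPA
Cocktail 9	VC6TF + AM 580 + DZNep	CHIR99021
Cocktail 9	VC6TF + AM 580 + DZNep	RepSox
Cocktail 9	VC6TF + AM 580 + DZNep	Parnate
Cocktail 9	VC6TF + AM 580 + DZNep	Forskolin
Cocktail 9	VC6TF + AM 580 + DZNep	AM 580
Cocktail 9	VC6TF + AM 580 + DZNep	DZNep
Cocktail 10	CNaATP	CHIR99021
Cocktail 10	CNaATP	NaB
Cocktail 10	CNaATP	cyclic pifithrin-a
Cocktail 10	CNaATP	A-83-01
Cocktail 10	CNaATP	Thiazovivin
Cocktail 10	CNaATP	PD0325901
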