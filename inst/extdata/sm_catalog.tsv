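canonical_name	synonyms	categories	bioactivity
CHIR99021	C|CHIR-99021	metabolic	GSK3 inhibitor (promotes glycolysis)
RepSox	6|E-616452	signaling	TGFbeta inhibitor; can replace Sox2
Valproic acid	VPA|V	epigenetic	HDAC inhibitor
Forskolin	F	signaling	cAMP activator; can replace Oct4
Parnate	T|Tranylcypromine	epigenetic	Inhibitor of LSD1 acting on histone H3
DZNep	3-Deazaneplanocin A	epigenetic	Inhibitor of HMT EZH and SAH synthesis
AM 580	AM580	signaling	Nuclear RARalpha selective agonist
EPZ004777	EPZ-004777	epigenetic	DOT1L histone (H3K79) methyltransferase inhibitor
NaB	Sodium butyrate|Sodium Butyrate (NaB)	epigenetic	HDAC inhibitor
TTNPB	Arotinoid acid	signaling	Synthetic retinoic acid receptor ligand
BrdU	5-bromo-2'-deoxyuridine|Bromodeoxyuridine	epigenetic|signaling	Synthetic analog of thymidine, incorporated into DNA; can replace Oct4
LiCl	Lithium chloride	metabolic	GSK3 inhibitor (promotes glycolysis)
SB431542	SB-431542	signaling	TGFbeta inhibitor; can replace RepSox
Tranilast	Rizaben	signaling	TGFbeta inhibitor; can replace RepSox
Trichostatin A	TSA	epigenetic	HDAC inhibitor
Li2CO3	Lithium carbonate	metabolic	GSK3 inhibitor (promotes glycolysis)
5-aza-dC	5'-aza-dC|Decitabine|5-Aza-2'-deoxycytidine	epigenetic	DNMT inhibitor
SGC0946	SGC-0946	epigenetic	DOT1L histone (H3K79) methyltransferase inhibitor
Cyclic pifithrin-a	cyclic pifithrin-alpha|Pifithrin-alpha cyclic	signaling	p53 inhibitor
A-83-01	A83-01	signaling	TGF-beta receptor inhibitor
Thiazovivin	Tzv	signaling	Rho kinase (ROCK) inhibitor
PD0325901	PD-0325901	signaling	MKK1 (MEK1) and MKK2 (MEK2) inhibitor
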