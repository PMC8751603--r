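# The 28 reprogramming SMs that are also found in the human metabolome,
# with their role in induced cell reprogramming and chemical class.
name	role	chemical_class
5'-Azacytidine (5'-azaC)	Enhancer	Nucleotides and nucleotide derivatives
5'-Aza-2'-deoxycytidine	Enhancer	Nucleotides and nucleotide derivatives
7-hydroxyflavone	Enhancer	Flavonoids
90-D3 (Vitamin D3)	Enhancer	Steroids and steroid derivatives
Apigenin	Enhancer	Flavonoids
Caffeic acid	Putative enhancer or inducer	Cinnamic acids and derivatives
Chlorogenic acid	Putative enhancer or inducer	Fatty acids and derivatives
Curcumin	Enhancer	Diarylheptanoids
Dasatinib	Inducer	Benzene and derivatives
Dexamethasone	Enhancer	Steroids and steroid derivatives
EGCG	Enhancer	Flavonoids
Fisetin	Enhancer	Flavonoids
Forskolin	Inducer	Benzofurans
Fru-2,6-P2	Enhancer	Organooxygen compounds
Luteolin	Enhancer	Flavonoids
N-acetyl-cysteine	Enhancer	Amino acids and derivatives
Sodium Butyrate (NaB)	Inducer and enhancer	Fatty acids and derivatives
Prostaglandin E2	Enhancer	Fatty acids and derivatives
Quercetin	Enhancer	Flavonoids
Rapamycin	Enhancer	Macrolide lactams
Resveratrol	Enhancer	Stilbenes
Retinoic acid	Enhancer	Prenol lipids
SAHA	Enhancer	Benzene and derivatives
Spermidine	Enhancer	Organonitrogen compounds
Valproic acid	Inducer	Fatty acids and derivatives
Vitamin A (Retinol acetate)	Enhancer	Prenol lipids
Vitamin C (Ascorbic acid; Ascorbate)	Enhancer	Dihydrofurans
Zolpidem	Enhancer	Azoles
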