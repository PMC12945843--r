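# Functional-group multiset for cefdinir (C14H13N5O5S2), neutral form,
# expressed in the labels of groups_hvk_fedors.csv. Derived by manual
# decomposition of the cephem core (beta-lactam + dihydrothiazine rings,
# 3-vinyl, 4-COOH), the 7-amido side chain (amide C=O/NH, oxime C=N-OH)
# and the 2-aminothiazole ring. Heavy atoms sum to 26, matching the
# molecular formula.
group,count
CH2,1
CH,2
CH2=,1
CH=,2
C=,5
C=O,2
COOH,1
OH,1
NH2,1
NH,1
N,1
N=,2
S,2
ring5plus,2
ring3or4,1
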