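# Group-contribution increments for organic functional groups.
# Fd, Fp: Hoftyzer-Van Krevelen molar attraction constants, MPa^0.5 cm^3/mol
#   (Van Krevelen & Te Nijenhuis, Properties of Polymers, 4th ed., ch. 7).
# Eh: Hoftyzer-Van Krevelen hydrogen-bond cohesion energy, J/mol.
# delta_v: Fedors molar volume increment, cm^3/mol
#   (Fedors, Polym. Eng. Sci. 14 (1974) 147-154).
# heavy_atoms: heavy (non-H) atoms consumed by the group; 0 for ring
#   corrections. smarts is documentation of the intended chemical
#   environment; matching is done by the bundled rule set keyed on label.
# priority: lower numbers are matched first (most specific groups first).
label,smarts,priority,Fd,Fp,Eh,delta_v,heavy_atoms
COOH,[CX3](=O)[OX2H1],10,530,420,10000,28.5,3
COO,[CX3](=O)[OX2H0],20,390,490,7000,18.0,3
C=O,[CX3]=[OX1],30,290,770,2000,10.8,2
OH,[OX2H1],40,210,500,20000,10.0,1
O,[OX2H0],50,100,400,3000,3.8,1
NH2,[NX3H2],60,280,0,8400,19.2,1
NH,[NX3H1],70,160,210,3100,4.5,1
N,[NX3H0],80,20,800,5000,-9.0,1
N=,[NX2]=*,85,20,800,5000,5.0,1
S,[SX2],90,440,0,0,12.0,1
CH2=,[CX3H2]=*,100,400,0,0,28.5,1
CH=,[CX3H1]=*,110,200,0,0,13.5,1
C=,[CX3H0]=*,120,70,0,0,-5.5,1
CH3,[CX4H3],130,420,0,0,33.5,1
CH2,[CX4H2],140,270,0,0,16.1,1
CH,[CX4H1],150,80,0,0,-1.0,1
C,[CX4H0],160,-70,0,0,-19.2,1
ring5plus,ring closure of 5 or more atoms,900,190,0,0,16.0,0
ring3or4,ring closure of 3 or 4 atoms,910,190,0,0,18.0,0
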