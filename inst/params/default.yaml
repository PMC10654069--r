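# Default parameter profile for the cell flux model of phytoplankton.
#
# Units: concentrations uM; rates d^-1; quotas mol (mol C)^-1.
# A_P carries (mol P (mol C)^-1 d^-1) per uM so that V_P = A_P * [PO4]
# is a phosphorus flux per cell carbon.  At the reference irradiance of
# 200 umol photons m^-2 s^-1 this profile saturates at mu = 1.16 d^-1.

# --- uptake and photosynthesis ---
A_P: 0.03        # phosphate affinity, (mol P (mol C)^-1 d^-1) uM^-1
A_N: 0.03        # nitrate affinity (N variant), (mol N (mol C)^-1 d^-1) uM^-1
A_Pho: 3.0       # photosynthetic machinery : chlorophyll quota ratio, -
P_max: 260.0     # max C fixation per chlorophyll C at light saturation, d^-1
O_I: 0.00863     # irradiance saturation constant, (umol photons m^-2 s^-1)^-1

# --- biosynthesis ---
E: 0.6           # respiration + excretion overhead on biosynthesis, -
A_Bio: 0.25      # biosynthetic protein per unit growth rate, d
A_RNA: 0.18      # RNA quota per (mu x protein quota), d
A_Plip: 0.12     # thylakoid phospholipid per unit chlorophyll, -

# --- constant carbon quotas, mol C (mol C)^-1 ---
Q_C_Pro_other: 0.24   # growth-independent (essential) protein
Q_C_DNA: 0.011        # DNA
Q_C_RNA_min: 0.005    # growth-independent RNA floor
Q_C_other: 0.30       # cell wall, structural lipid, remaining carbon

# --- P:C stoichiometry, mol P (mol C)^-1 ---
Y_RNA: 0.105     # one phosphate per ~9.5 ribonucleotide carbons
Y_DNA: 0.105     # deoxyribonucleotide composition, ~ RNA
Y_Plip: 0.025    # one phosphate per ~40 phospholipid carbons
Q_P_other: 0.0008  # residual P (metabolites, ATP pool), mol P (mol C)^-1

# --- N:C stoichiometry (nitrogen-limitation comparison variant) ---
Y_Pro_N: 0.27    # protein N:C from mean amino-acid composition
Y_RNA_N: 0.40    # ~3.8 N per 9.5 C in ribonucleotides
Y_DNA_N: 0.40    # deoxyribonucleotide composition
Y_Chl_N: 0.073   # 4 N per 55 C in chlorophyll a
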