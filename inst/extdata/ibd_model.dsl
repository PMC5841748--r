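# 43-node Boolean model of the mucosal immune circuitry of inflammatory
# bowel disease. One rule per node; precedence NOT > AND > OR.
# ALL(X, w): X active in every one of the previous w iterations.
# ANY(X, w): X active in at least one of the previous w iterations.
#
# Parameter-name note: the canonical underscore spellings below subsume the
# spelling variants downregcyt/downreg_cyt, upreg_cel/upreg_cell,
# downregcell/downreg_cell and AG-elim/Ag_elim; IEC_ULPB1_6 subsumes
# IEC_ULPB_1_6, IL23 subsumes Il23.
#@ title: IBD cytokine signalling network (chronic antigen exposure)
#@ input: PGN MDP LPS
#@ output: MMPs
#@ animal: IL6 IL21 IL23

# thresholds (iterations)
Ag_elim = 6
downreg_cyt = 4
upreg_cyt = 3
upreg_cell = 2
downreg_cell = 2
upreg_rec = 2
THR_Th0 = 3
THR_Th0_Treg = 3
THR_NOD2_DEF = 3
THR_LIGANDS_NKG2D = 3

# -- inputs: chronic bacterial antigen exposure -------------------------
# An antigen stays ON unless an antimicrobial effector (perforin,
# granzyme B or defensins) has been active for Ag_elim consecutive
# iterations.
PGN = !(ALL(PERFOR, Ag_elim) | ALL(GRANZB, Ag_elim) | ALL(DEF, Ag_elim))
MDP = !(ALL(PERFOR, Ag_elim) | ALL(GRANZB, Ag_elim) | ALL(DEF, Ag_elim))
LPS = !(ALL(PERFOR, Ag_elim) | ALL(GRANZB, Ag_elim) | ALL(DEF, Ag_elim))

# -- internal nodes -----------------------------------------------------
TLR2 = PGN
TLR4 = LPS
NOD2 = MDP
NFkB = TLR2 | NOD2 | TLR4
IL6 = (MACR & PGN) | (DC & (LPS | PGN)) | (Th17 & IL23) | (NFkB & !(IL4 | IL10))
TNFa = ((NFkB & LPS) | (MACR & (IL2 | (IFNg & LPS) | PGN)) | (NK & (MDP | PGN | LPS) & ((IL2 | IL12) & (IL2 | IL15))) | (FIBROBLAST & IFNg) | ((CD4_NKG2D | CD8_NKG2D | NK_NKG2D) & (IEC_MICA_B | IEC_ULPB1_6))) & !(ALL(IL10, downreg_cyt) & (ALL(TLR2, downreg_cyt) | ALL(TLR4, downreg_cyt)) & TNFa)
TGFb = Treg | MACR
Th0 = ALL(LPS, THR_Th0) | ALL(MDP, THR_Th0) | ALL(PGN, THR_Th0)
Th0_M = (Th0 & (IL23 | IL12)) | Th0_M
IL18 = ((MACR | DC) & LPS) & NFkB
IL1b = ((MACR | DC) & LPS & NFkB) & !(IL1b & ANY(IL10, downreg_cyt))
IFNg = ((NK & (PGN | LPS | MDP) & (IL23 | (IL12 & (IL2 | IL15 | IL18)))) | (Th0_M & (LPS | MDP | PGN) & (IL12 | IL23)) | Th1 | ((CD8_NKG2D | NK_NKG2D) & (IEC_MICA_B | IEC_ULPB1_6)) | (Th17 & (PGN | LPS | MDP)) | ((MACR | Th0) & IL18 & IL12)) & !(IFNg & (ALL(TGFb, downreg_cyt) | ALL(IL10, downreg_cyt) | Th2))
IL23 = (MACR & IL1b) | DC
IL22 = Th17 | (NK & ((IL18 & IL12) | IL23)) | CD4_NKG2D | (((IL22 & Th0 & IL21) & !(ALL(IL22, upreg_cyt) & ALL(Th0, upreg_cyt) & ALL(IL21, upreg_cyt))) & !TGFb)
IL21 = Th17 | ((Th0 & IL6) & !(IL4 | IFNg | TGFb))
IL17 = (Th17 | (Th17_M & (LPS | MDP | PGN)) | (CD4_NKG2D & (IEC_MICA_B | IEC_ULPB1_6))) & !((ALL(TGFb, downreg_cyt) | ALL(IL13, downreg_cyt)) & IL17)
IL10 = Treg | (Th2 & !IL23) | ((TLR2 & NFkB) & !(MACR & IFNg)) | ((MACR & LPS) & !IL4) | (DC & LPS)
Th17 = ((Th0 & (IL1b | IL23 | IL6)) | ((Th17 & IL23) & !(ALL(Th17, upreg_cell) & ALL(IL23, upreg_cell)))) & !((ANY(TGFb, downreg_cell) | ANY(IL12, downreg_cell) | ANY(IL4, downreg_cell) | ANY(IFNg, downreg_cell) | ANY(Treg, downreg_cell)) & Th17)
Th17_M = ((Th0_M & (PGN | MDP | LPS)) & ((IL1b & IL6) | IL23 | IL2)) | Th17_M
Th1 = (Th0 & ((IL12 | IFNg | IL18) | (DC & IL12 & IL23 & LPS))) & !(((ANY(IL17, downreg_cell) & ANY(IL12, downreg_cell)) | (ANY(Treg, downreg_cell) | ANY(Th2, downreg_cell) | ANY(TGFb, downreg_cell) | ANY(IL10, downreg_cell) | ANY(IL4, downreg_cell))) & Th1)
Th2 = (Th0 & (IL10 | ((IL18 & IL4) & !IL12)) | ((Th2 & IL4) & !(ALL(Th2, upreg_cell) & ALL(IL4, upreg_cell)))) & !((ANY(Treg, downreg_cell) | ANY(IFNg, downreg_cell) | ANY(TGFb, downreg_cell)) & Th2)
IL4 = Th2
IL15 = (FIBROBLAST & (MDP | LPS | PGN)) | (MACR & (LPS | IFNg))
IL12 = ((((MACR | DC) & (LPS | PGN) & IFNg) & !(IL12 & ANY(TNFa, downreg_cyt))) | (DC & IL1b) | (IL12 & (IL13 | IL4))) & !((ANY(TGFb, downreg_cyt) | ANY(IL10, downreg_cyt)) & IL12)
IL13 = Th2
Treg = (ALL(Th0, THR_Th0_Treg) & (TGFb | TLR2)) & !((ANY(IL6, downreg_cell) | ANY(IL21, downreg_cell) | ANY(IL23, downreg_cell) | ANY(Th17, downreg_cell) | ANY(IL22, downreg_cell) | ANY(TNFa, downreg_cell)) & Treg)
NK = (IL15 | IL2 | IL12 | IL23 | (IL18 & IL10)) & !(ANY(Treg, downreg_cell) & NK)
DEF = IL22 | IL17 | ALL(NOD2, THR_NOD2_DEF)
IL2 = Th0 | (Th0_M & (MDP | LPS | PGN)) | DC
MACR = (NFkB | ((MACR & (IFNg | IL15)) & !(ALL(NFkB, upreg_cell) & (ALL(IFNg, upreg_cell) | ALL(IL15, upreg_cell))))) & !(ANY(IL10, downreg_cell) & MACR)
DC = NFkB & !(ANY(IL10, downreg_cell) & DC)
IEC_MICA_B = ((LPS | MDP | PGN) | (IEC_MICA_B & TNFa) & !(ALL(IEC_MICA_B, upreg_rec) & ALL(TNFa, upreg_rec))) & !TGFb
IEC_ULPB1_6 = CD8_NKG2D & (LPS | MDP | PGN)
CD8_NKG2D = (LPS | PGN | MDP) & !((ALL(IEC_MICA_B, THR_LIGANDS_NKG2D) | ALL(IEC_ULPB1_6, THR_LIGANDS_NKG2D) | (ANY(IL21, downreg_cell) & ANY(IL2, downreg_cell))) & CD8_NKG2D)
NK_NKG2D = (LPS | PGN | MDP) & !((ANY(TGFb, downreg_cell) | ALL(IEC_MICA_B, THR_LIGANDS_NKG2D) | ALL(IEC_ULPB1_6, THR_LIGANDS_NKG2D) | (ANY(IL21, downreg_cell) & ANY(IL12, downreg_cell))) & NK_NKG2D)
CD4_NKG2D = (LPS | PGN | MDP | ((CD4_NKG2D & (IL15 | TNFa)) & !(ALL(CD4_NKG2D, upreg_rec) & (ALL(IL15, upreg_rec) | ALL(TNFa, upreg_rec))))) & !((ANY(IL10, downreg_cell) | ALL(IEC_MICA_B, THR_LIGANDS_NKG2D) | ALL(IEC_ULPB1_6, THR_LIGANDS_NKG2D)) & CD4_NKG2D)
FIBROBLAST = ((MACR & (IL4 | IL13 | TGFb)) | IL2) & !((ANY(IFNg, downreg_cell) | ANY(IL12, downreg_cell)) & FIBROBLAST)
PERFOR = NK | NK_NKG2D
GRANZB = CD8_NKG2D | NK | NK_NKG2D | (DC & !(LPS | PGN))

# -- output node --------------------------------------------------------
MMPs = (MACR & TNFa) | (FIBROBLAST & (IL21 | IL17 | IL1b | TNFa))
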