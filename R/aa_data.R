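# Amino-acid chemistry tables used by the microenvironment descriptors and
# by the toy-structure generator. Names follow PDB atom-name conventions.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# Partition of the 20 standard residues into six physicochemical classes.
AA_CLASS <- c(
  ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
  ILE = "hydrophobic", MET = "hydrophobic",
  PHE = "aromatic", TYR = "aromatic", TRP = "aromatic", HIS = "aromatic",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
  LYS = "positive", ARG = "positive",
  ASP = "negative", GLU = "negative",
  GLY = "special", PRO = "special", CYS = "special"
)

AA_CLASSES <- c("hydrophobic", "aromatic", "polar", "positive", "negative",
                "special")

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5, GLN = -3.5,
  GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5, LEU = 3.8, LYS = -3.9,
  MET = 1.9, PHE = 2.8, PRO = -1.6, SER = -0.8, THR = -0.7, TRP = -0.9,
  TYR = -1.3, VAL = 4.2
)

# Side-chain heavy atoms (name = element), in the usual build order.
SIDECHAIN_ATOMS <- list(
  ALA = c(CB = "C"),
  ARG = c(CB = "C", CG = "C", CD = "C", NE = "N", CZ = "C",
          NH1 = "N", NH2 = "N"),
  ASN = c(CB = "C", CG = "C", OD1 = "O", ND2 = "N"),
  ASP = c(CB = "C", CG = "C", OD1 = "O", OD2 = "O"),
  CYS = c(CB = "C", SG = "S"),
  GLN = c(CB = "C", CG = "C", CD = "C", OE1 = "O", NE2 = "N"),
  GLU = c(CB = "C", CG = "C", CD = "C", OE1 = "O", OE2 = "O"),
  GLY = character(0),
  HIS = c(CB = "C", CG = "C", ND1 = "N", CD2 = "C", CE1 = "C", NE2 = "N"),
  ILE = c(CB = "C", CG1 = "C", CG2 = "C", CD1 = "C"),
  LEU = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C"),
  LYS = c(CB = "C", CG = "C", CD = "C", CE = "C", NZ = "N"),
  MET = c(CB = "C", CG = "C", SD = "S", CE = "C"),
  PHE = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C",
          CZ = "C"),
  PRO = c(CB = "C", CG = "C", CD = "C"),
  SER = c(CB = "C", OG = "O"),
  THR = c(CB = "C", OG1 = "O", CG2 = "C"),
  TRP = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", NE1 = "N", CE2 = "C",
          CE3 = "C", CZ2 = "C", CZ3 = "C", CH2 = "C"),
  TYR = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", CE1 = "C", CE2 = "C",
          CZ = "C", OH = "O"),
  VAL = c(CB = "C", CG1 = "C", CG2 = "C")
)

BACKBONE_ATOMS <- c(N = "N", CA = "C", C = "C", O = "O")

# Side-chain hydrogen-bond donor / acceptor heavy atoms; backbone N is a
# donor and backbone O an acceptor for every residue.
HBD_SIDECHAIN <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1",
  HIS = c("ND1", "NE2"), CYS = "SG"
)
HBA_SIDECHAIN <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

# Atoms of formally charged side-chain groups at physiological pH.
POS_GROUP_ATOMS <- list(
  LYS = "NZ", ARG = c("NE", "CZ", "NH1", "NH2")
)
NEG_GROUP_ATOMS <- list(
  ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2")
)

# Aromatic ring heavy atoms.
AROMATIC_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
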