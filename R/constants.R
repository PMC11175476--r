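# Internal data constants: amino-acid residue templates, descriptor
# contribution tables and property scales. Generated once from standard
# sources (wwPDB atom nomenclature; Wildman & Crippen 1999 atomic logP
# contributions; Ertl 2000 TPSA fragment contributions) and frozen.
# Contribution values are stored as per-residue sums for the three backbone
# contexts a residue can occupy in a linear peptide: free N-terminus,
# internal (both backbone bonds formed), free C-terminus.

.AA_CODES <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

.ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

.CRIPPEN_CTX <- matrix(c(
  -0.5905, -0.4953, -0.4866,
  -0.6806, -0.5854, -0.5767,
  -1.1357, -1.0405, -1.0318,
  -0.7456, -0.6504, -0.6417,
  0.6323, 0.7275, 0.7362,
  -0.979, -0.8838, -0.8751,
  -0.6446, -0.5494, -0.5407,
  0.4357, 0.5309, 0.5396,
  -0.4814, -0.3862, -0.3775,
  0.4357, 0.5309, 0.5396,
  0.1427, 0.2379, 0.2466,
  -1.735, -1.6398, -1.6311,
  -0.1857, -0.009, -0.0003,
  -1.3449, -1.2497, -1.241,
  -1.34713, -1.25193, -1.24323,
  -1.6181, -1.5229, -1.5142,
  -1.2296, -1.1344, -1.1257,
  0.0456, 0.1408, 0.1495,
  1.1136, 1.2088, 1.2175,
  0.3379, 0.4331, 0.4418
), ncol = 3, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), c("nterm", "internal", "cterm")))

.TPSA_CTX <- matrix(c(
  43.09, 29.1, 49.33,
  43.09, 29.1, 49.33,
  80.39, 66.4, 86.63,
  80.39, 66.4, 86.63,
  43.09, 29.1, 49.33,
  43.09, 29.1, 49.33,
  71.77, 57.78, 78.01,
  43.09, 29.1, 49.33,
  69.11, 55.12, 75.35,
  43.09, 29.1, 49.33,
  43.09, 29.1, 49.33,
  86.18, 72.19, 92.42,
  29.1, 20.31, 40.54,
  86.18, 72.19, 92.42,
  104.99, 91.0, 111.23,
  63.32, 49.33, 69.56,
  63.32, 49.33, 69.56,
  43.09, 29.1, 49.33,
  58.88, 44.89, 65.12,
  63.32, 49.33, 69.56
), ncol = 3, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), c("nterm", "internal", "cterm")))

# Per-residue heavy-atom templates in internal (mid-chain) context.
# Backbone termini are adjusted at graph-build time (N gains one H at the
# N-terminus; OXT with one H is appended at the C-terminus).
.AA_TEMPLATES <- list(
  A = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      nH = c(1, 1, 0, 0, 3),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA"),
      to = c("CA", "C", "O", "CB"),
      order = c("1", "1", "2", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE))),
  C = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "SG"),
      element = c("N", "C", "C", "O", "C", "S"),
      nH = c(1, 1, 0, 0, 2, 1),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB"),
      to = c("CA", "C", "O", "CB", "SG"),
      order = c("1", "1", "2", "1", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE))),
  D = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
      element = c("N", "C", "C", "O", "C", "C", "O", "O"),
      nH = c(1, 1, 0, 0, 2, 0, 0, 1),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CG"),
      to = c("CA", "C", "O", "CB", "CG", "OD1", "OD2"),
      order = c("1", "1", "2", "1", "1", "2", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  E = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
      element = c("N", "C", "C", "O", "C", "C", "C", "O", "O"),
      nH = c(1, 1, 0, 0, 2, 2, 0, 0, 1),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CD", "CD"),
      to = c("CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
      order = c("1", "1", "2", "1", "1", "1", "2", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  F = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      element = c("N", "C", "C", "O", "C", "C", "C", "C", "C", "C", "C"),
      nH = c(1, 1, 0, 0, 2, 0, 1, 1, 1, 1, 1),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP2", "SP2", "SP2", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      to = c("CA", "C", "O", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG"),
      order = c("1", "1", "2", "1", "1", "AR", "AR", "AR", "AR", "AR", "AR"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))),
  G = list(
    atoms = data.frame(name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      nH = c(1, 2, 0, 0),
      aromatic = c(FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C"),
      to = c("CA", "C", "O"),
      order = c("1", "1", "2"),
      ring = c(FALSE, FALSE, FALSE))),
  H = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
      element = c("N", "C", "C", "O", "C", "C", "N", "C", "C", "N"),
      nH = c(1, 1, 0, 0, 2, 0, 0, 1, 1, 1),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP2", "SP2", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "ND1", "CE1", "NE2", "CD2"),
      to = c("CA", "C", "O", "CB", "CG", "ND1", "CE1", "NE2", "CD2", "CG"),
      order = c("1", "1", "2", "1", "1", "AR", "AR", "AR", "AR", "AR"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))),
  I = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
      element = c("N", "C", "C", "O", "C", "C", "C", "C"),
      nH = c(1, 1, 0, 0, 1, 3, 2, 3),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP3", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CB", "CG2"),
      to = c("CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
      order = c("1", "1", "2", "1", "1", "1", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  K = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
      element = c("N", "C", "C", "O", "C", "C", "C", "C", "N"),
      nH = c(1, 1, 0, 0, 2, 2, 2, 2, 2),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP3", "SP3", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CD", "CE"),
      to = c("CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
      order = c("1", "1", "2", "1", "1", "1", "1", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  L = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
      element = c("N", "C", "C", "O", "C", "C", "C", "C"),
      nH = c(1, 1, 0, 0, 2, 1, 3, 3),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP3", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CG"),
      to = c("CA", "C", "O", "CB", "CG", "CD1", "CD2"),
      order = c("1", "1", "2", "1", "1", "1", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  M = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
      element = c("N", "C", "C", "O", "C", "C", "S", "C"),
      nH = c(1, 1, 0, 0, 2, 2, 0, 3),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP3", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "SD"),
      to = c("CA", "C", "O", "CB", "CG", "SD", "CE"),
      order = c("1", "1", "2", "1", "1", "1", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  N = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
      element = c("N", "C", "C", "O", "C", "C", "O", "N"),
      nH = c(1, 1, 0, 0, 2, 0, 0, 2),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CG"),
      to = c("CA", "C", "O", "CB", "CG", "OD1", "ND2"),
      order = c("1", "1", "2", "1", "1", "2", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  P = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD"),
      element = c("N", "C", "C", "O", "C", "C", "C"),
      nH = c(0, 1, 0, 0, 2, 2, 2),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP3"),
      ring = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CD"),
      to = c("CA", "C", "O", "CB", "CG", "CD", "N"),
      order = c("1", "1", "2", "1", "1", "1", "1"),
      ring = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))),
  Q = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
      element = c("N", "C", "C", "O", "C", "C", "C", "O", "N"),
      nH = c(1, 1, 0, 0, 2, 2, 0, 0, 2),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CD", "CD"),
      to = c("CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
      order = c("1", "1", "2", "1", "1", "1", "2", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  R = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
      element = c("N", "C", "C", "O", "C", "C", "C", "N", "C", "N", "N"),
      nH = c(1, 1, 0, 0, 2, 2, 2, 1, 0, 1, 2),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP3", "SP2", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CD", "NE", "CZ", "CZ"),
      to = c("CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
      order = c("1", "1", "2", "1", "1", "1", "1", "1", "2", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  S = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "OG"),
      element = c("N", "C", "C", "O", "C", "O"),
      nH = c(1, 1, 0, 0, 2, 1),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB"),
      to = c("CA", "C", "O", "CB", "OG"),
      order = c("1", "1", "2", "1", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE))),
  T = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
      element = c("N", "C", "C", "O", "C", "O", "C"),
      nH = c(1, 1, 0, 0, 1, 1, 3),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CB"),
      to = c("CA", "C", "O", "CB", "OG1", "CG2"),
      order = c("1", "1", "2", "1", "1", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  V = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
      element = c("N", "C", "C", "O", "C", "C", "C"),
      nH = c(1, 1, 0, 0, 1, 3, 3),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP3", "SP3"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CB"),
      to = c("CA", "C", "O", "CB", "CG1", "CG2"),
      order = c("1", "1", "2", "1", "1", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))),
  W = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
      element = c("N", "C", "C", "O", "C", "C", "C", "C", "N", "C", "C", "C", "C", "C"),
      nH = c(1, 1, 0, 0, 2, 0, 1, 0, 1, 0, 1, 1, 1, 1),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP2", "SP2", "SP2", "SP2", "SP2", "SP2", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CG", "CD1", "CD2", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3"),
      to = c("CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CE2", "CZ2", "CZ3", "CH2", "CH2"),
      order = c("1", "1", "2", "1", "1", "AR", "AR", "AR", "AR", "AR", "AR", "AR", "AR", "AR", "AR"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))),
  Y = list(
    atoms = data.frame(name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
      element = c("N", "C", "C", "O", "C", "C", "C", "C", "C", "C", "C", "O"),
      nH = c(1, 1, 0, 0, 2, 0, 1, 1, 1, 1, 0, 1),
      aromatic = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
      hyb = c("SP2", "SP3", "SP2", "SP2", "SP3", "SP2", "SP2", "SP2", "SP2", "SP2", "SP2", "SP2"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    bonds = data.frame(from = c("N", "CA", "C", "CA", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CZ"),
      to = c("CA", "C", "O", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2", "CG", "OH"),
      order = c("1", "1", "2", "1", "1", "AR", "AR", "AR", "AR", "AR", "AR", "1"),
      ring = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)))
)

# Eisenberg consensus hydrophobicity scale (Eisenberg, Schwarz, Komaromy &
# Wall 1984). Positive = hydrophobic.
.EISENBERG <- c(
  A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
  Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
  L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
  S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08
)

# Classical property scales used by type-1 pseudo amino-acid composition:
# hydrophobicity (Eisenberg consensus), hydrophilicity (Hopp & Woods 1981)
# and side-chain mass (Da). Standardised to zero mean / unit population SD
# over the 20 residues before use.
.PSEAAC_SCALES <- list(
  hydrophobicity = c(
    A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
    Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
    L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
    S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08),
  hydrophilicity = c(
    A = -0.5, R =  3.0, N =  0.2, D =  3.0, C = -1.0,
    Q =  0.2, E =  3.0, G =  0.0, H = -0.5, I = -1.8,
    L = -1.8, K =  3.0, M = -1.3, F = -2.5, P =  0.0,
    S =  0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
  sidechain_mass = c(
    A =  15.0, R = 101.0, N =  58.0, D =  59.0, C =  47.0,
    Q =  72.0, E =  73.0, G =   1.0, H =  82.0, I =  57.0,
    L =  57.0, K =  73.0, M =  75.0, F =  91.0, P =  42.0,
    S =  31.0, T =  45.0, W = 130.0, Y = 107.0, V =  43.0)
)

# Default 40-dipeptide catalogue for the dipeptide-composition features.
# The first ten are the uptake-motif pairs singled out for the
# Kendall-selected composition; the remaining thirty are defaults drawn
# from Arg/Lys/Gly/Leu/Ala/Phe/Val/Cys/Gln/Trp pairings and can be
# overridden via feature_config().
.DPC_DEFAULT <- c(
  "GL", "GF", "LG", "GA", "VC", "RK", "RQ", "KR", "KK", "RR",
  "AG", "AL", "AR", "AK", "CV", "CC", "FG", "FL", "FR", "FK",
  "GG", "GR", "GK", "GV", "GW", "LL", "LR", "LK", "LA", "VG",
  "VL", "VV", "QR", "QK", "WR", "WK", "WW", "KG", "KL", "RG"
)

# Three-letter -> one-letter residue codes (standard residues plus common
# modified forms used as a default map for PDB parsing).
.RESIDUE_MAP_DEFAULT <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P"
)

# Whole-molecule contribution sums for free (single-residue) amino acids.
.CRIPPEN_FREE <- c(A = -0.5817999999999999, C = -0.6719000000000002, D = -1.127, E = -0.7369000000000001, F = 0.6409999999999996, G = -0.9702999999999999, H = -0.6359000000000006, I = 0.44439999999999985, K = -0.4726999999999995, L = 0.44439999999999985, M = 0.15140000000000015, N = -1.7262999999999993, P = -0.17700000000000032, Q = -1.336199999999999, R = -1.338429999999999, S = -1.6094000000000002, T = -1.2209, V = 0.05429999999999996, W = 1.1222999999999996, Y = 0.34659999999999935)
.TPSA_FREE <- c(A = 63.32000000000001, C = 63.32000000000001, D = 100.62, E = 100.62, F = 63.32000000000001, G = 63.32000000000001, H = 92.00000000000001, I = 63.32000000000001, K = 89.34, L = 63.32000000000001, M = 63.32000000000001, N = 106.41000000000001, P = 49.33, Q = 106.41000000000001, R = 125.22, S = 83.55000000000001, T = 83.55000000000001, V = 63.32000000000001, W = 79.11, Y = 83.55000000000001)
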