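# Bundled alphabets and physicochemical tables.
#
# All amino-acid vectors are ordered over AA20 = ACDEFGHIKLMNPQRSTVWY.
# Nucleotide tables use the DNA canonical alphabet ACGT; RNA sequences are
# transliterated U->T internally and presented back with U.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA4 <- c("A", "C", "G", "T")
RNA4 <- c("A", "C", "G", "U")

ALPHABETS <- list(
  protein = AA20,
  dna     = DNA4,
  rna     = RNA4
)

# characters rejected by default (permissive mode drops them)
AMBIGUITY <- list(
  protein = c("X", "B", "Z", "U", "J", "O", "*", "-"),
  dna     = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "-"),
  rna     = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "-")
)

aa_vec <- function(...) {
  v <- c(...)
  stats::setNames(v, AA20)
}

# --- PseAAC property triplet -------------------------------------------------
# hydrophobicity / hydrophilicity / side-chain mass, standardized on use
PAAC_HYDROPHOBICITY <- aa_vec(
  0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38, -1.50, 1.06,
  0.64, -0.78, 0.12, -0.85, -2.53, -0.18, -0.05, 1.08, 0.81, 0.26)
PAAC_HYDROPHILICITY <- aa_vec(
  -0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
  -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3)
PAAC_SIDECHAIN_MASS <- aa_vec(
  15, 47, 59, 73, 91, 1, 82, 57, 73, 57,
  75, 58, 42, 72, 101, 31, 45, 43, 130, 107)

# --- Grantham component tables (composition, polarity, volume) --------------
GRANTHAM_C <- aa_vec(
  0, 2.75, 1.38, 0.92, 0, 0.74, 0.58, 0, 0.33, 0,
  0, 1.33, 0.39, 0.89, 0.65, 1.42, 0.71, 0, 0.13, 0.20)
GRANTHAM_P <- aa_vec(
  8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
  5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2)
GRANTHAM_V <- aa_vec(
  31, 55, 54, 83, 132, 3, 96, 111, 119, 111,
  105, 56, 32.5, 85, 124, 32, 61, 84, 170, 136)

# Grantham distance matrix from component differences, scaled to mean 100
grantham_matrix <- function() {
  a <- 1.833; b <- 0.1018; g <- 0.000399
  d2 <- outer(GRANTHAM_C, GRANTHAM_C, "-")^2 * a +
    outer(GRANTHAM_P, GRANTHAM_P, "-")^2 * b +
    outer(GRANTHAM_V, GRANTHAM_V, "-")^2 * g
  d <- sqrt(d2)
  off <- d[upper.tri(d)]
  d * (100 / mean(off))
}

# Physicochemical Euclidean distance over standardized hydrophobicity,
# hydrophilicity and side-chain mass (second sequence-order metric).
physchem_matrix <- function() {
  m <- cbind(PAAC_HYDROPHOBICITY, PAAC_HYDROPHILICITY, PAAC_SIDECHAIN_MASS)
  m <- scale(m)  # population-irrelevant: used only pairwise
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(AA20, AA20)
  d / max(d)
}

# --- AAindex-style property subset (8 indices) -------------------------------
AAINDEX_SUBSET <- local({
  tab <- rbind(
    hydropathy = aa_vec(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
                        1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3),
    hydrophilicity = PAAC_HYDROPHILICITY,
    sidechain_mass = PAAC_SIDECHAIN_MASS,
    polarity = GRANTHAM_P,
    volume = GRANTHAM_V,
    isoelectric = aa_vec(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02, 9.74, 5.98,
                         5.74, 5.41, 6.30, 5.65, 10.76, 5.68, 5.60, 5.96, 5.89, 5.66),
    bulkiness = aa_vec(11.50, 13.46, 11.68, 13.57, 19.80, 3.40, 13.69, 21.40, 15.71, 21.40,
                       16.25, 12.82, 17.43, 14.45, 14.28, 9.47, 15.77, 21.57, 21.67, 18.03),
    polarizability = aa_vec(0.046, 0.128, 0.105, 0.151, 0.290, 0.000, 0.230, 0.186, 0.219, 0.186,
                            0.221, 0.134, 0.131, 0.180, 0.291, 0.062, 0.108, 0.140, 0.409, 0.298)
  )
  colnames(tab) <- AA20
  tab
})

# standardize a property vector to mean 0 / population sd 1 over the 20 AAs
standardize_property <- function(p) {
  mu <- mean(p)
  sdev <- sqrt(mean((p - mu)^2))
  if (sdev == 0) return(p * 0)
  (p - mu) / sdev
}

# --- Z-scales (Sandberg 5-descriptor set) ------------------------------------
ZSCALE <- local({
  m <- matrix(c(
    0.24, -2.32, 0.60, -0.14, 1.30,    # A
    0.84, -1.67, 3.71, 0.18, -2.65,    # C
    3.98, 0.93, 1.93, -2.46, 0.75,     # D
    3.11, 0.26, -0.11, -3.04, -0.25,   # E
    -4.22, 1.94, 1.06, 0.54, -0.62,    # F
    2.05, -4.06, 0.36, -0.82, -0.38,   # G
    2.47, 1.95, 0.26, 3.90, 0.09,      # H
    -3.89, -1.73, -1.71, -0.84, 0.26,  # I
    2.29, 0.89, -2.49, 1.49, 0.31,     # K
    -4.28, -1.30, -1.49, -0.72, 0.84,  # L
    -2.85, -0.22, 0.47, 1.94, -0.98,   # M
    3.05, 1.62, 1.04, -1.15, 1.61,     # N
    -1.66, 0.27, 1.84, 0.70, 2.00,     # P
    1.75, 0.50, -1.44, -1.34, 0.66,    # Q
    3.52, 2.50, -3.50, 1.99, -0.17,    # R
    2.39, -1.07, 1.15, -1.39, 0.67,    # S
    0.75, -2.18, -1.12, -1.46, -0.40,  # T
    -2.59, -2.64, -1.54, -0.85, -0.02, # V
    -4.36, 3.94, 0.59, 3.44, -1.59,    # W
    -2.54, 2.44, 0.43, 0.04, -1.47     # Y
  ), nrow = 20, byrow = TRUE)
  dimnames(m) <- list(AA20, paste0("z", 1:5))
  m
})

# AESNN3: derived 3-d embedding (first three PCs of the standardized Z-scales)
AESNN3 <- local({
  p <- stats::prcomp(ZSCALE, center = TRUE, scale. = TRUE)
  m <- p$x[, 1:3]
  colnames(m) <- paste0("e", 1:3)
  round(m, 4)
})

# --- CTD: 7 properties x 3 groups --------------------------------------------
CTD_GROUPS <- list(
  hydrophobicity = list(g1 = "RKEDQN",   g2 = "GASTPHY", g3 = "CLVIMFW"),
  vdw_volume     = list(g1 = "GASTPDC",  g2 = "NVEQIL",  g3 = "MHKFRYW"),
  polarity       = list(g1 = "LIFWCMVY", g2 = "PATGS",   g3 = "HQRKNED"),
  polarizability = list(g1 = "GASDT",    g2 = "CPNVEQIL", g3 = "KMHFRYW"),
  charge         = list(g1 = "KR",       g2 = "ANCQGHILMFPSTWYV", g3 = "DE"),
  secondary_struct = list(g1 = "EALMQKRH", g2 = "VIYCWFT", g3 = "GNPSD"),
  solvent_access   = list(g1 = "ALFCGIVW", g2 = "RKQEND",  g3 = "MSPTHY")
)

# --- five physicochemical groups (grouped composition, shell GAAC) ----------
AA_GROUPS5 <- list(
  aliphatic = strsplit("GAVLMI", "")[[1]],
  aromatic  = strsplit("FYW", "")[[1]],
  positive  = strsplit("KRH", "")[[1]],
  negative  = strsplit("DE", "")[[1]],
  uncharged = strsplit("STCPNQ", "")[[1]]
)

aa_group5_of <- local({
  v <- character(0)
  for (g in names(AA_GROUPS5)) v[AA_GROUPS5[[g]]] <- g
  v[AA20]
})

# conjoint triad classes (CTriad)
CTRIAD_CLASSES <- list(
  c1 = c("A", "G", "V"), c2 = c("I", "L", "F", "P"), c3 = c("Y", "M", "T", "S"),
  c4 = c("H", "N", "Q", "W"), c5 = c("R", "K"), c6 = c("D", "E"), c7 = c("C")
)

# Dayhoff-style 6 classes for the 6-bit encoding
AA_GROUPS6 <- list(
  basic = c("H", "R", "K"), acidamide = c("D", "E", "N", "Q"), cys = "C",
  small = c("S", "T", "P", "A", "G"), aliphatic = c("M", "I", "L", "V"),
  aromatic = c("F", "Y", "W")
)

# Overlapping property flags (10-bit): Taylor-style classes
OPF10 <- list(
  hydrophobic = strsplit("ACFGHIKLMTVWY", "")[[1]],
  polar       = strsplit("CDEHKNQRSTWY", "")[[1]],
  small       = strsplit("ACDGNPSTV", "")[[1]],
  tiny        = strsplit("AGS", "")[[1]],
  aliphatic   = strsplit("ILV", "")[[1]],
  aromatic    = strsplit("FHWY", "")[[1]],
  positive    = strsplit("HKR", "")[[1]],
  negative    = strsplit("DE", "")[[1]],
  charged     = strsplit("DEHKR", "")[[1]],
  proline     = "P"
)

# DDE codon multiplicities (standard genetic code, 61 sense codons)
AA_CODON_COUNT <- aa_vec(4, 2, 2, 2, 2, 4, 2, 3, 2, 6, 1, 2, 4, 2, 6, 6, 4, 4, 1, 2)

# --- nucleotide tables -------------------------------------------------------
# electron-ion interaction pseudopotential constants
EIIP <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)

# nucleotide chemical property code: (ring structure, functional group, H-bond)
NCP_CODE <- rbind(A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0), T = c(0, 0, 1))

all_kmers <- function(k, alphabet = DNA4) {
  if (k == 1) return(alphabet)
  g <- do.call(expand.grid, rev(replicate(k, alphabet, simplify = FALSE)))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste0, collapse = "")
}

# Representative B-DNA dinucleotide step parameters; order AA..TT lexicographic.
DNA_DI_PROPS <- local({
  dn <- all_kmers(2)
  m <- rbind(
    twist = c(38.90, 31.12, 32.15, 33.81, 41.41, 34.96, 32.91, 32.15,
              41.31, 38.50, 34.96, 31.12, 33.28, 41.31, 41.41, 38.90),
    tilt  = c(-1.84, -0.64, -1.48, 0.00, 1.52, 0.05, 0.00, 1.48,
              -1.44, 0.00, -0.05, 0.64, 0.00, 1.44, -1.52, 1.84),
    roll  = c(0.76, 2.87, 2.46, 7.13, 2.23, 1.24, 4.96, 2.46,
              1.61, 0.12, 1.24, 2.87, 4.46, 1.61, 2.23, 0.76),
    shift = c(0.06, 0.12, 0.02, 0.00, 0.02, 0.05, 0.00, -0.02,
              -0.02, 0.00, -0.05, -0.12, 0.00, 0.02, -0.02, -0.06),
    slide = c(-0.17, -0.15, -0.02, -0.60, 0.35, -0.10, 0.32, -0.02,
              -0.02, -0.35, -0.10, -0.15, 0.25, -0.02, 0.35, -0.17),
    rise  = c(3.25, 3.30, 3.32, 3.21, 3.37, 3.36, 3.29, 3.32,
              3.30, 3.27, 3.36, 3.30, 3.39, 3.30, 3.37, 3.25)
  )
  colnames(m) <- dn
  m
})

# Representative A-RNA dinucleotide step parameters (same property names).
RNA_DI_PROPS <- local({
  dn <- all_kmers(2)
  m <- rbind(
    twist = c(31.0, 32.0, 30.0, 33.0, 31.0, 32.0, 27.0, 30.0,
              32.0, 35.0, 32.0, 32.0, 32.0, 32.0, 31.0, 31.0),
    tilt  = c(-0.8, 0.8, 0.5, 1.1, 1.0, 0.3, -0.1, 0.5,
              1.3, 0.0, 0.3, 0.8, -0.2, 1.3, 1.0, -0.8),
    roll  = c(7.0, 4.8, 8.5, 7.1, 9.9, 8.7, 12.1, 8.5,
              9.4, 6.1, 8.7, 4.8, 10.7, 9.4, 9.9, 7.0),
    shift = c(-0.08, 0.23, -0.04, -0.06, 0.11, -0.01, 0.30, -0.04,
              0.07, -0.39, -0.01, 0.23, -0.01, 0.07, 0.11, -0.08),
    slide = c(-1.27, -1.43, -1.50, -1.36, -1.46, -1.78, -1.89, -1.50,
              -1.70, -1.39, -1.78, -1.43, -1.45, -1.70, -1.46, -1.27),
    rise  = c(3.18, 3.24, 3.30, 3.24, 3.09, 3.32, 3.30, 3.30,
              3.38, 3.22, 3.32, 3.24, 3.26, 3.38, 3.09, 3.18)
  )
  colnames(m) <- dn
  m
})

# Derived trinucleotide table: mean of the two constituent dinucleotide steps.
tri_props_from_di <- function(di) {
  tri <- all_kmers(3)
  m <- sapply(tri, function(t) {
    (di[, substr(t, 1, 2)] + di[, substr(t, 2, 3)]) / 2
  })
  colnames(m) <- tri
  m
}
DNA_TRI_PROPS <- tri_props_from_di(DNA_DI_PROPS)

nuc_prop_table <- function(kind, order) {
  if (order == 2) {
    if (kind == "rna") RNA_DI_PROPS else DNA_DI_PROPS
  } else {
    if (kind == "rna") tri_props_from_di(RNA_DI_PROPS) else DNA_TRI_PROPS
  }
}

# standardized property table (per row mean 0 / population sd 1)
std_prop_table <- function(tab) {
  t(apply(tab, 1, standardize_property))
}

# --- PseKRAAC reduction families ---------------------------------------------
# 16 deterministic reduction schemes: 8 physicochemical orderings x 2 split
# rules (equal-size blocks vs largest-gap splits). Cluster counts supported:
# 2,3,4,5,8,10,15,20 (20 = identity reduction for every scheme).
PSEKRAAC_ORDERINGS <- local({
  props <- list(
    AAINDEX_SUBSET["hydropathy", ], AAINDEX_SUBSET["hydrophilicity", ],
    AAINDEX_SUBSET["sidechain_mass", ], AAINDEX_SUBSET["polarity", ],
    AAINDEX_SUBSET["volume", ], AAINDEX_SUBSET["isoelectric", ],
    AAINDEX_SUBSET["bulkiness", ], AAINDEX_SUBSET["polarizability", ]
  )
  lapply(props, function(p) AA20[order(p, AA20)])
})
PSEKRAAC_SCHEMES <- paste0("type", 1:16)
# families 3 and 6 carry lettered sub-variants (different orderings)
PSEKRAAC_VARIANTS <- c("type1", "type2", "type3A", "type3B", "type4", "type5",
                       "type6A", "type6B", "type6C", paste0("type", 7:16))
PSEKRAAC_SIZES <- c(2, 3, 4, 5, 8, 10, 15, 20)

psekraac_mapping <- function(scheme, cluster_count) {
  if (!scheme %in% PSEKRAAC_VARIANTS) stop("unknown PseKRAAC scheme ", scheme)
  if (!cluster_count %in% PSEKRAAC_SIZES) {
    stop("unsupported cluster count ", cluster_count, " for ", scheme)
  }
  idx <- as.integer(sub("^type([0-9]+).*$", "\\1", scheme))
  letter <- sub("^type[0-9]+", "", scheme)
  offset <- match(letter, c("A", "B", "C"), nomatch = 1L) - 1L
  ord <- PSEKRAAC_ORDERINGS[[(idx - 1L + offset) %% 8L + 1L]]
  if (cluster_count == 20) {
    groups <- seq_len(20) - 1L
  } else if (idx <= 8) {
    # equal-size contiguous blocks along the ordering
    groups <- floor((seq_len(20) - 1L) * cluster_count / 20)
  } else {
    # split at the largest property gaps along the ordering
    p <- AAINDEX_SUBSET[(idx - 1L + offset) %% 8L + 1L, ord]
    gaps <- diff(p)
    cut_at <- sort(order(gaps, decreasing = TRUE)[seq_len(cluster_count - 1L)])
    groups <- findInterval(seq_len(20), c(1L, cut_at + 1L)) - 1L
  }
  stats::setNames(groups, ord)[AA20]
}

# --- van der Waals radii / atomic properties (ligand + structure) -----------
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10)

ATOMIC_PROPS <- local({
  el <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
  data.frame(
    element = el,
    mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 28.085, 30.974,
             32.06, 35.45, 79.904, 126.904),
    electronegativity = c(2.20, 2.04, 2.55, 3.04, 3.44, 3.98, 1.90, 2.19,
                          2.58, 3.16, 2.96, 2.66),
    vdw_volume = 4 / 3 * pi * VDW_RADII[el]^3,
    polarizability = c(0.667, 3.03, 1.76, 1.10, 0.802, 0.557, 5.38, 3.63,
                       2.90, 2.18, 3.05, 5.35),
    default_valence = c(1, 3, 4, 3, 2, 1, 4, 3, 2, 1, 1, 1),
    row.names = el
  )
})

# pharmacophore SMARTS definitions (bundled data)
PHARMACOPHORE_SMARTS <- c(
  donor      = "[#7,#8;!H0]",
  acceptor   = "[#7,#8;!$([#7H3]);!$([#8H2])]",
  aromatic   = "a",
  hydrophobe = "[C;!$(C=[O,N,S]);!$(C#N)]",
  positive   = "[+,#7H2;!$([-])]",
  negative   = "[-,$([#8H1]C=O)]"
)
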