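# Descriptor manifest: the pinned roster of named descriptor sets per
# molecule kind (71 protein + 49 DNA + 37 RNA + 14 structure + 18 ligand
# = 189), plus the analysis-algorithm and plot-kind registries.

reg_entry <- function(name, kind, category) {
  tibble::tibble(name = name, kind = kind, category = category)
}

protein_roster <- function() {
  dplyr::bind_rows(
    reg_entry(c("AAC", "EAAC", "CKSAAP type 1", "CKSAAP type 2",
                "DPC type 1", "DPC type 2", "DDE", "TPC type 1", "TPC type 2",
                "CTDC", "CTDT", "CTDD", "CTriad type 1", "CTriad type 2",
                "KSCTriad type 1", "KSCTriad type 2", "ASDC"),
              "protein", "composition"),
    reg_entry(c("GAAC", "EGAAC", "CKSAAGP", "GDPC", "GTPC"),
              "protein", "grouped composition"),
    reg_entry(c("Moran", "Geary", "NMBroto", "AC", "CC", "ACC"),
              "protein", "autocorrelation"),
    reg_entry(c("SOCNumber", "QSOrder"), "protein", "sequence order"),
    reg_entry(c("PAAC", "APAAC"), "protein", "pseudo composition"),
    reg_entry(c("binary", "binary_6bit", "binary_5bit type 1",
                "binary_5bit type 2", paste0("binary_3bit type ", 1:7),
                "AESNN3", "OPF_10bit", paste0("OPF_7bit type ", 1:3),
                "ZScale", "BLOSUM62", "AAIndex"),
              "protein", "residue encoding"),
    reg_entry("KNN", "protein", "similarity"),
    reg_entry(paste0("PseKRAAC ", PSEKRAAC_VARIANTS),
              "protein", "reduced alphabet")
  )
}

nuc_shared_roster <- function(kind) {
  dplyr::bind_rows(
    reg_entry(c("Kmer", "RCKmer", "Mismatch", "Subsequence", "NAC", "DNC",
                "TNC", "ENAC", "CKSNAP"), kind, "composition"),
    reg_entry(c("ANF", "NCP", "DBE", "binary", "PS2", "PS3", "PS4"),
              kind, "position encoding"),
    reg_entry(c("EIIP", "PseEIIP"), kind, "electron-ion"),
    reg_entry(paste0("Z_curve_", c("9bit", "12bit", "36bit", "48bit", "144bit")),
              kind, "Z-curve"),
    reg_entry(c("Moran", "Geary", "NMBroto", "DAC", "DCC", "DACC"),
              kind, "autocorrelation"),
    reg_entry("MMI", kind, "mutual information"),
    reg_entry(c("PseDNC", "PseKNC", "PC-PseDNC", "SC-PseDNC"),
              kind, "pseudo composition"),
    reg_entry("KNN", kind, "similarity"),
    reg_entry(c("DPCP", "DPCP type 2"), kind, "physicochemical composition")
  )
}

dna_roster <- function() {
  dplyr::bind_rows(
    nuc_shared_roster("dna"),
    reg_entry(c("TAC", "TCC", "TACC"), "dna", "autocorrelation"),
    reg_entry(c("TPCP", "TPCP type 2"), "dna", "physicochemical composition"),
    reg_entry(c("PC-PseTNC", "SC-PseTNC"), "dna", "pseudo composition"),
    reg_entry(c("PSTNPss", "PSTNPds"), "dna", "position-specific propensity"),
    reg_entry(c("CKSNAP type 2", "Kmer type 2", "RCKmer type 2"),
              "dna", "composition")
  )
}

structure_roster <- function() {
  reg_entry(STRUCTURE_DESCRIPTORS, "structure",
            c(rep("shell composition", 4), rep("secondary-structure shell", 4),
              rep("half-sphere exposure", 2), "residue depth",
              rep("atom-composition shell", 2), "network index"))
}

ligand_roster <- function() {
  dplyr::bind_rows(
    reg_entry(LIGAND_BLOCKS, "ligand", "descriptor block"),
    reg_entry(LIGAND_FP_FAMILIES, "ligand", "fingerprint")
  )
}

#' List registered descriptor sets
#'
#' @param kind optional filter: `protein`, `dna`, `rna`, `structure` or
#'   `ligand`.
#' @return tibble with columns `name`, `kind`, `category`, in a fixed order.
#' @export
list_descriptors <- function(kind = NULL) {
  reg <- dplyr::bind_rows(protein_roster(), dna_roster(), nuc_shared_roster("rna"),
                          structure_roster(), ligand_roster())
  if (!is.null(kind)) {
    if (!kind %in% c("protein", "dna", "rna", "structure", "ligand")) {
      stop("unknown kind: ", kind)
    }
    reg <- reg[reg$kind == kind, , drop = FALSE]
  }
  reg
}

#' Registered feature-analysis algorithms
#' @return tibble with columns `name`, `type` (cluster / reduction /
#'   normalization).
#' @export
list_analysis_algorithms <- function() {
  dplyr::bind_rows(
    tibble::tibble(name = c("kmeans", "minibatch_kmeans", "gaussian_mixture",
                            "hierarchical_agglomerative", "spectral",
                            "markov_clustering", "hclust_tree_cut",
                            "affinity_propagation", "mean_shift", "dbscan"),
                   type = "cluster"),
    tibble::tibble(name = c("pca", "tsne", "lda"), type = "reduction"),
    tibble::tibble(name = c("zscore", "minmax"), type = "normalization")
  )
}

#' Registered plot kinds
#' @export
list_plot_kinds <- function() {
  c("histogram", "kde", "heatmap", "boxplot", "line", "scatter",
    "circular", "structure3d", "ligand2d")
}

#' Supported feature export formats
#' @export
list_export_formats <- function() c("csv", "tsv", "svm_light", "arff")

# --- sequence descriptor dispatch --------------------------------------------
seq_descriptor_matrix <- function(seqs, descriptor, ...) {
  kind <- seq_kind(seqs)
  known <- list_descriptors(kind)$name
  if (!descriptor %in% known) {
    stop("descriptor '", descriptor, "' is not registered for kind ", kind)
  }
  if (kind == "protein") {
    protein_descriptor_matrix(seqs, descriptor, ...)
  } else {
    nucleic_descriptor_matrix(seqs, descriptor, ...)
  }
}

protein_descriptor_matrix <- function(seqs, descriptor, ...) {
  if (startsWith(descriptor, "PseKRAAC")) {
    scheme <- sub("^PseKRAAC ", "", descriptor)
    return(pf_psekraac(seqs, scheme = scheme, ...))
  }
  if (startsWith(descriptor, "binary_3bit")) {
    return(pf_binary_3bit(seqs, type = as.integer(sub(".*type ", "", descriptor)), ...))
  }
  if (startsWith(descriptor, "OPF_7bit")) {
    return(pf_opf_7bit(seqs, type = as.integer(sub(".*type ", "", descriptor)), ...))
  }
  t2 <- endsWith(descriptor, "type 2")
  base <- sub(" type [12]$", "", descriptor)
  tag_t2 <- function(m) {
    # count variants share the formula prefix; tag them so batch runs
    # produce unique column names
    if (t2 && !base %in% c("binary_5bit")) {
      colnames(m) <- sub("^([A-Za-z0-9]+)\\.", "\\1.t2.", colnames(m))
    }
    m
  }
  tag_t2(switch(base,
    AAC = pf_aac(seqs, ...),
    EAAC = pf_eaac(seqs, ...),
    CKSAAP = pf_cksaap(seqs, type = if (t2) 2 else 1, ...),
    DPC = pf_dpc(seqs, type = if (t2) 2 else 1, ...),
    DDE = pf_dde(seqs, ...),
    TPC = pf_tpc(seqs, type = if (t2) 2 else 1, ...),
    CTDC = pf_ctdc(seqs, ...), CTDT = pf_ctdt(seqs, ...),
    CTDD = pf_ctdd(seqs, ...),
    CTriad = pf_ctriad(seqs, type = if (t2) 2 else 1, ...),
    KSCTriad = pf_ksctriad(seqs, type = if (t2) 2 else 1, ...),
    ASDC = pf_asdc(seqs, ...),
    GAAC = pf_gaac(seqs, ...), EGAAC = pf_egaac(seqs, ...),
    CKSAAGP = pf_cksaagp(seqs, ...), GDPC = pf_gdpc(seqs, ...),
    GTPC = pf_gtpc(seqs, ...),
    Moran = pf_autocorr(seqs, "Moran", ...),
    Geary = pf_autocorr(seqs, "Geary", ...),
    NMBroto = pf_autocorr(seqs, "NMBroto", ...),
    AC = pf_autocorr(seqs, "AC", ...),
    CC = pf_autocorr(seqs, "CC", ...),
    ACC = pf_autocorr(seqs, "ACC", ...),
    SOCNumber = pf_socnumber(seqs, ...),
    QSOrder = pf_qsorder(seqs, ...),
    PAAC = pf_paac(seqs, ...), APAAC = pf_apaac(seqs, ...),
    binary = pf_binary(seqs, ...),
    binary_6bit = pf_binary_6bit(seqs, ...),
    binary_5bit = pf_binary_5bit(seqs, type = if (t2) 2 else 1, ...),
    AESNN3 = pf_aesnn3(seqs, ...),
    OPF_10bit = pf_opf_10bit(seqs, ...),
    ZScale = pf_zscale(seqs, ...),
    BLOSUM62 = pf_blosum62(seqs, ...),
    AAIndex = pf_aaindex(seqs, ...),
    KNN = pf_knn(seqs, ...),
    stop("unhandled protein descriptor: ", descriptor)
  ))
}

nucleic_descriptor_matrix <- function(seqs, descriptor, ...) {
  t2 <- endsWith(descriptor, "type 2")
  base <- sub(" type 2$", "", descriptor)
  args <- list(...)
  call1 <- function(f, ...) do.call(f, c(list(seqs), list(...), args))
  tag_t2 <- function(m) {
    if (t2) colnames(m) <- sub("^([A-Za-z0-9]+)\\.", "\\1.t2.", colnames(m))
    m
  }
  tag_t2(switch(base,
    Kmer = call1(nf_kmer, type = if (t2) 2 else 1),
    "RCKmer" = call1(nf_rckmer, type = if (t2) 2 else 1),
    Mismatch = call1(nf_mismatch),
    Subsequence = call1(nf_subsequence),
    NAC = nf_kmer(seqs, k = 1),
    DNC = nf_kmer(seqs, k = 2),
    TNC = nf_kmer(seqs, k = 3),
    ENAC = call1(nf_enac),
    CKSNAP = call1(nf_cksnap, type = if (t2) 2 else 1),
    ANF = call1(nf_anf), NCP = call1(nf_ncp), DBE = call1(nf_dbe),
    binary = call1(nf_binary),
    PS2 = nf_ps_k(seqs, 2), PS3 = nf_ps_k(seqs, 3), PS4 = nf_ps_k(seqs, 4),
    EIIP = call1(nf_eiip), PseEIIP = call1(nf_pseeiip),
    Z_curve_9bit = nf_zcurve(seqs, "9bit"),
    Z_curve_12bit = nf_zcurve(seqs, "12bit"),
    Z_curve_36bit = nf_zcurve(seqs, "36bit"),
    Z_curve_48bit = nf_zcurve(seqs, "48bit"),
    Z_curve_144bit = nf_zcurve(seqs, "144bit"),
    Moran = call1(nf_autocorr, variant = "Moran"),
    Geary = call1(nf_autocorr, variant = "Geary"),
    NMBroto = call1(nf_autocorr, variant = "NMBroto"),
    DAC = call1(nf_covariance, variant = "DAC"),
    DCC = call1(nf_covariance, variant = "DCC"),
    DACC = call1(nf_covariance, variant = "DACC"),
    TAC = call1(nf_covariance, variant = "TAC"),
    TCC = call1(nf_covariance, variant = "TCC"),
    TACC = call1(nf_covariance, variant = "TACC"),
    MMI = call1(nf_mmi),
    PseDNC = call1(nf_pseknc, k = 2, label = "PseDNC"),
    PseKNC = call1(nf_pseknc, k = 3, label = "PseKNC"),
    "PC-PseDNC" = call1(nf_pseknc, k = 2, label = "PCPseDNC"),
    "PC-PseTNC" = call1(nf_pseknc, k = 3, prop_order = 3, label = "PCPseTNC"),
    "SC-PseDNC" = call1(nf_pseknc, k = 2, series = TRUE, label = "SCPseDNC"),
    "SC-PseTNC" = call1(nf_pseknc, k = 3, prop_order = 3, series = TRUE,
                        label = "SCPseTNC"),
    DPCP = call1(nf_pcp, order = 2, type = if (t2) 2 else 1),
    TPCP = call1(nf_pcp, order = 3, type = if (t2) 2 else 1),
    PSTNPss = call1(nf_pstnp, double_strand = FALSE),
    PSTNPds = call1(nf_pstnp, double_strand = TRUE),
    KNN = call1(pf_knn),
    stop("unhandled nucleic descriptor: ", descriptor)
  ))
}

#' Compute a descriptor set as a feature tibble
#'
#' The generic entry point: dispatches on the input object (sequence set,
#' structure model or molecule set) and returns a tibble whose first column
#' is the sample id, followed by an optional `label` column and the named
#' feature columns.
#'
#' @param x an `omega_seqs`, `omega_structure` or `omega_mols` object.
#' @param descriptor a registered descriptor name for the input's kind.
#' @param ... descriptor parameters (e.g. `k`, `gap`, `nlag`, `lambda`, `w`,
#'   shell scheme settings).
#' @return a feature tibble.
#' @export
calculate_features <- function(x, descriptor, ...) {
  UseMethod("calculate_features")
}

#' @export
calculate_features.omega_seqs <- function(x, descriptor, ...) {
  m <- seq_descriptor_matrix(x, descriptor, ...)
  feature_tbl(m, x$id, x$label)
}

#' @export
calculate_features.omega_structure <- function(x, descriptor, ...) {
  calc_structure_features(x, descriptor, ...)
}

#' @export
calculate_features.omega_mols <- function(x, descriptor, ...) {
  calc_ligand_features(x, descriptor, ...)
}
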