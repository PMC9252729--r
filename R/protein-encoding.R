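# Residue-level encodings (fixed width per residue over equal-length sets)
# and the nearest-neighbour similarity descriptor.

one_hot <- function(x, levels) {
  m <- matrix(0, length(x), length(levels))
  m[cbind(seq_along(x), match(x, levels))] <- 1
  m
}

encode_per_residue <- function(seqs, width_names, row_fn, prefix) {
  check_equal_lengths(seqs)
  L <- nchar(seqs$seq[[1]])
  nm <- as.vector(t(outer(paste0(prefix, ".p", seq_len(L)), width_names,
                          paste, sep = ".")))
  m <- do.call(rbind, lapply(seqs$seq, function(s) {
    as.vector(t(row_fn(chars(s))))
  }))
  colnames(m) <- nm
  rownames(m) <- seqs$id
  m
}

pf_binary <- function(seqs, ...) {
  encode_per_residue(seqs, AA20, function(ch) one_hot(ch, AA20), "binary")
}

pf_binary_6bit <- function(seqs, ...) {
  g6 <- names(AA_GROUPS6)
  of <- local({
    v <- character(0)
    for (g in g6) v[AA_GROUPS6[[g]]] <- g
    v
  })
  encode_per_residue(seqs, g6, function(ch) one_hot(unname(of[ch]), g6), "binary6")
}

# type 1: one-hot over the five physicochemical groups
# type 2: 5-bit binary code of the alphabet rank
pf_binary_5bit <- function(seqs, type = 1, ...) {
  if (type == 1) {
    encode_per_residue(seqs, G5, function(ch) one_hot(group5_of(ch), G5), "binary5.t1")
  } else {
    codes <- t(vapply(seq_along(AA20) - 1L, function(i) {
      as.integer(intToBits(i))[1:5]
    }, integer(5)))
    rownames(codes) <- AA20
    encode_per_residue(seqs, paste0("b", 1:5),
                       function(ch) codes[ch, , drop = FALSE], "binary5.t2")
  }
}

# one-hot over the 3 groups of CTD property `type` (types 1..7)
pf_binary_3bit <- function(seqs, type = 1, ...) {
  prop <- names(CTD_GROUPS)[[type]]
  encode_per_residue(seqs, paste0("g", 1:3), function(ch) {
    one_hot(ctd_group_of(ch, prop), 1:3)
  }, paste0("binary3.t", type))
}

pf_aesnn3 <- function(seqs, ...) {
  encode_per_residue(seqs, colnames(AESNN3),
                     function(ch) AESNN3[ch, , drop = FALSE], "AESNN3")
}

pf_opf_10bit <- function(seqs, ...) {
  flags <- sapply(OPF10, function(set) AA20 %in% set) * 1
  rownames(flags) <- AA20
  encode_per_residue(seqs, names(OPF10),
                     function(ch) flags[ch, , drop = FALSE], "OPF10")
}

# membership bit for group `type` (1..3) of each of the 7 CTD properties
pf_opf_7bit <- function(seqs, type = 1, ...) {
  flags <- sapply(names(CTD_GROUPS), function(p) {
    (ctd_group_of(AA20, p) == type) * 1
  })
  rownames(flags) <- AA20
  encode_per_residue(seqs, names(CTD_GROUPS),
                     function(ch) flags[ch, , drop = FALSE],
                     paste0("OPF7.t", type))
}

pf_zscale <- function(seqs, ...) {
  encode_per_residue(seqs, colnames(ZSCALE),
                     function(ch) ZSCALE[ch, , drop = FALSE], "ZScale")
}

blosum62_table <- function() {
  m <- get_blosum62()
  m[AA20, AA20]
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

pf_blosum62 <- function(seqs, ...) {
  b <- blosum62_table()
  encode_per_residue(seqs, AA20, function(ch) b[ch, , drop = FALSE], "BLOSUM62")
}

pf_aaindex <- function(seqs, properties = NULL, ...) {
  prop <- default_protein_props(properties)
  encode_per_residue(seqs, rownames(prop),
                     function(ch) t(prop[, ch, drop = FALSE]), "AAIndex")
}

# --- nearest-neighbour descriptor --------------------------------------------
# similarity = global alignment score normalized by the longer sequence,
# BLOSUM62 gap open 10 / extend 1 for protein, +2/-1 for nucleic acids
knn_similarity <- function(a, b, kind) {
  if (kind == "protein") {
    sc <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = get_blosum62(),
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                    baseOnly = FALSE)
    a <- gsub("U", "T", a, fixed = TRUE)
    b <- gsub("U", "T", b, fixed = TRUE)
    sc <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
  }
  sc / max(nchar(a), nchar(b))
}

#' Nearest-neighbour class-proportion descriptor
#'
#' For each query sequence and each neighbourhood fraction, the proportion of
#' each class among its k nearest training sequences under a normalized
#' global-alignment similarity. Ties in similarity are broken by training-set
#' order.
#'
#' @param query,train sequence-set tibbles of the same kind; `train` must be
#'   fully labelled with at least two classes.
#' @param k_fractions neighbourhood sizes as fractions of the training set
#'   (rounded up to at least one sequence).
#' @return numeric matrix (queries x fractions*classes).
#' @keywords internal
knn_matrix <- function(query, train, k_fractions = seq(0.01, 0.30, by = 0.01)) {
  if (is.null(train$label) || any(is.na(train$label))) {
    stop("KNN requires a fully labelled training set")
  }
  classes <- sort(unique(train$label))
  if (length(classes) < 2) stop("KNN requires at least two classes")
  n <- nrow(train)
  ks <- unique(pmax(1L, ceiling(k_fractions * n)))
  if (any(ks > n)) stop("k larger than training-set size")
  kind <- seq_kind(train)
  sim <- vapply(train$seq, function(t) {
    vapply(query$seq, knn_similarity, numeric(1), b = t, kind = kind)
  }, numeric(nrow(query)))
  sim <- matrix(sim, nrow = nrow(query))
  rows <- lapply(seq_len(nrow(query)), function(qi) {
    ord <- order(-sim[qi, ], seq_len(n))
    unlist(lapply(seq_along(ks), function(j) {
      top <- train$label[ord[seq_len(ks[j])]]
      stats::setNames(count_on(top, classes) / ks[j],
                      paste0("KNN.k", ks[j], ".", classes))
    }))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- query$id
  m
}

pf_knn <- function(seqs, train = NULL, k_fractions = seq(0.05, 0.30, by = 0.05), ...) {
  if (is.null(train)) train <- seqs
  knn_matrix(seqs, train, k_fractions)
}
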