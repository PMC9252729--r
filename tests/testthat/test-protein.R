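AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("amino-acid composition basics", {
  t1 <- calculate_features(one_seq("AAAA"), "AAC")
  v <- feat_mat(t1)[1, ]
  expect_equal(unname(v["AAC.A"]), 1)
  expect_equal(sum(v), 1)

  t2 <- calculate_features(one_seq(paste(AA20, collapse = "")), "AAC")
  expect_true(all(abs(feat_mat(t2) - 0.05) < 1e-12))

  t3 <- calculate_features(one_seq("AAAA"), "DPC type 1")
  expect_equal(unname(feat_mat(t3)[1, "DPC.AA"]), 1)
})

test_that("CKSAAP gap blocks each sum to one and match brute-force pairs", {
  s <- "ACACADEKW"
  tbl <- calculate_features(one_seq(s), "CKSAAP type 1", gap = 2)
  v <- feat_mat(tbl)[1, ]
  ch <- strsplit(s, "")[[1]]
  for (g in 0:2) {
    block <- v[grep(paste0("^CKSAAP\\.g", g, "\\."), names(v))]
    expect_equal(sum(block), 1, tolerance = 1e-9)
    # brute force: enumerate all pairs at that gap
    i <- seq_len(nchar(s) - g - 1)
    pairs <- table(paste0(ch[i], ch[i + g + 1]))
    for (p in names(pairs)) {
      expect_equal(unname(block[paste0("CKSAAP.g", g, ".", p)]),
                   unname(pairs[[p]]) / length(i), tolerance = 1e-12)
    }
  }
})

test_that("grouped compositions collapse onto the five physicochemical groups", {
  v <- feat_mat(calculate_features(one_seq("AAAA"), "GAAC"))[1, ]
  expect_equal(unname(v["GAAC.aliphatic"]), 1)
  v2 <- feat_mat(calculate_features(fx_protein(), "GAAC"))
  expect_true(all(abs(rowSums(v2) - 1) < 1e-9))

  # GDPC on a 2-residue sequence equals the single observed group pair
  v3 <- feat_mat(calculate_features(one_seq("AG"), "GDPC"))[1, ]
  expect_equal(unname(v3["GDPC.aliphatic-aliphatic"]), 1)
  expect_equal(sum(v3), 1)
})

test_that("autocorrelation descriptors equal a naive double-loop oracle", {
  # independent oracle: direct transcription of the formulas
  moran_o <- function(x, d) {
    n <- length(x); xb <- mean(x)
    num <- sum(sapply(1:(n - d), function(i) (x[i] - xb) * (x[i + d] - xb))) / (n - d)
    den <- sum((x - xb)^2) / n
    if (den == 0) 0 else num / den
  }
  geary_o <- function(x, d) {
    n <- length(x); xb <- mean(x)
    num <- sum(sapply(1:(n - d), function(i) (x[i] - x[i + d])^2)) / (2 * (n - d))
    den <- sum((x - xb)^2) / (n - 1)
    if (den == 0) 0 else num / den
  }
  broto_o <- function(x, d) {
    n <- length(x)
    sum(sapply(1:(n - d), function(i) x[i] * x[i + d])) / (n - d)
  }
  prop <- omegafeat:::default_protein_props("hydropathy")["hydropathy", ]
  seqs <- fixture_sequences(21, 50, 25, "protein")
  for (i in seq_len(nrow(seqs))) {
    x <- unname(prop[strsplit(seqs$seq[[i]], "")[[1]]])
    one <- seqs[i, ]; class(one) <- class(seqs); attr(one, "kind") <- "protein"
    for (variant in c("Moran", "Geary", "NMBroto")) {
      got <- feat_mat(calculate_features(one, variant, nlag = 3,
                                         properties = "hydropathy"))[1, ]
      oracle <- switch(variant, Moran = moran_o, Geary = geary_o, NMBroto = broto_o)
      for (d in 1:3) {
        expect_equal(unname(got[paste0(variant, ".hydropathy.lag", d)]),
                     oracle(x, d), tolerance = 1e-9)
      }
    }
  }
})

test_that("autocorrelation edge rules: constant signal and short sequences", {
  # constant property signal: zero-variance rule forces Moran/Geary to 0
  v <- feat_mat(calculate_features(one_seq("AAAA"), "Moran", nlag = 2))
  expect_true(all(v == 0))
  expect_error(calculate_features(one_seq("AR"), "Geary", nlag = 2), "nlag")
})

test_that("sequence-order descriptors: tau terms and QSOrder degeneracies", {
  # identical residues have zero distance
  v <- feat_mat(calculate_features(one_seq("AA"), "SOCNumber", nlag = 1))[1, ]
  expect_true(all(v == 0))

  # w = 0 degenerates to amino-acid composition per distance matrix
  s <- fx_protein()
  q <- feat_mat(calculate_features(s, "QSOrder", nlag = 3, w = 0))
  aac <- feat_mat(calculate_features(s, "AAC"))
  for (m in c("grantham", "physchem")) {
    block <- q[, paste0("QSOrder.", m, ".", AA20)]
    expect_lt(max(abs(block - aac)), 1e-9)
    expect_true(all(q[, grep(paste0(m, ".tau"), colnames(q))] == 0))
  }
  # each matrix block sums to one
  q2 <- feat_mat(calculate_features(s, "QSOrder", nlag = 3, w = 0.1))
  for (m in c("grantham", "physchem")) {
    block <- q2[, grep(paste0("QSOrder\\.", m, "\\."), colnames(q2))]
    expect_true(all(abs(rowSums(block) - 1) < 1e-9))
  }
})

test_that("pseudo amino-acid composition: degeneracy and two-pass oracle", {
  s <- fx_protein()
  paac0 <- feat_mat(calculate_features(s, "PAAC", lambda = 0))
  aac <- feat_mat(calculate_features(s, "AAC"))
  expect_lt(max(abs(paac0 - aac)), 1e-12)

  # identical residues give zero correlation terms
  th <- feat_mat(calculate_features(one_seq("AAAA"), "PAAC", lambda = 2))[1, ]
  expect_true(all(th[grep("theta", names(th))] == 0))

  # independent transcription of the formula on a short sequence
  seq <- "MKVL"; lam <- 2; w <- 0.05
  props <- omegafeat:::paac_props()
  ch <- strsplit(seq, "")[[1]]
  theta <- sapply(1:lam, function(j) {
    mean(sapply(1:(length(ch) - j), function(i) {
      mean((props[, ch[i]] - props[, ch[i + j]])^2)
    }))
  })
  f <- table(factor(ch, levels = AA20)) / length(ch)
  denom <- sum(f) + w * sum(theta)
  expected <- c(as.numeric(f) / denom, w * theta / denom)
  got <- feat_mat(calculate_features(one_seq(seq), "PAAC", lambda = lam, w = w))[1, ]
  expect_equal(unname(got), expected, tolerance = 1e-9)

  # APAAC dimensionality 20 + 2*lambda
  ap <- feat_mat(calculate_features(one_seq(seq), "APAAC", lambda = lam))
  expect_equal(ncol(ap), 20 + 2 * lam)
})

test_that("reduced-alphabet k-tuple compositions behave like compositions", {
  s <- fx_protein()
  # identity reduction at k = 1 equals AAC up to column ordering
  ident <- feat_mat(calculate_features(s, "PseKRAAC type1",
                                       cluster_count = 20, k = 1))
  aac <- feat_mat(calculate_features(s, "AAC"))
  expect_equal(apply(ident, 1, sort), apply(aac, 1, sort), tolerance = 1e-12)

  kt <- feat_mat(calculate_features(s, "PseKRAAC type5", cluster_count = 5, k = 2))
  expect_true(all(abs(rowSums(kt) - 1) < 1e-9))
  expect_equal(ncol(kt), 25)

  two <- feat_mat(calculate_features(one_seq("AAAA"), "PseKRAAC type2",
                                     cluster_count = 2, k = 2))
  expect_equal(sum(two != 0), 1)
  expect_error(calculate_features(s, "PseKRAAC type1", cluster_count = 7),
               "cluster count")
})

test_that("residue-level encodings have their documented widths", {
  s <- fx_protein(4, 10)
  L <- 10
  widths <- c("binary" = 20, "binary_6bit" = 6, "binary_5bit type 1" = 5,
              "binary_5bit type 2" = 5, "binary_3bit type 1" = 3,
              "AESNN3" = 3, "OPF_10bit" = 10, "OPF_7bit type 1" = 7,
              "ZScale" = 5, "BLOSUM62" = 20, "AAIndex" = 8)
  for (nm in names(widths)) {
    m <- feat_mat(calculate_features(s, nm))
    expect_equal(ncol(m), L * widths[[nm]])
  }
  # one-hot is exactly one per residue
  b <- feat_mat(calculate_features(one_seq("ACD"), "binary"))
  expect_equal(sum(b), 3)
  # BLOSUM62 row lookup for tryptophan
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  w_row <- e$BLOSUM62["W", AA20]
  got <- feat_mat(calculate_features(one_seq("W"), "BLOSUM62"))[1, ]
  expect_equal(unname(got), unname(w_row))
  expect_error(calculate_features(fixture_sequences(1, 3, 8, "protein"),
                                  "AAIndex", properties = "NOPE123"),
               "unknown property")
})

test_that("nearest-neighbour descriptor ranks by alignment similarity", {
  train <- seq_set(c("t1", "t2", "t3"),
                   c("MKVLAWDE", "MKVLAWDF", "GGGGGGGG"),
                   "protein", label = c("1", "1", "0"))
  query <- seq_set("q", "MKVLAWDE", "protein")
  got <- omegafeat:::knn_matrix(query, train, k_fractions = 1 / 3)
  expect_equal(unname(got[1, ]), c(0, 1))  # all neighbours in class "1"

  # proportions sum to one per (query, k)
  got2 <- omegafeat:::knn_matrix(fx_protein(), fx_protein(),
                                 k_fractions = c(0.2, 0.5))
  for (k in unique(sub("\\..*$", "", sub("^KNN\\.", "", colnames(got2))))) {
    block <- got2[, grep(paste0("KNN\\.", k, "\\."), colnames(got2)), drop = FALSE]
    expect_true(all(abs(rowSums(block) - 1) < 1e-9))
  }

  # neighbour order equals brute-force all-pairs similarity
  sims <- sapply(train$seq, function(t) {
    omegafeat:::knn_similarity("MKVLAWDE", t, "protein")
  })
  expect_equal(order(-sims), c(1, 2, 3))
  expect_error(omegafeat:::knn_matrix(query, fixture_sequences(1, 3, 8, "protein",
                                                               labelled = FALSE)),
               "labelled")
})

test_that("composition symmetry under reversal holds only where expected", {
  s <- "MKVLAWDE"
  r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(feat_mat(calculate_features(one_seq(s), "AAC")),
               feat_mat(calculate_features(one_seq(r), "AAC")),
               ignore_attr = TRUE)
  dp_f <- feat_mat(calculate_features(one_seq("AC"), "DPC type 1"))
  dp_r <- feat_mat(calculate_features(one_seq("CA"), "DPC type 1"))
  expect_false(isTRUE(all.equal(as.numeric(dp_f), as.numeric(dp_r))))
})

test_that("CTD and conjoint-triad blocks are well-formed", {
  s <- fx_protein()
  ctdc <- feat_mat(calculate_features(s, "CTDC"))
  expect_equal(ncol(ctdc), 21)
  # per-property frequencies sum to one
  for (p in seq_len(7)) {
    expect_true(all(abs(rowSums(ctdc[, (3 * p - 2):(3 * p)]) - 1) < 1e-9))
  }
  ctdd <- feat_mat(calculate_features(s, "CTDD"))
  expect_equal(ncol(ctdd), 105)
  expect_true(all(ctdd >= 0 & ctdd <= 100))
  ct <- feat_mat(calculate_features(s, "CTriad type 1"))
  expect_equal(ncol(ct), 343)
  expect_true(all(abs(rowSums(ct) - 1) < 1e-9))
  dde <- feat_mat(calculate_features(s, "DDE"))
  expect_equal(ncol(dde), 400)
  expect_true(all(is.finite(dde)))
})
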