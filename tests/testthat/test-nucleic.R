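test_that("k-mer compositions match hand counts", {
  v1 <- feat_mat(calculate_features(one_seq("ACGT", "dna"), "Kmer", k = 1))[1, ]
  expect_true(all(abs(v1 - 0.25) < 1e-12))
  v2 <- feat_mat(calculate_features(one_seq("ACGT", "dna"), "Kmer", k = 2))[1, ]
  expect_equal(unname(v2[c("Kmer2.AC", "Kmer2.CG", "Kmer2.GT")]),
               rep(1 / 3, 3))
  expect_equal(sum(v2), 1)
  expect_error(calculate_features(one_seq("AC", "dna"), "Kmer", k = 3), "shorter")
})

test_that("reverse-complement k-mers collapse onto canonical classes", {
  v <- feat_mat(calculate_features(one_seq("AAAA", "dna"), "RCKmer", k = 1))[1, ]
  expect_equal(unname(v["RCKmer1.A"]), 1)  # canonical {A,T} class
  expect_equal(length(v), 2)               # {A,T} and {C,G}

  # exact reverse-complement invariance for RCKmer; a witness breaks Kmer
  s <- "ACGGTAAC"
  rc <- "GTTACCGT"
  a <- feat_mat(calculate_features(one_seq(s, "dna"), "RCKmer", k = 3))
  b <- feat_mat(calculate_features(one_seq(rc, "dna"), "RCKmer", k = 3))
  expect_lt(max(abs(a - b)), 1e-12)
  ka <- feat_mat(calculate_features(one_seq(s, "dna"), "Kmer", k = 3))
  kb <- feat_mat(calculate_features(one_seq(rc, "dna"), "Kmer", k = 3))
  expect_false(isTRUE(all.equal(as.numeric(ka), as.numeric(kb))))

  # RNA complementation goes through A<->U
  vr <- feat_mat(calculate_features(one_seq("AAAA", "rna"), "RCKmer", k = 1))[1, ]
  expect_equal(names(vr)[vr == 1], "RCKmer1.A")
})

test_that("position encodings: running frequency and one-hot widths", {
  expect_equal(unname(feat_mat(calculate_features(one_seq("AAAA", "dna"), "ANF"))[1, ]),
               c(1, 1, 1, 1))
  expect_equal(unname(feat_mat(calculate_features(one_seq("AC", "dna"), "ANF"))[1, ]),
               c(1, 0.5))
  b <- feat_mat(calculate_features(one_seq("A", "dna"), "binary"))[1, ]
  expect_equal(unname(b), c(1, 0, 0, 0))
  d <- fx_dna(4, 12)
  expect_equal(ncol(feat_mat(calculate_features(d, "PS2"))), 11 * 16)
  expect_equal(ncol(feat_mat(calculate_features(d, "NCP"))), 12 * 3)
  # unequal lengths are rejected for positional encodings
  uneq <- seq_set(c("a", "b"), c("ACGT", "ACGTA"), "dna")
  expect_error(calculate_features(uneq, "binary"), "equal-length")
})

test_that("electron-ion interaction potentials come from the bundled constants", {
  v <- feat_mat(calculate_features(one_seq("AAAA", "dna"), "EIIP"))[1, ]
  expect_equal(unname(v), rep(0.1260, 4))
  p <- feat_mat(calculate_features(one_seq("AAAA", "dna"), "PseEIIP"))[1, ]
  nz <- p[p != 0]
  expect_equal(names(nz), "PseEIIP.AAA")
  expect_equal(unname(nz), 3 * 0.1260)
  # trinucleotide-composition property: permutations with equal counts agree
  a <- feat_mat(calculate_features(one_seq("ACGACG", "dna"), "PseEIIP"))
  b <- feat_mat(calculate_features(one_seq("CGACGA", "dna"), "PseEIIP"))
  expect_equal(sort(as.numeric(a[a != 0])), sort(as.numeric(b[b != 0])),
               tolerance = 1e-12)
})

test_that("nucleotide autocorrelation equals a double-loop oracle", {
  tab <- omegafeat:::std_prop_table(omegafeat:::nuc_prop_table("dna", 2))
  seqs <- fixture_sequences(31, 50, 20, "dna")
  moran_o <- function(x, d) {
    n <- length(x); xb <- mean(x)
    den <- sum((x - xb)^2) / n
    if (den == 0) return(0)
    sum(sapply(1:(n - d), function(i) (x[i] - xb) * (x[i + d] - xb))) / (n - d) / den
  }
  ac_o <- function(x, d) {
    n <- length(x); xb <- mean(x)
    sum(sapply(1:(n - d), function(i) (x[i] - xb) * (x[i + d] - xb))) / (n - d)
  }
  for (i in seq_len(nrow(seqs))) {
    ch <- strsplit(seqs$seq[[i]], "")[[1]]
    din <- paste0(ch[-length(ch)], ch[-1])
    one <- seqs[i, ]; class(one) <- class(seqs); attr(one, "kind") <- "dna"
    got_m <- feat_mat(calculate_features(one, "Moran", nlag = 2))[1, ]
    got_a <- feat_mat(calculate_features(one, "DAC", nlag = 2))[1, ]
    for (p in rownames(tab)) {
      x <- unname(tab[p, din])
      for (d in 1:2) {
        expect_equal(unname(got_m[paste0("Moran.", p, ".lag", d)]), moran_o(x, d),
                     tolerance = 1e-9)
        expect_equal(unname(got_a[paste0("DAC.", p, ".lag", d)]), ac_o(x, d),
                     tolerance = 1e-9)
      }
    }
  }
  # homopolymer: standardized dinucleotide signal is constant
  expect_true(all(feat_mat(calculate_features(one_seq("AAAAAA", "dna"),
                                              "DAC", nlag = 2)) == 0))
  expect_error(calculate_features(one_seq("ACG", "dna"), "TAC", nlag = 2),
               "too short")
})

test_that("mutual-information terms match a direct entropy evaluation", {
  expect_true(all(feat_mat(calculate_features(one_seq("AAAAAA", "dna"), "MMI")) == 0))

  H <- function(f) if (f > 0) -f * log(f) else 0
  mmi_oracle <- function(s) {
    ch <- strsplit(s, "")[[1]]; n <- length(ch)
    f1 <- table(factor(ch, levels = c("A", "C", "G", "T"))) / n
    pk <- function(a, b) paste(sort(c(a, b)), collapse = "")
    p2 <- sapply(1:(n - 1), function(i) pk(ch[i], ch[i + 1]))
    p3 <- sapply(1:(n - 2), function(i) paste(sort(ch[i:(i + 2)]), collapse = ""))
    f2 <- table(p2) / length(p2)
    f3 <- table(p3) / length(p3)
    g2 <- function(k) if (k %in% names(f2)) f2[[k]] else 0
    g3 <- function(k) if (k %in% names(f3)) f3[[k]] else 0
    lv <- omegafeat:::mmi_levels()
    i2 <- sapply(lv$pairs, function(p) {
      xy <- strsplit(p, "")[[1]]
      H(f1[[xy[1]]]) + H(f1[[xy[2]]]) - H(g2(p))
    })
    i3 <- sapply(lv$triples, function(t) {
      xyz <- strsplit(t, "")[[1]]
      ixy <- H(f1[[xyz[1]]]) + H(f1[[xyz[2]]]) - H(g2(pk(xyz[1], xyz[2])))
      ixy - (H(g2(pk(xyz[1], xyz[3]))) + H(g2(pk(xyz[2], xyz[3]))) -
               H(f1[[xyz[3]]]) - H(g3(t)))
    })
    c(i2, i3)
  }
  got <- feat_mat(calculate_features(one_seq("ACGTACGT", "dna"), "MMI"))[1, ]
  expect_equal(unname(got), unname(mmi_oracle("ACGTACGT")), tolerance = 1e-9)

  # pair/triple multisets are direction-free, so reversal leaves MMI unchanged
  seqs <- fixture_sequences(77, 20, 15, "dna")
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$seq[[i]]
    r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(feat_mat(calculate_features(one_seq(s, "dna"), "MMI")),
                 feat_mat(calculate_features(one_seq(r, "dna"), "MMI")),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(calculate_features(one_seq("AC", "dna"), "MMI"), ">= 3")
})

test_that("pseudo k-nucleotide compositions degenerate and normalize", {
  d <- fx_dna()
  p0 <- feat_mat(calculate_features(d, "PseDNC", lambda = 0))
  dnc <- feat_mat(calculate_features(d, "DNC"))
  expect_lt(max(abs(p0 - dnc)), 1e-12)

  for (nm in c("PseDNC", "PseKNC", "PC-PseDNC", "SC-PseDNC")) {
    v <- feat_mat(calculate_features(d, nm, lambda = 2, w = 0.1))
    expect_true(all(abs(rowSums(v) - 1) < 1e-9))
  }

  # independent two-pass transcription for PseDNC
  s <- "ACGTACGT"; lam <- 2; w <- 0.1
  tab <- omegafeat:::std_prop_table(omegafeat:::nuc_prop_table("dna", 2))
  ch <- strsplit(s, "")[[1]]
  din <- paste0(ch[-length(ch)], ch[-1])
  theta <- sapply(1:lam, function(j) {
    mean(sapply(1:(length(din) - j), function(i) {
      mean((tab[, din[i]] - tab[, din[i + j]])^2)
    }))
  })
  f <- table(factor(din, levels = colnames(tab))) / length(din)
  denom <- sum(f) + w * sum(theta)
  expected <- c(as.numeric(f) / denom, w * theta / denom)
  got <- feat_mat(calculate_features(one_seq(s, "dna"), "PseDNC",
                                     lambda = lam, w = w))[1, ]
  expect_equal(unname(got), expected, tolerance = 1e-9)
  expect_error(calculate_features(one_seq("ACGT", "dna"), "PseDNC", lambda = 4),
               "lambda")
})

test_that("Z-curve transforms have their stated dimensions and purine axis", {
  dims <- c("Z_curve_9bit" = 9, "Z_curve_12bit" = 12, "Z_curve_36bit" = 36,
            "Z_curve_48bit" = 48, "Z_curve_144bit" = 144)
  d <- fx_dna()
  for (nm in names(dims)) {
    expect_equal(ncol(feat_mat(calculate_features(d, nm))), dims[[nm]])
  }
  v <- feat_mat(calculate_features(one_seq("AAAA", "dna"), "Z_curve_9bit"))[1, ]
  xs <- v[grep("\\.x$", names(v))]
  expect_true(all(xs == 1))  # pure purine
})

test_that("position-specific propensities need two labelled classes", {
  d <- fx_dna(6, 15)
  ss <- feat_mat(calculate_features(d, "PSTNPss"))
  expect_equal(ncol(ss), 13)
  ds <- feat_mat(calculate_features(d, "PSTNPds"))
  expect_equal(ncol(ds), 13)
  expect_error(calculate_features(fixture_sequences(1, 4, 12, "dna",
                                                    labelled = FALSE),
                                  "PSTNPss"),
               "label")
})

test_that("RNA and DNA rosters share code paths but differ in scope", {
  r <- fx_rna()
  expect_equal(nrow(list_descriptors("rna")), 37)
  expect_equal(nrow(list_descriptors("dna")), 49)
  expect_error(calculate_features(r, "TAC"), "not registered")
  # RNA feature names present U
  v <- feat_mat(calculate_features(r, "Kmer", k = 1))
  expect_true("Kmer1.U" %in% colnames(v))
})
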