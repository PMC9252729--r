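# Nucleotide autocorrelation, mutual-information, Z-curve and pseudo
# k-nucleotide composition descriptors.

# property signal: value of the k-mer starting at each position
nuc_prop_signal <- function(ch, tab, km_order) {
  w <- seq_kmers(ch, km_order)
  tab[, w, drop = FALSE]
}

nf_autocorr <- function(seqs, variant, nlag = 2, km_order = 2, ...) {
  kind <- seq_kind(seqs)
  tab <- std_prop_table(nuc_prop_table(kind, km_order))
  pn <- rownames(tab)
  lab <- paste0(variant, if (km_order == 3) ".tri" else "")
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    if (nchar(s) < nlag + km_order) stop("sequence too short for nlag ", nlag)
    sig <- nuc_prop_signal(ch, tab, km_order)
    f <- switch(variant, Moran = moran_lags, Geary = geary_lags,
                NMBroto = nmbroto_lags)
    unlist(lapply(pn, function(p) {
      stats::setNames(f(sig[p, ], nlag),
                      paste0(lab, ".", p, ".lag", seq_len(nlag)))
    }))
  })
}

# dinucleotide/trinucleotide auto- and cross-covariance
nf_covariance <- function(seqs, variant, nlag = 2, ...) {
  kind <- seq_kind(seqs)
  km_order <- if (substr(variant, 1, 1) == "T") 3 else 2
  base <- substr(variant, 2, 10)  # AC, CC or ACC
  tab <- std_prop_table(nuc_prop_table(kind, km_order))
  pn <- rownames(tab)
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    if (nchar(s) < nlag + km_order) stop("sequence too short for nlag ", nlag)
    sig <- nuc_prop_signal(ch, tab, km_order)
    auto <- function() unlist(lapply(pn, function(p) {
      stats::setNames(ac_lags(sig[p, ], nlag),
                      paste0(variant, ".", p, ".lag", seq_len(nlag)))
    }))
    cross <- function() {
      out <- list()
      for (p1 in pn) for (p2 in setdiff(pn, p1)) {
        out[[paste(p1, p2)]] <- stats::setNames(
          cc_lags(sig[p1, ], sig[p2, ], nlag),
          paste0(variant, ".", p1, "-", p2, ".lag", seq_len(nlag)))
      }
      unlist(unname(out))
    }
    switch(base, AC = auto(), CC = cross(), ACC = c(auto(), cross()))
  })
}

# --- multivariate mutual information ----------------------------------------
# Frequencies of unordered adjacent pairs and triples; single-term entropy
# H(s) = -f(s) ln f(s); I(x;y) = H(x)+H(y)-H(x,y);
# I(x;y;z) = I(x;y) - [H(x,z)+H(y,z)-H(z)-H(x,y,z)].
mmi_levels <- function() {
  pairs <- apply(utils::combn(c(DNA4, DNA4), 2), 2, function(p) paste(sort(p), collapse = ""))
  pairs <- sort(unique(c(pairs, paste0(DNA4, DNA4))))
  g <- expand.grid(a = DNA4, b = DNA4, c = DNA4, stringsAsFactors = FALSE)
  triples <- sort(unique(apply(g, 1, function(t) paste(sort(t), collapse = ""))))
  list(pairs = pairs, triples = triples)
}

nf_mmi <- function(seqs, ...) {
  kind <- seq_kind(seqs)
  lv <- mmi_levels()
  H <- function(f) ifelse(f > 0, -f * log(f), 0)
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    n <- length(ch)
    if (n < 3) stop("MMI requires length >= 3")
    f1 <- stats::setNames(count_on(ch, DNA4) / n, DNA4)
    p2 <- vapply(seq_len(n - 1), function(i) paste(sort(ch[i:(i + 1)]), collapse = ""),
                 character(1))
    f2 <- stats::setNames(count_on(p2, lv$pairs) / length(p2), lv$pairs)
    p3 <- vapply(seq_len(n - 2), function(i) paste(sort(ch[i:(i + 2)]), collapse = ""),
                 character(1))
    f3 <- stats::setNames(count_on(p3, lv$triples) / length(p3), lv$triples)
    pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "")
    i2 <- vapply(lv$pairs, function(p) {
      xy <- chars(p)
      H(f1[[xy[1]]]) + H(f1[[xy[2]]]) - H(f2[[p]])
    }, numeric(1))
    names(i2) <- paste0("MMI.", present_kmer(lv$pairs, kind))
    i3 <- vapply(lv$triples, function(t) {
      xyz <- chars(t)
      x <- xyz[1]; y <- xyz[2]; z <- xyz[3]
      ixy <- H(f1[[x]]) + H(f1[[y]]) - H(f2[[pair_key(x, y)]])
      ixy - (H(f2[[pair_key(x, z)]]) + H(f2[[pair_key(y, z)]]) -
               H(f1[[z]]) - H(f3[[t]]))
    }, numeric(1))
    names(i3) <- paste0("MMI.", present_kmer(lv$triples, kind))
    c(i2, i3)
  })
}

# --- Z-curve -----------------------------------------------------------------
# x = (A+G)-(C+T) (purine), y = (A+C)-(G+T) (amino), z = (A+T)-(C+G) (weak H-bond)
zcurve_xyz <- function(f) {
  c(x = (f[["A"]] + f[["G"]]) - (f[["C"]] + f[["T"]]),
    y = (f[["A"]] + f[["C"]]) - (f[["G"]] + f[["T"]]),
    z = (f[["A"]] + f[["T"]]) - (f[["C"]] + f[["G"]]))
}

# frequency of base b immediately after context `ctx` (per phase subset)
zcurve_context <- function(ch, ctx_len, idx) {
  n <- length(ch)
  pos <- idx[idx > ctx_len & idx <= n]
  if (ctx_len == 0) {
    f <- stats::setNames(count_on(ch[pos], DNA4) / max(1, length(pos)), DNA4)
    return(list(all = f))
  }
  ctx <- vapply(pos, function(i) paste(ch[(i - ctx_len):(i - 1)], collapse = ""),
                character(1))
  out <- list()
  for (cx in all_kmers(ctx_len)) {
    sel <- ch[pos[ctx == cx]]
    tot <- length(sel)
    out[[cx]] <- stats::setNames(
      if (tot > 0) count_on(sel, DNA4) / tot else rep(0, 4), DNA4)
  }
  out
}

nf_zcurve <- function(seqs, variant = c("9bit", "12bit", "36bit", "48bit", "144bit"), ...) {
  variant <- match.arg(variant)
  phased <- variant %in% c("9bit", "36bit", "144bit")
  ctx_len <- switch(variant, "9bit" = 0, "12bit" = 1, "36bit" = 1,
                    "48bit" = 2, "144bit" = 2)
  if (variant == "9bit") ctx_len <- 0
  if (variant == "12bit") ctx_len <- 1
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    n <- length(ch)
    idx_sets <- if (phased) {
      lapply(1:3, function(p) seq(p, n, by = 3))
    } else list(seq_len(n))
    out <- c()
    for (pi in seq_along(idx_sets)) {
      ctxs <- zcurve_context(ch, ctx_len, idx_sets[[pi]])
      for (cx in names(ctxs)) {
        v <- zcurve_xyz(ctxs[[cx]])
        tag <- paste0("Zcurve", variant,
                      if (phased) paste0(".phase", pi) else "",
                      if (cx != "all") paste0(".", cx) else "")
        out <- c(out, stats::setNames(v, paste0(tag, ".", names(v))))
      }
    }
    out
  })
}

# --- pseudo k-nucleotide compositions ----------------------------------------
# Parallel (PC) variants average the property correlation; series (SC)
# variants keep one theta term per property and lag.
nf_pseknc <- function(seqs, k = 2, lambda = 2, w = 0.1,
                      series = FALSE, prop_order = 2, label = "PseDNC", ...) {
  kind <- seq_kind(seqs)
  tab <- std_prop_table(nuc_prop_table(kind, prop_order))
  km <- all_kmers(k)
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    n <- length(ch)
    if (lambda > n - prop_order) stop("lambda too large for sequence length")
    wn <- seq_kmers(ch, k)
    f <- count_on(wn, km) / length(wn)
    sig <- nuc_prop_signal(ch, tab, prop_order)
    nwin <- ncol(sig)
    if (series) {
      theta <- unlist(lapply(seq_len(lambda), function(j) {
        i <- seq_len(nwin - j)
        rowMeans((sig[, i, drop = FALSE] - sig[, i + j, drop = FALSE])^2)
      }))
      tn <- paste0(label, ".lam", rep(seq_len(lambda), each = nrow(sig)),
                   ".", rownames(sig))
    } else {
      theta <- vapply(seq_len(lambda), function(j) {
        i <- seq_len(nwin - j)
        mean(colMeans((sig[, i, drop = FALSE] - sig[, i + j, drop = FALSE])^2))
      }, numeric(1))
      tn <- paste0(label, ".theta", seq_len(lambda))
    }
    if (lambda == 0) { theta <- numeric(0); tn <- character(0) }
    denom <- sum(f) + w * sum(theta)
    stats::setNames(c(f / denom, if (length(theta)) w * theta / denom),
                    c(paste0(label, ".", present_kmer(km, kind)), tn))
  })
}
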