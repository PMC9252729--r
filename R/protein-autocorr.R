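# Autocorrelation, sequence-order and pseudo-composition protein descriptors.

default_protein_props <- function(properties = NULL) {
  tab <- if (is.null(properties)) AAINDEX_SUBSET else {
    bad <- setdiff(properties, rownames(AAINDEX_SUBSET))
    if (length(bad)) stop("unknown property index: ", paste(bad, collapse = ", "))
    AAINDEX_SUBSET[properties, , drop = FALSE]
  }
  t(apply(tab, 1, standardize_property))
}

prop_signal <- function(s, prop) unname(prop[chars(s)])

# Moran autocorrelation at lags 1..nlag for one standardized property
moran_lags <- function(x, nlag) {
  n <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2) / n
  vapply(seq_len(nlag), function(d) {
    if (denom == 0) return(0)
    num <- sum((x[1:(n - d)] - xb) * (x[(1 + d):n] - xb)) / (n - d)
    num / denom
  }, numeric(1))
}

geary_lags <- function(x, nlag) {
  n <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2) / (n - 1)
  vapply(seq_len(nlag), function(d) {
    if (denom == 0) return(0)
    num <- sum((x[1:(n - d)] - x[(1 + d):n])^2) / (2 * (n - d))
    num / denom
  }, numeric(1))
}

nmbroto_lags <- function(x, nlag) {
  n <- length(x)
  vapply(seq_len(nlag), function(d) {
    sum(x[1:(n - d)] * x[(1 + d):n]) / (n - d)
  }, numeric(1))
}

ac_lags <- function(x, nlag) {
  n <- length(x)
  xb <- mean(x)
  vapply(seq_len(nlag), function(d) {
    sum((x[1:(n - d)] - xb) * (x[(1 + d):n] - xb)) / (n - d)
  }, numeric(1))
}

cc_lags <- function(x, y, nlag) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  vapply(seq_len(nlag), function(d) {
    sum((x[1:(n - d)] - xb) * (y[(1 + d):n] - yb)) / (n - d)
  }, numeric(1))
}

#' @keywords internal
autocorr_matrix <- function(seqs, variant, nlag, prop_tab, prefix) {
  pn <- rownames(prop_tab)
  per_seq(seqs, function(s) {
    if (nlag >= nchar(s)) stop("nlag (", nlag, ") must be < sequence length")
    sig <- lapply(pn, function(p) prop_signal(s, prop_tab[p, ]))
    names(sig) <- pn
    if (variant %in% c("Moran", "Geary", "NMBroto", "AC")) {
      f <- switch(variant, Moran = moran_lags, Geary = geary_lags,
                  NMBroto = nmbroto_lags, AC = ac_lags)
      unlist(lapply(pn, function(p) {
        stats::setNames(f(sig[[p]], nlag), paste0(prefix, ".", p, ".lag", seq_len(nlag)))
      }))
    } else if (variant == "CC") {
      out <- list()
      for (p1 in pn) for (p2 in setdiff(pn, p1)) {
        out[[paste(p1, p2)]] <- stats::setNames(
          cc_lags(sig[[p1]], sig[[p2]], nlag),
          paste0(prefix, ".", p1, "-", p2, ".lag", seq_len(nlag)))
      }
      unlist(unname(out))
    } else stop("unknown autocorrelation variant ", variant)
  })
}

pf_autocorr <- function(seqs, variant, nlag = 5, properties = NULL, ...) {
  prop <- default_protein_props(properties)
  if (variant == "ACC") {
    cbind(autocorr_matrix(seqs, "AC", nlag, prop, "ACC.AC"),
          autocorr_matrix(seqs, "CC", nlag, prop, "ACC.CC"))
  } else {
    autocorr_matrix(seqs, variant, nlag, prop, variant)
  }
}

# --- sequence order ----------------------------------------------------------
qso_matrices <- function() {
  list(grantham = grantham_matrix(), physchem = physchem_matrix())
}

tau_terms <- function(ch, dmat, nlag) {
  n <- length(ch)
  vapply(seq_len(nlag), function(d) {
    i <- seq_len(n - d)
    sum(dmat[cbind(ch[i], ch[i + d])]^2)
  }, numeric(1))
}

pf_socnumber <- function(seqs, nlag = 5, ...) {
  mats <- qso_matrices()
  per_seq(seqs, function(s) {
    ch <- chars(s)
    if (nlag >= length(ch)) stop("nlag must be < sequence length")
    unlist(lapply(names(mats), function(m) {
      stats::setNames(tau_terms(ch, mats[[m]], nlag),
                      paste0("SOCNumber.", m, ".tau", seq_len(nlag)))
    }))
  })
}

pf_qsorder <- function(seqs, nlag = 5, w = 0.1, ...) {
  mats <- qso_matrices()
  per_seq(seqs, function(s) {
    ch <- chars(s)
    if (nlag >= length(ch)) stop("nlag must be < sequence length")
    f <- count_on(ch, AA20)
    unlist(lapply(names(mats), function(m) {
      tau <- tau_terms(ch, mats[[m]], nlag)
      denom <- sum(f) + w * sum(tau)
      stats::setNames(c(f / denom, w * tau / denom),
                      c(paste0("QSOrder.", m, ".", AA20),
                        paste0("QSOrder.", m, ".tau", seq_len(nlag))))
    }))
  })
}

# --- pseudo amino-acid composition -------------------------------------------
paac_props <- function() {
  rbind(h1 = standardize_property(PAAC_HYDROPHOBICITY),
        h2 = standardize_property(PAAC_HYDROPHILICITY),
        m  = standardize_property(PAAC_SIDECHAIN_MASS))
}

pf_paac <- function(seqs, lambda = NULL, w = 0.05, ...) {
  prop <- paac_props()
  per_seq(seqs, function(s) {
    ch <- chars(s)
    n <- length(ch)
    lam <- if (is.null(lambda)) min(30, n - 1) else lambda
    if (lam >= n) stop("lambda must be < sequence length")
    f <- count_on(ch, AA20) / n
    theta <- if (lam > 0) vapply(seq_len(lam), function(j) {
      i <- seq_len(n - j)
      mean(colMeans((prop[, ch[i], drop = FALSE] - prop[, ch[i + j], drop = FALSE])^2))
    }, numeric(1)) else numeric(0)
    denom <- sum(f) + w * sum(theta)
    stats::setNames(c(f / denom, if (lam > 0) w * theta / denom),
                    c(paste0("PAAC.", AA20),
                      if (lam > 0) paste0("PAAC.theta", seq_len(lam))))
  })
}

pf_apaac <- function(seqs, lambda = NULL, w = 0.05, ...) {
  prop <- paac_props()[1:2, , drop = FALSE]  # amphiphilic pair
  per_seq(seqs, function(s) {
    ch <- chars(s)
    n <- length(ch)
    lam <- if (is.null(lambda)) min(30, n - 1) else lambda
    if (lam >= n) stop("lambda must be < sequence length")
    f <- count_on(ch, AA20) / n
    tau <- if (lam > 0) unlist(lapply(seq_len(lam), function(j) {
      i <- seq_len(n - j)
      vapply(rownames(prop), function(p) {
        mean(prop[p, ch[i]] * prop[p, ch[i + j]])
      }, numeric(1))
    })) else numeric(0)
    denom <- sum(f) + w * sum(tau)
    nm <- if (lam > 0) paste0("APAAC.", rep(paste0("lam", seq_len(lam)), each = 2),
                              ".", rownames(prop)) else character(0)
    stats::setNames(c(f / denom, if (lam > 0) w * tau / denom),
                    c(paste0("APAAC.", AA20), nm))
  })
}

# --- pseudo K-tuple reduced amino-acid composition ---------------------------
pf_psekraac <- function(seqs, scheme = "type1", cluster_count = 5, k = 2,
                        gap = 0, mode = c("ktuple", "lambda"),
                        lambda = 2, w = 0.05, ...) {
  mode <- match.arg(mode)
  map <- psekraac_mapping(scheme, cluster_count)
  groups <- sort(unique(map))
  per_seq(seqs, function(s) {
    g <- unname(map[chars(s)])
    n <- length(g)
    if (mode == "ktuple") {
      step <- gap + 1
      if (n < 1 + (k - 1) * step) stop("sequence too short for k-tuple")
      starts <- seq_len(n - (k - 1) * step)
      keys <- vapply(starts, function(i) {
        paste(g[i + (0:(k - 1)) * step], collapse = ".")
      }, character(1))
      lv <- apply(do.call(expand.grid, rev(replicate(k, groups, simplify = FALSE))),
                  1, function(r) paste(rev(r), collapse = "."))
      cnt <- count_on(keys, lv)
      stats::setNames(cnt / sum(cnt), paste0(scheme, ".c", cluster_count, ".", lv))
    } else {
      if (lambda >= n) stop("lambda must be < sequence length")
      z <- standardize_property(stats::setNames(as.numeric(groups), groups))
      sig <- unname(z[as.character(g)])
      f <- count_on(g, groups) / n
      theta <- vapply(seq_len(lambda), function(j) {
        i <- seq_len(n - j)
        mean((sig[i] - sig[i + j])^2)
      }, numeric(1))
      denom <- sum(f) + w * sum(theta)
      stats::setNames(c(f / denom, w * theta / denom),
                      c(paste0(scheme, ".c", cluster_count, ".g", groups),
                        paste0(scheme, ".theta", seq_len(lambda))))
    }
  })
}
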