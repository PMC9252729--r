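# Protein composition-type descriptors.
#
# Each pf_* function maps a sequence-set tibble to a numeric matrix with
# named columns; calculate_features() wraps them into feature tibbles.

chars <- function(s) strsplit(s, "")[[1]]

per_seq <- function(seqs, fn, ...) {
  rows <- lapply(seqs$seq, fn, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- seqs$id
  m
}

count_on <- function(x, levels) {
  tab <- table(factor(x, levels = levels))
  as.numeric(tab)
}

# amino-acid composition
pf_aac <- function(seqs, ...) {
  per_seq(seqs, function(s) {
    ch <- chars(s)
    stats::setNames(count_on(ch, AA20) / length(ch), paste0("AAC.", AA20))
  })
}

# enhanced AAC: sliding-window composition over an equal-length set
pf_eaac <- function(seqs, window = 5, ...) {
  check_equal_lengths(seqs)
  L <- nchar(seqs$seq[[1]])
  if (L < window) stop("sequences shorter than EAAC window ", window)
  per_seq(seqs, function(s) {
    ch <- chars(s)
    out <- lapply(seq_len(L - window + 1), function(i) {
      w <- ch[i:(i + window - 1)]
      stats::setNames(count_on(w, AA20) / window,
                      paste0("EAAC.w", i, ".", AA20))
    })
    unlist(out)
  })
}

dipeptides <- function(alpha = AA20) {
  as.vector(outer(alpha, alpha, paste0))
}

# composition of k-spaced amino-acid pairs; type 1 = per-gap frequencies,
# type 2 = raw counts
pf_cksaap <- function(seqs, gap = 3, type = 1, ...) {
  dp <- dipeptides()
  per_seq(seqs, function(s) {
    ch <- chars(s)
    n <- length(ch)
    if (n < gap + 2) stop("sequence too short for CKSAAP gap ", gap)
    out <- lapply(0:gap, function(g) {
      i <- seq_len(n - g - 1)
      pairs <- paste0(ch[i], ch[i + g + 1])
      cnt <- count_on(pairs, dp)
      v <- if (type == 1) cnt / length(i) else cnt
      stats::setNames(v, paste0("CKSAAP.g", g, ".", dp))
    })
    unlist(out)
  })
}

pf_dpc <- function(seqs, type = 1, ...) {
  dp <- dipeptides()
  per_seq(seqs, function(s) {
    ch <- chars(s)
    if (length(ch) < 2) stop("sequence too short for DPC")
    pairs <- paste0(ch[-length(ch)], ch[-1])
    cnt <- count_on(pairs, dp)
    v <- if (type == 1) cnt / length(pairs) else cnt
    stats::setNames(v, paste0("DPC.", dp))
  })
}

# dipeptide deviation from expected mean
pf_dde <- function(seqs, ...) {
  dp <- dipeptides()
  cn <- AA_CODON_COUNT
  tm <- as.vector(outer(cn, cn, function(a, b) (a / 61) * (b / 61)))
  per_seq(seqs, function(s) {
    ch <- chars(s)
    n <- length(ch) - 1
    if (n < 1) stop("sequence too short for DDE")
    dc <- count_on(paste0(ch[-(n + 1)], ch[-1]), dp) / n
    tv <- tm * (1 - tm) / n
    v <- ifelse(tv > 0, (dc - tm) / sqrt(tv), 0)
    stats::setNames(v, paste0("DDE.", dp))
  })
}

pf_tpc <- function(seqs, type = 1, ...) {
  tp <- as.vector(outer(dipeptides(), AA20, paste0))
  per_seq(seqs, function(s) {
    ch <- chars(s)
    n <- length(ch) - 2
    if (n < 1) stop("sequence too short for TPC")
    tri <- paste0(ch[seq_len(n)], ch[seq_len(n) + 1], ch[seq_len(n) + 2])
    cnt <- count_on(tri, tp)
    v <- if (type == 1) cnt / n else cnt
    stats::setNames(v, paste0("TPC.", tp))
  })
}

# adaptive skip dipeptide composition: all ordered pairs i<j
pf_asdc <- function(seqs, ...) {
  dp <- dipeptides()
  per_seq(seqs, function(s) {
    ch <- chars(s)
    n <- length(ch)
    if (n < 2) stop("sequence too short for ASDC")
    pairs <- unlist(lapply(seq_len(n - 1), function(i) paste0(ch[i], ch[(i + 1):n])))
    stats::setNames(count_on(pairs, dp) / length(pairs), paste0("ASDC.", dp))
  })
}

# --- CTD ---------------------------------------------------------------------
ctd_group_of <- function(ch, prop) {
  gs <- CTD_GROUPS[[prop]]
  out <- integer(length(ch))
  for (g in 1:3) out[ch %in% chars(gs[[g]])] <- g
  out
}

pf_ctdc <- function(seqs, ...) {
  per_seq(seqs, function(s) {
    ch <- chars(s)
    unlist(lapply(names(CTD_GROUPS), function(p) {
      g <- ctd_group_of(ch, p)
      stats::setNames(count_on(g, 1:3) / length(ch),
                      paste0("CTDC.", p, ".g", 1:3))
    }))
  })
}

pf_ctdt <- function(seqs, ...) {
  per_seq(seqs, function(s) {
    ch <- chars(s)
    if (length(ch) < 2) stop("sequence too short for CTDT")
    unlist(lapply(names(CTD_GROUPS), function(p) {
      g <- ctd_group_of(ch, p)
      a <- g[-length(g)]; b <- g[-1]
      tr <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
              sum((a == 1 & b == 3) | (a == 3 & b == 1)),
              sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (length(ch) - 1)
      stats::setNames(tr, paste0("CTDT.", p, ".", c("g1g2", "g1g3", "g2g3")))
    }))
  })
}

pf_ctdd <- function(seqs, ...) {
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  per_seq(seqs, function(s) {
    ch <- chars(s)
    n <- length(ch)
    unlist(lapply(names(CTD_GROUPS), function(p) {
      g <- ctd_group_of(ch, p)
      unlist(lapply(1:3, function(grp) {
        pos <- which(g == grp)
        v <- if (length(pos) == 0) rep(0, 5) else {
          idx <- pmax(1, ceiling(qs * length(pos)))
          idx[1] <- 1
          pos[idx] / n * 100
        }
        stats::setNames(v, paste0("CTDD.", p, ".g", grp, ".",
                                  c("first", "p25", "p50", "p75", "p100")))
      }))
    }))
  })
}

# --- conjoint triads ---------------------------------------------------------
ctriad_class_of <- local({
  v <- integer(0)
  for (i in seq_along(CTRIAD_CLASSES)) v[CTRIAD_CLASSES[[i]]] <- i
  function(ch) unname(v[ch])
})

triad_names <- function(prefix) {
  g <- expand.grid(k = 1:7, j = 1:7, i = 1:7)
  paste0(prefix, ".", g$i, ".", g$j, ".", g$k)
}

triad_count <- function(ch, gap) {
  n <- length(ch)
  i <- seq_len(n - 2 * (gap + 1))
  if (length(i) == 0) stop("sequence too short for triad gap ", gap)
  cls <- ctriad_class_of(ch)
  key <- (cls[i] - 1) * 49 + (cls[i + gap + 1] - 1) * 7 + cls[i + 2 * (gap + 1)]
  count_on(key, 1:343)
}

pf_ctriad <- function(seqs, type = 1, ...) {
  nm <- triad_names("CTriad")
  per_seq(seqs, function(s) {
    cnt <- triad_count(chars(s), 0)
    v <- if (type == 1) cnt / sum(cnt) else cnt
    stats::setNames(v, nm)
  })
}

pf_ksctriad <- function(seqs, kmax = 1, type = 1, ...) {
  per_seq(seqs, function(s) {
    ch <- chars(s)
    unlist(lapply(0:kmax, function(k) {
      cnt <- triad_count(ch, k)
      v <- if (type == 1) cnt / sum(cnt) else cnt
      stats::setNames(v, paste0("KSCTriad.k", k, ".", triad_names("t")))
    }))
  })
}

# --- grouped compositions ----------------------------------------------------
G5 <- names(AA_GROUPS5)

group5_of <- function(ch) aa_group5_of[match(ch, AA20)]

pf_gaac <- function(seqs, ...) {
  per_seq(seqs, function(s) {
    g <- group5_of(chars(s))
    stats::setNames(count_on(g, G5) / length(g), paste0("GAAC.", G5))
  })
}

pf_egaac <- function(seqs, window = 5, ...) {
  check_equal_lengths(seqs)
  L <- nchar(seqs$seq[[1]])
  if (L < window) stop("sequences shorter than EGAAC window ", window)
  per_seq(seqs, function(s) {
    g <- group5_of(chars(s))
    unlist(lapply(seq_len(L - window + 1), function(i) {
      stats::setNames(count_on(g[i:(i + window - 1)], G5) / window,
                      paste0("EGAAC.w", i, ".", G5))
    }))
  })
}

gpairs <- as.vector(outer(G5, G5, paste, sep = "-"))

pf_cksaagp <- function(seqs, gap = 3, ...) {
  per_seq(seqs, function(s) {
    g <- group5_of(chars(s))
    n <- length(g)
    if (n < gap + 2) stop("sequence too short for CKSAAGP gap ", gap)
    unlist(lapply(0:gap, function(k) {
      i <- seq_len(n - k - 1)
      p <- paste(g[i], g[i + k + 1], sep = "-")
      stats::setNames(count_on(p, gpairs) / length(i),
                      paste0("CKSAAGP.g", k, ".", gpairs))
    }))
  })
}

pf_gdpc <- function(seqs, ...) {
  per_seq(seqs, function(s) {
    g <- group5_of(chars(s))
    if (length(g) < 2) stop("sequence too short for GDPC")
    p <- paste(g[-length(g)], g[-1], sep = "-")
    stats::setNames(count_on(p, gpairs) / length(p), paste0("GDPC.", gpairs))
  })
}

pf_gtpc <- function(seqs, ...) {
  gt <- as.vector(outer(gpairs, G5, paste, sep = "-"))
  per_seq(seqs, function(s) {
    g <- group5_of(chars(s))
    n <- length(g) - 2
    if (n < 1) stop("sequence too short for GTPC")
    p <- paste(g[seq_len(n)], g[seq_len(n) + 1], g[seq_len(n) + 2], sep = "-")
    stats::setNames(count_on(p, gt) / n, paste0("GTPC.", gt))
  })
}

check_equal_lengths <- function(seqs) {
  if (length(unique(nchar(seqs$seq))) > 1) {
    stop("this descriptor requires equal-length sequences")
  }
  invisible(TRUE)
}
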