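# Nucleotide composition-type descriptors.
#
# All computation runs over the canonical ACGT alphabet (RNA sequences are
# held internally with U and transliterated here); feature names present U
# for RNA.

nuc_chars <- function(s) chars(gsub("U", "T", s, fixed = TRUE))

present_kmer <- function(km, kind) {
  if (kind == "rna") gsub("T", "U", km, fixed = TRUE) else km
}

seq_kmers <- function(ch, k) {
  n <- length(ch)
  if (n < k) stop("sequence shorter than k = ", k)
  i <- seq_len(n - k + 1)
  out <- ch[i]
  if (k > 1) for (j in 1:(k - 1)) out <- paste0(out, ch[i + j])
  out
}

nf_kmer <- function(seqs, k = 3, type = 1, ...) {
  kind <- seq_kind(seqs)
  km <- all_kmers(k)
  per_seq(seqs, function(s) {
    w <- seq_kmers(nuc_chars(s), k)
    cnt <- count_on(w, km)
    v <- if (type == 1) cnt / length(w) else cnt
    stats::setNames(v, paste0("Kmer", k, ".", present_kmer(km, kind)))
  })
}

revcomp <- function(km) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(km, function(x) {
    paste(rev(comp[chars(x)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

canonical_kmers <- function(k) {
  km <- all_kmers(k)
  pmin(km, revcomp(km))
}

nf_rckmer <- function(seqs, k = 3, type = 1, ...) {
  kind <- seq_kind(seqs)
  canon <- canonical_kmers(k)
  lv <- sort(unique(canon))
  per_seq(seqs, function(s) {
    w <- seq_kmers(nuc_chars(s), k)
    wc <- canon[match(w, all_kmers(k))]
    cnt <- count_on(wc, lv)
    v <- if (type == 1) cnt / length(w) else cnt
    stats::setNames(v, paste0("RCKmer", k, ".", present_kmer(lv, kind)))
  })
}

nf_nac <- function(seqs, ...) nf_kmer(seqs, k = 1, ...)

nf_enac <- function(seqs, window = 5, ...) {
  kind <- seq_kind(seqs)
  check_equal_lengths(seqs)
  L <- nchar(seqs$seq[[1]])
  if (L < window) stop("sequences shorter than ENAC window ", window)
  alpha <- present_kmer(DNA4, kind)
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    unlist(lapply(seq_len(L - window + 1), function(i) {
      stats::setNames(count_on(ch[i:(i + window - 1)], DNA4) / window,
                      paste0("ENAC.w", i, ".", alpha))
    }))
  })
}

# occurrences of each k-mer pattern within m substitutions
nf_mismatch <- function(seqs, k = 3, m = 1, ...) {
  kind <- seq_kind(seqs)
  km <- all_kmers(k)
  kmat <- do.call(rbind, strsplit(km, ""))
  per_seq(seqs, function(s) {
    w <- seq_kmers(nuc_chars(s), k)
    wmat <- do.call(rbind, strsplit(w, ""))
    cnt <- vapply(seq_len(nrow(kmat)), function(p) {
      d <- rowSums(wmat != matrix(kmat[p, ], nrow(wmat), k, byrow = TRUE))
      sum(d <= m)
    }, numeric(1))
    stats::setNames(cnt / length(w), paste0("Mismatch", k, "m", m, ".",
                                            present_kmer(km, kind)))
  })
}

# counts of (possibly gapped) length-k subsequences, decay delta per gap
nf_subsequence <- function(seqs, k = 2, delta = 1, ...) {
  kind <- seq_kind(seqs)
  km <- all_kmers(k)
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    n <- length(ch)
    if (n < k) stop("sequence shorter than k")
    acc <- stats::setNames(numeric(length(km)), km)
    if (k == 2) {
      for (i in seq_len(n - 1)) {
        j <- (i + 1):n
        wt <- delta^(j - i - 1)
        key <- paste0(ch[i], ch[j])
        for (u in unique(key)) acc[u] <- acc[u] + sum(wt[key == u])
      }
    } else {
      idx <- utils::combn(n, k)
      wt <- delta^(idx[k, ] - idx[1, ] - (k - 1))
      key <- apply(idx, 2, function(ii) paste(ch[ii], collapse = ""))
      for (u in unique(key)) acc[u] <- acc[u] + sum(wt[key == u])
    }
    tot <- sum(acc)
    stats::setNames(if (tot > 0) acc / tot else acc,
                    paste0("Subseq", k, ".", present_kmer(km, kind)))
  })
}

nf_cksnap <- function(seqs, gap = 3, type = 1, ...) {
  kind <- seq_kind(seqs)
  np <- as.vector(outer(DNA4, DNA4, paste0))
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    n <- length(ch)
    if (n < gap + 2) stop("sequence too short for CKSNAP gap ", gap)
    unlist(lapply(0:gap, function(g) {
      i <- seq_len(n - g - 1)
      p <- paste0(ch[i], ch[i + g + 1])
      cnt <- count_on(p, np)
      v <- if (type == 1) cnt / length(i) else cnt
      stats::setNames(v, paste0("CKSNAP.g", g, ".", present_kmer(np, kind)))
    }))
  })
}

# --- positional encodings ----------------------------------------------------
nf_binary <- function(seqs, ...) {
  kind <- seq_kind(seqs)
  check_equal_lengths(seqs)
  alpha <- present_kmer(DNA4, kind)
  encode_nuc(seqs, alpha, function(ch) one_hot(ch, DNA4), "binary")
}

encode_nuc <- function(seqs, width_names, row_fn, prefix) {
  L <- nchar(seqs$seq[[1]])
  m <- do.call(rbind, lapply(seqs$seq, function(s) as.vector(t(row_fn(nuc_chars(s))))))
  npos <- ncol(m) / length(width_names)
  colnames(m) <- as.vector(t(outer(paste0(prefix, ".p", seq_len(npos)),
                                   width_names, paste, sep = ".")))
  rownames(m) <- seqs$id
  m
}

# position-specific k-mer one-hot (PS2/PS3/PS4 for k = 2..4)
nf_ps_k <- function(seqs, k, ...) {
  kind <- seq_kind(seqs)
  check_equal_lengths(seqs)
  km <- all_kmers(k)
  if (nchar(seqs$seq[[1]]) < k) stop("sequences shorter than k")
  encode_nuc(seqs, present_kmer(km, kind), function(ch) {
    one_hot(seq_kmers(ch, k), km)
  }, paste0("PS", k))
}

nf_ncp <- function(seqs, ...) {
  check_equal_lengths(seqs)
  encode_nuc(seqs, c("ring", "fgroup", "hbond"),
             function(ch) NCP_CODE[ch, , drop = FALSE], "NCP")
}

# accumulated nucleotide frequency: freq of seq[i] within seq[1..i]
nf_anf <- function(seqs, ...) {
  check_equal_lengths(seqs)
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    v <- vapply(seq_along(ch), function(i) sum(ch[1:i] == ch[i]) / i, numeric(1))
    stats::setNames(v, paste0("ANF.p", seq_along(ch)))
  })
}

# dinucleotide binary encoding: adjacent pair one-hot
nf_dbe <- function(seqs, ...) {
  kind <- seq_kind(seqs)
  check_equal_lengths(seqs)
  np <- all_kmers(2)
  if (nchar(seqs$seq[[1]]) < 2) stop("sequences shorter than 2")
  encode_nuc(seqs, present_kmer(np, kind),
             function(ch) one_hot(seq_kmers(ch, 2), np), "DBE")
}

# --- EIIP --------------------------------------------------------------------
nf_eiip <- function(seqs, ...) {
  check_equal_lengths(seqs)
  per_seq(seqs, function(s) {
    ch <- nuc_chars(s)
    stats::setNames(unname(EIIP[ch]), paste0("EIIP.p", seq_along(ch)))
  })
}

nf_pseeiip <- function(seqs, ...) {
  kind <- seq_kind(seqs)
  tri <- all_kmers(3)
  esum <- vapply(tri, function(t) sum(EIIP[chars(t)]), numeric(1))
  per_seq(seqs, function(s) {
    w <- seq_kmers(nuc_chars(s), 3)
    f <- count_on(w, tri) / length(w)
    stats::setNames(f * esum, paste0("PseEIIP.", present_kmer(tri, kind)))
  })
}

# --- physicochemical-property weighted compositions --------------------------
nf_pcp <- function(seqs, order = 2, type = 1, ...) {
  kind <- seq_kind(seqs)
  tab <- nuc_prop_table(kind, order)
  km <- colnames(tab)
  label <- if (order == 2) "DPCP" else "TPCP"
  per_seq(seqs, function(s) {
    w <- seq_kmers(nuc_chars(s), order)
    cnt <- count_on(w, km)
    f <- if (type == 1) cnt / length(w) else cnt
    out <- as.vector(tab * rep(f, each = nrow(tab)))
    stats::setNames(out, paste0(label, ".", rep(present_kmer(km, kind),
                                                each = nrow(tab)),
                                ".", rownames(tab)))
  })
}

# --- position-specific trinucleotide propensity ------------------------------
# Needs labelled, equal-length sets with exactly two classes; features are
# per-position propensity differences between classes.
nf_pstnp <- function(seqs, double_strand = FALSE, ...) {
  check_equal_lengths(seqs)
  lab <- seqs$label
  if (any(is.na(lab))) stop("PSTNP requires labelled sequences")
  cls <- sort(unique(lab))
  if (length(cls) != 2) stop("PSTNP requires exactly two classes")
  tri <- all_kmers(3)
  key_of <- function(w) {
    if (double_strand) pmin(w, revcomp(w)) else w
  }
  L <- nchar(seqs$seq[[1]])
  if (L < 3) stop("sequences shorter than 3")
  wins <- lapply(seqs$seq, function(s) key_of(seq_kmers(nuc_chars(s), 3)))
  wmat <- do.call(rbind, wins)
  lv <- if (double_strand) sort(unique(pmin(tri, revcomp(tri)))) else tri
  z <- sapply(seq_len(L - 2), function(p) {
    fpos <- count_on(wmat[lab == cls[[2]], p], lv) / sum(lab == cls[[2]])
    fneg <- count_on(wmat[lab == cls[[1]], p], lv) / sum(lab == cls[[1]])
    d <- fpos - fneg
    d[match(wmat[, p], lv)]
  })
  z <- matrix(z, nrow = nrow(seqs))
  colnames(z) <- paste0(if (double_strand) "PSTNPds.p" else "PSTNPss.p",
                        seq_len(ncol(z)))
  rownames(z) <- seqs$id
  z
}
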