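# The 14 ligand descriptor blocks. Dimensions are pinned by this roster;
# formulas that degenerate on single-atom molecules return 0.

LIGAND_BLOCKS <- c("constitution", "topology", "connectivity", "kappa",
                   "estate", "basak", "burden", "pharmacophore",
                   "moran", "geary", "moreau_broto", "charge", "property",
                   "moe")
LIGAND_FP_FAMILIES <- c("maccs", "morgan", "estate_fp", "topological_fp")

atom_prop <- function(mol, what) {
  p <- ATOMIC_PROPS[mol$atoms$element, what]
  p[is.na(p)] <- stats::median(ATOMIC_PROPS[[what]])
  p
}

lf_constitution <- function(mol, ...) {
  a <- mol$atoms; b <- mol$bonds
  el <- a$element
  halogens <- c("F", "Cl", "Br", "I")
  nH_total <- sum(a$nH)
  mw <- sum(ATOMIC_PROPS[el, "mass"], na.rm = TRUE) + nH_total * 1.008
  hbd <- sum(el %in% c("N", "O") & a$nH > 0)
  hba <- sum(el %in% c("N", "O"))
  rot <- 0
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      if (b$order[k] == 1 && !b$aromatic[k] &&
          mol$atoms$degree[b$a[k]] > 1 && mol$atoms$degree[b$b[k]] > 1) {
        g2 <- igraph::delete_edges(mol$graph, k)
        if (!is.finite(igraph::distances(g2, v = b$a[k], to = b$b[k]))) rot <- rot + 1
      }
    }
  }
  c(nAtom = mol$n_heavy + nH_total, nHeavy = mol$n_heavy,
    nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
    nS = sum(el == "S"), nP = sum(el == "P"), nHal = sum(el %in% halogens),
    nH = nH_total, nBond = nrow(b),
    nSingle = sum(b$order == 1 & !b$aromatic), nDouble = sum(b$order == 2),
    nTriple = sum(b$order == 3), nAromBond = sum(b$aromatic),
    nRing = ring_count(mol), nRotB = rot, HBD = hbd, HBA = hba,
    MW = mw, AMW = mw / max(1, mol$n_heavy + nH_total))
}

lf_topology <- function(mol, ...) {
  n <- mol$n_heavy
  zero <- c(Wiener = 0, WienerPol = 0, Zagreb1 = 0, Zagreb2 = 0, Platt = 0,
            Harary = 0, BalabanJ = 0, Radius = 0, Diameter = 0, Petitjean = 0)
  if (n < 2 || nrow(mol$bonds) == 0) return(zero)
  d <- mol_dist(mol)
  fin <- is.finite(d) & upper.tri(d)
  deg <- mol$atoms$degree
  w <- sum(d[fin])
  wp <- sum(d[fin] == 3)
  z1 <- sum(deg^2)
  z2 <- sum(deg[mol$bonds$a] * deg[mol$bonds$b])
  platt <- sum(deg[mol$bonds$a] + deg[mol$bonds$b] - 2)
  harary <- sum(1 / d[fin])
  ecc <- apply(ifelse(is.finite(d), d, NA), 1, max, na.rm = TRUE)
  rad <- min(ecc); diam <- max(ecc)
  s <- rowSums(ifelse(is.finite(d), d, 0))
  m <- nrow(mol$bonds)
  mu <- m - n + igraph::components(mol$graph)$no
  bj <- if (all(s[mol$bonds$a] * s[mol$bonds$b] > 0)) {
    m / (mu + 1) * sum(1 / sqrt(s[mol$bonds$a] * s[mol$bonds$b]))
  } else 0
  c(Wiener = w, WienerPol = wp, Zagreb1 = z1, Zagreb2 = z2, Platt = platt,
    Harary = harary, BalabanJ = bj, Radius = rad, Diameter = diam,
    Petitjean = if (rad > 0) (diam - rad) / rad else 0)
}

# valence electrons for the simple delta-v
VALENCE_E <- c(C = 4, N = 5, O = 6, F = 7, Cl = 7, Br = 7, I = 7,
               S = 6, P = 5, B = 3, Si = 4, H = 1)
ATOMIC_Z <- c(C = 6, N = 7, O = 8, F = 9, Cl = 17, Br = 35, I = 53,
              S = 16, P = 15, B = 5, Si = 14, H = 1)

chi_deltas <- function(mol) {
  el <- mol$atoms$element
  zv <- VALENCE_E[el]; z <- ATOMIC_Z[el]
  zv[is.na(zv)] <- 4; z[is.na(z)] <- 6
  delta <- mol$atoms$degree
  dv <- (zv - mol$atoms$nH) / pmax(1, z - zv - 1)
  dv[z <= 10] <- (zv - mol$atoms$nH)[z <= 10]
  list(delta = delta, dv = pmax(dv, 1e-6))
}

paths_up_to <- function(mol, maxlen) {
  # simple paths (vertex sequences) of edge-length 1..maxlen, undirected
  adj <- igraph::as_adj_list(mol$graph)
  out <- vector("list", maxlen)
  paths <- lapply(seq_len(mol$n_heavy), function(v) v)
  for (len in seq_len(maxlen)) {
    nxt <- list()
    for (p in paths) {
      last <- p[length(p)]
      for (nb in as.integer(adj[[last]])) {
        if (!(nb %in% p)) nxt[[length(nxt) + 1]] <- c(p, nb)
      }
    }
    # keep one direction only
    keep <- vapply(nxt, function(p) p[1] < p[length(p)] ||
                     (p[1] == p[length(p)]), logical(1))
    out[[len]] <- nxt[keep]
    paths <- nxt
    if (!length(nxt)) break
  }
  out
}

lf_connectivity <- function(mol, ...) {
  dl <- chi_deltas(mol)
  nm <- c(paste0("Chi", 0:4), paste0("Chiv", 0:4))
  out <- stats::setNames(numeric(10), nm)
  out["Chi0"] <- sum(1 / sqrt(pmax(dl$delta, 1)))
  out["Chiv0"] <- sum(1 / sqrt(dl$dv))
  if (nrow(mol$bonds) == 0) return(out)
  pths <- paths_up_to(mol, 4)
  for (len in 1:4) {
    ps <- pths[[len]]
    if (is.null(ps) || !length(ps)) next
    out[paste0("Chi", len)] <- sum(vapply(ps, function(p) {
      1 / sqrt(prod(pmax(dl$delta[p], 1)))
    }, numeric(1)))
    out[paste0("Chiv", len)] <- sum(vapply(ps, function(p) {
      1 / sqrt(prod(dl$dv[p]))
    }, numeric(1)))
  }
  out
}

lf_kappa <- function(mol, ...) {
  A <- mol$n_heavy
  out <- c(Kappa1 = 0, Kappa2 = 0, Kappa3 = 0,
           KappaA1 = 0, KappaA2 = 0, KappaA3 = 0, PhiKappa = 0)
  if (A < 2) return(out)
  pths <- paths_up_to(mol, 3)
  p1 <- length(pths[[1]]); p2 <- length(pths[[2]]); p3 <- length(pths[[3]])
  # covalent radius ratio alpha relative to sp3 carbon
  rcov <- c(C = 0.77, N = 0.74, O = 0.74, S = 1.04, P = 1.10, F = 0.72,
            Cl = 0.99, Br = 1.14, I = 1.33, B = 0.82, Si = 1.17)
  r <- rcov[mol$atoms$element]; r[is.na(r)] <- 0.77
  alpha <- sum(r / 0.77 - 1)
  k1 <- if (p1 > 0) A * (A - 1)^2 / p1^2 else 0
  k2 <- if (p2 > 0 && A > 2) (A - 1) * (A - 2)^2 / p2^2 else 0
  k3 <- if (p3 > 0 && A > 3) {
    if (A %% 2 == 1) (A - 1) * (A - 3)^2 / p3^2 else (A - 3) * (A - 2)^2 / p3^2
  } else 0
  ka1 <- if (p1 + alpha > 0) (A + alpha) * (A + alpha - 1)^2 / (p1 + alpha)^2 else 0
  ka2 <- if (p2 + alpha > 0 && A > 2) (A + alpha - 1) * (A + alpha - 2)^2 / (p2 + alpha)^2 else 0
  ka3 <- if (p3 + alpha > 0 && A > 3) {
    if (A %% 2 == 1) (A + alpha - 1) * (A + alpha - 3)^2 / (p3 + alpha)^2
    else (A + alpha - 3) * (A + alpha - 2)^2 / (p3 + alpha)^2
  } else 0
  c(Kappa1 = k1, Kappa2 = k2, Kappa3 = k3, KappaA1 = ka1, KappaA2 = ka2,
    KappaA3 = ka3, PhiKappa = ka1 * ka2 / A)
}

estate_values <- function(mol) {
  dl <- chi_deltas(mol)
  z <- ATOMIC_Z[mol$atoms$element]; z[is.na(z)] <- 6
  pqn <- ifelse(z <= 2, 1, ifelse(z <= 10, 2, ifelse(z <= 18, 3,
                ifelse(z <= 36, 4, 5))))
  intr <- ((2 / pqn)^2 * dl$dv + 1) / pmax(dl$delta, 1)
  if (mol$n_heavy == 1) return(intr)
  d <- mol_dist(mol)
  pert <- vapply(seq_len(mol$n_heavy), function(i) {
    j <- setdiff(seq_len(mol$n_heavy), i)
    fin <- is.finite(d[i, j])
    sum(((intr[i] - intr[j]) / (d[i, j] + 1)^2)[fin])
  }, numeric(1))
  intr + pert
}

lf_estate <- function(mol, ...) {
  s <- estate_values(mol)
  el <- mol$atoms$element
  c(Ssum = sum(s), Smax = max(s), Smin = min(s), Smean = mean(s),
    Srange = max(s) - min(s),
    SsumC = sum(s[el == "C"]), SsumN = sum(s[el == "N"]),
    SsumO = sum(s[el == "O"]), SsumS = sum(s[el == "S"]),
    SsumHet = sum(s[!el %in% "C"]))
}

shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

lf_basak <- function(mol, ...) {
  # neighbourhood-class information indices; hydrogens included as classes
  el_all <- c(mol$atoms$element, rep("H", sum(mol$atoms$nH)))
  nAll <- length(el_all)
  cls0 <- el_all
  adj <- igraph::as_adj_list(mol$graph)
  cls_heavy <- mol$atoms$element
  refine <- function(cls) {
    vapply(seq_len(mol$n_heavy), function(i) {
      nbs <- sort(c(cls[as.integer(adj[[i]])], rep("H", mol$atoms$nH[i])))
      paste(cls[i], paste(nbs, collapse = ","), sep = "|")
    }, character(1))
  }
  ics <- function(cls_h) {
    # heavy atoms by refined class; hydrogens keep a single class
    cnt <- c(table(cls_h), H = sum(mol$atoms$nH))
    cnt <- cnt[cnt > 0]
    ic <- shannon(cnt)
    c(ic, if (nAll > 1) ic / log2(nAll) else 0, log2(max(nAll, 1)) - ic)
  }
  c0 <- ics(cls_heavy)
  cls1 <- refine(cls_heavy)
  c1 <- ics(cls1)
  cls2 <- refine(cls1)
  c2 <- ics(cls2)
  stats::setNames(c(c0, c1, c2),
                  paste0(rep(c("IC", "SIC", "CIC"), 3),
                         rep(0:2, each = 3)))
}

lf_burden <- function(mol, ...) {
  props <- c("mass", "electronegativity", "vdw_volume", "polarizability")
  out <- c()
  n <- mol$n_heavy
  for (p in props) {
    v <- atom_prop(mol, p)
    B <- matrix(0.001, n, n)
    diag(B) <- v / max(abs(v))
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
      B[a, b] <- B[b, a] <- mol$bonds$order[k] * 0.1
    }
    ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
    lo <- c(ev[1], if (n > 1) ev[2] else 0)
    hi <- c(ev[n], if (n > 1) ev[n - 1] else 0)
    out <- c(out, stats::setNames(c(hi, lo),
             paste0("BCUT.", p, c(".hi1", ".hi2", ".lo1", ".lo2"))))
  }
  out
}

lf_autocorrelation <- function(mol, variant, nlag = 8, ...) {
  props <- c("mass", "electronegativity", "vdw_volume", "polarizability")
  d <- mol_dist(mol)
  out <- c()
  for (p in props) {
    v <- atom_prop(mol, p)
    v <- (v - mean(v))
    sq <- mean(v^2)
    for (k in seq_len(nlag)) {
      pairs <- which(d == k, arr.ind = TRUE)  # ordered pairs, both directions
      val <- if (nrow(pairs) == 0) 0 else {
        switch(variant,
          moreau_broto = {
            raw <- atom_prop(mol, p)
            sum(raw[pairs[, 1]] * raw[pairs[, 2]])
          },
          moran = if (sq == 0) 0 else {
            (sum(v[pairs[, 1]] * v[pairs[, 2]]) / nrow(pairs)) / sq
          },
          geary = {
            denom <- sum(v^2) / max(1, (mol$n_heavy - 1))
            if (denom == 0) 0 else {
              sum((v[pairs[, 1]] - v[pairs[, 2]])^2) / (2 * nrow(pairs)) / denom
            }
          })
      }
      out <- c(out, stats::setNames(val, paste0(toupper(substr(variant, 1, 2)),
                                                ".", p, ".lag", k)))
    }
  }
  out
}

lf_charge <- function(mol, ...) {
  q <- mol$atoms$charge_h
  qpos <- q[q > 0]; qneg <- q[q < 0]
  bdiff <- if (nrow(mol$bonds)) {
    abs(q[mol$bonds$a] - q[mol$bonds$b])
  } else 0
  c(QposMax = if (length(qpos)) max(qpos) else 0,
    QnegMax = if (length(qneg)) min(qneg) else 0,
    QposSum = sum(qpos), QnegSum = sum(qneg),
    QabsSum = sum(abs(q)), QabsMean = mean(abs(q)),
    RelPos = if (sum(qpos) > 0) max(qpos) / sum(qpos) else 0,
    RelNeg = if (sum(qneg) < 0) min(qneg) / sum(qneg) else 0,
    LocalDipole = mean(bdiff),
    QRange = max(q) - min(q))
}

lf_property <- function(mol, sdf_one, ...) {
  p <- ChemmineR::propOB(sdf_one)
  c(Prop.logP = p$logP, Prop.MR = p$MR, Prop.MW = p$MW, Prop.TPSA = p$TPSA,
    Prop.HBA1 = p$HBA1, Prop.HBA2 = p$HBA2, Prop.HBD = p$HBD, Prop.nF = p$nF)
}

# per-atom accessible-surface proxy used by the VSA bins
atom_vsa <- function(mol) {
  r <- VDW_RADII[mol$atoms$element]
  r[is.na(r)] <- 1.7
  area <- 4 * pi * r^2
  shielding <- pmin(0.9, 0.2 * (mol$atoms$degree + mol$atoms$nH))
  area * (1 - shielding)
}

lf_moe <- function(mol, ...) {
  vsa <- atom_vsa(mol)
  q <- mol$atoms$charge
  s <- estate_values(mol)
  qb <- c(-Inf, -0.3, -0.1, 0, 0.1, 0.3, Inf)
  sb <- c(-Inf, 0, 1, 2, 5, 10, Inf)
  qbin <- vapply(seq_len(6), function(k) {
    sum(vsa[q > qb[k] & q <= qb[k + 1]])
  }, numeric(1))
  sbin <- vapply(seq_len(6), function(k) {
    sum(vsa[s > sb[k] & s <= sb[k + 1]])
  }, numeric(1))
  stats::setNames(c(qbin, sbin),
                  c(paste0("PEOE.VSA", 1:6), paste0("EState.VSA", 1:6)))
}

lf_pharmacophore <- function(mols_sdf, ...) {
  out <- sapply(names(PHARMACOPHORE_SMARTS), function(nm) {
    as.numeric(ChemmineR::smartsSearchOB(mols_sdf, PHARMACOPHORE_SMARTS[[nm]],
                                         uniqueMatches = TRUE))
  })
  m <- matrix(out, nrow = length(mols_sdf))
  colnames(m) <- paste0("Pharm.", names(PHARMACOPHORE_SMARTS))
  m
}

#' Compute one ligand descriptor block or fingerprint family
#'
#' @param mols an `omega_mols` object from [read_molecules()].
#' @param descriptor one of the 18 registered ligand sets (see
#'   `list_descriptors("ligand")`).
#' @param ... block parameters (`nlag` for autocorrelations, `nbits`/`radius`
#'   for the circular fingerprint).
#' @return a feature tibble (one row per molecule).
#' @export
calc_ligand_features <- function(mols, descriptor, ...) {
  stopifnot(inherits(mols, "omega_mols"))
  if (descriptor %in% LIGAND_FP_FAMILIES) {
    return(ligand_fingerprints(mols, descriptor, ...))
  }
  if (!descriptor %in% LIGAND_BLOCKS) stop("unknown ligand block: ", descriptor)
  if (descriptor == "pharmacophore") {
    m <- lf_pharmacophore(mols$sdf, ...)
    rownames(m) <- mols$ids
    return(feature_tbl(m, mols$ids))
  }
  rows <- lapply(seq_along(mols$ids), function(i) {
    mol <- mols$graphs[[i]]
    switch(descriptor,
      constitution = lf_constitution(mol, ...),
      topology = lf_topology(mol, ...),
      connectivity = lf_connectivity(mol, ...),
      kappa = lf_kappa(mol, ...),
      estate = lf_estate(mol, ...),
      basak = lf_basak(mol, ...),
      burden = lf_burden(mol, ...),
      moran = lf_autocorrelation(mol, "moran", ...),
      geary = lf_autocorrelation(mol, "geary", ...),
      moreau_broto = lf_autocorrelation(mol, "moreau_broto", ...),
      charge = lf_charge(mol, ...),
      property = lf_property(mol, mols$sdf[i], ...),
      moe = lf_moe(mol, ...))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- mols$ids
  feature_tbl(m, mols$ids)
}
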