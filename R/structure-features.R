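# The 14 structure descriptor sets: shell microenvironments (residue /
# grouped-residue / secondary-structure / atom composition, per-shell and
# cumulative), half-sphere exposure, residue depth, and contact-network
# indices.

STRUCTURE_DESCRIPTORS <- c(
  "AAC_type1", "AAC_type2", "GAAC_type1", "GAAC_type2",
  "SS3_type1", "SS3_type2", "SS8_type1", "SS8_type2",
  "HSE_CB", "HSE_pseudoCB", "Residue_depth", "AC_type1", "AC_type2",
  "Network")

# --- shell algebra -----------------------------------------------------------
# shell s covers [r0 + (s-1)*delta, r0 + s*delta) -- half-open outer bound
shell_index <- function(d, r0, delta, nshell) {
  s <- floor((d - r0) / delta) + 1
  s[d < r0 | s > nshell] <- NA
  s
}

shell_composition <- function(centers, points, categories, levels,
                              r0 = 0, delta = 2, nshell = 15,
                              cumulative = FALSE, exclude = NULL,
                              prefix = "shell") {
  out <- matrix(0, nrow(centers), nshell * length(levels))
  colnames(out) <- paste0(prefix, ".s", rep(seq_len(nshell), each = length(levels)),
                          ".", rep(levels, nshell))
  for (t in seq_len(nrow(centers))) {
    keep <- seq_len(nrow(points))
    if (!is.null(exclude) && !is.na(exclude[t])) keep <- keep[keep != exclude[t]]
    d <- sqrt(colSums((t(points[keep, , drop = FALSE]) - centers[t, ])^2))
    s <- shell_index(d, r0, delta, nshell)
    cnt <- matrix(0, nshell, length(levels))
    ok <- !is.na(s)
    if (any(ok)) {
      tab <- table(factor(s[ok], levels = seq_len(nshell)),
                   factor(categories[keep][ok], levels = levels))
      cnt <- unclass(tab)
    }
    if (cumulative) cnt <- apply(cnt, 2, cumsum)
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = nshell)
    tot <- rowSums(cnt)
    freq <- cnt / ifelse(tot > 0, tot, 1)
    out[t, ] <- as.vector(t(freq))
  }
  out
}

sf_shell_residue <- function(model, targets = NULL, grouping = c("aa", "group5"),
                             cumulative = FALSE, r0 = 0, delta = 2, nshell = 15, ...) {
  grouping <- match.arg(grouping)
  tg <- resolve_targets(model, targets)
  ca <- res_coords(model)
  aa <- model$residues$aa1
  if (grouping == "aa") {
    lv <- AA20; cats <- aa; pre <- if (cumulative) "AAC.t2" else "AAC.t1"
  } else {
    lv <- G5; cats <- group5_of(aa); pre <- if (cumulative) "GAAC.t2" else "GAAC.t1"
  }
  m <- shell_composition(tg$centers, ca, cats, lv, r0, delta, nshell,
                         cumulative, exclude = tg$idx, prefix = pre)
  rownames(m) <- tg$ids
  m
}

# --- secondary structure -----------------------------------------------------
# Classic electrostatic hydrogen-bond model: E = 0.084 * 332 *
# (1/rON + 1/rCH - 1/rOH - 1/rCN); bond when E < -0.5 kcal/mol.
# Amide H approximated 1 A from N opposite the preceding carbonyl.
backbone_hbonds <- function(model) {
  r <- model$residues
  n <- nrow(r)
  Np <- res_coords(model, "n"); Ca <- res_coords(model, "ca")
  Cp <- res_coords(model, "c"); Op <- res_coords(model, "o")
  Hp <- matrix(NA_real_, n, 3)
  for (j in 2:n) {
    if (!anyNA(c(Np[j, ], Cp[j - 1, ], Op[j - 1, ]))) {
      Hp[j, ] <- Np[j, ] + vunit(Cp[j - 1, ] - Op[j - 1, ])
    }
  }
  hb <- matrix(FALSE, n, n)  # hb[i, j]: CO(i) -> NH(j)
  for (i in 1:n) {
    if (anyNA(c(Cp[i, ], Op[i, ]))) next
    for (j in 1:n) {
      if (abs(i - j) < 2 || anyNA(c(Np[j, ], Hp[j, ]))) next
      if (r$resid[j] == "PRO") next
      rON <- vnorm(Op[i, ] - Np[j, ]); rCH <- vnorm(Cp[i, ] - Hp[j, ])
      rOH <- vnorm(Op[i, ] - Hp[j, ]); rCN <- vnorm(Cp[i, ] - Np[j, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) { hb[i, j] <- TRUE; next }
      E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- E < -0.5
    }
  }
  hb
}

#' Assign secondary structure
#'
#' Backbone hydrogen bonds are detected with the classic electrostatic
#' energy model and converted to 8-state labels (H, G, I = 4/3/5-turn
#' helices; E/B = extended bridges; T = turn; S = bend; '-' otherwise),
#' plus the 3-state collapse (H,G,I -> H; E,B -> E; rest -> C).
#'
#' @param model an `omega_structure`.
#' @return tibble with columns `id`, `ss8`, `ss3`.
#' @export
assign_secondary_structure <- function(model) {
  r <- model$residues
  n <- nrow(r)
  ss <- rep("-", n)
  missing_bb <- is.na(r$n_x) | is.na(r$ca_x) | is.na(r$c_x) | is.na(r$o_x)
  if (n >= 4) {
    hb <- backbone_hbonds(model)
    turn <- function(k) {
      t <- rep(FALSE, n)
      i <- seq_len(max(0, n - k))
      t[i] <- hb[cbind(i, i + k)]
      t
    }
    t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
    helix_from_turns <- function(t, k) {
      h <- rep(FALSE, n)
      for (i in 2:n) {
        if (t[i - 1] && t[i]) h[i:min(n, i + k - 1)] <- TRUE
      }
      h
    }
    h4 <- helix_from_turns(t4, 4)
    h3 <- helix_from_turns(t3, 3)
    h5 <- helix_from_turns(t5, 5)
    # bridges
    bridge <- rep(FALSE, n)
    partner <- rep(NA_integer_, n)
    for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
      if (abs(i - j) <= 2) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) { bridge[i] <- TRUE; partner[i] <- j }
    }
    ext <- bridge & (c(FALSE, bridge[-n]) | c(bridge[-1], FALSE))
    # bends: CA direction change > 70 degrees
    bend <- rep(FALSE, n)
    Ca <- res_coords(model)
    for (i in 3:(n - 2)) {
      if (anyNA(c(Ca[i - 2, ], Ca[i, ], Ca[i + 2, ]))) next
      v1 <- Ca[i, ] - Ca[i - 2, ]; v2 <- Ca[i + 2, ] - Ca[i, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2)))))
      bend[i] <- ang > 70 * pi / 180
    }
    turn_any <- rep(FALSE, n)
    for (k in 3:5) {
      tk <- turn(k)
      for (i in which(tk)) turn_any[(i + 1):min(n, i + k - 1)] <- TRUE
    }
    ss[bend] <- "S"
    ss[turn_any] <- "T"
    ss[h5] <- "I"
    ss[h3] <- "G"
    ss[ext] <- "E"
    ss[bridge & !ext] <- "B"
    ss[h4] <- "H"
  }
  ss[missing_bb] <- "-"
  ss3 <- ifelse(ss %in% c("H", "G", "I"), "H",
                ifelse(ss %in% c("E", "B"), "E", "C"))
  tibble::tibble(id = residue_ids(model), ss8 = ss, ss3 = ss3)
}

sf_shell_ss <- function(model, targets = NULL, states = 3, cumulative = FALSE,
                        r0 = 0, delta = 2, nshell = 15, ...) {
  tg <- resolve_targets(model, targets)
  ssa <- assign_secondary_structure(model)
  if (states == 3) {
    lv <- c("H", "E", "C"); cats <- ssa$ss3
  } else {
    lv <- c("H", "B", "E", "G", "I", "T", "S", "-"); cats <- ssa$ss8
  }
  pre <- paste0("SS", states, if (cumulative) ".t2" else ".t1")
  m <- shell_composition(tg$centers, res_coords(model), cats, lv,
                         r0, delta, nshell, cumulative, exclude = tg$idx,
                         prefix = pre)
  rownames(m) <- tg$ids
  m
}

# --- half-sphere exposure ----------------------------------------------------
sf_hse <- function(model, variant = c("cb", "pseudo_cb"), radius = 13, ...) {
  variant <- match.arg(variant)
  r <- model$residues
  ca <- res_coords(model)
  dir <- if (variant == "cb") {
    cbind(r$cb_x - r$ca_x, r$cb_y - r$ca_y, r$cb_z - r$ca_z)
  } else {
    t(vapply(seq_len(nrow(r)), function(i) {
      if (anyNA(c(r$n_x[i], r$c_x[i]))) return(c(NA_real_, NA_real_, NA_real_))
      pseudo_cb(c(r$n_x[i], r$n_y[i], r$n_z[i]), ca[i, ],
                c(r$c_x[i], r$c_y[i], r$c_z[i])) - ca[i, ]
    }, numeric(3)))
  }
  n <- nrow(ca)
  up <- down <- numeric(n)
  for (i in seq_len(n)) {
    if (anyNA(ca[i, ]) || anyNA(dir[i, ])) next
    d <- sqrt(colSums((t(ca) - ca[i, ])^2))
    nb <- which(d <= radius & seq_len(n) != i & !is.na(d))
    if (!length(nb)) next
    dots <- (ca[nb, , drop = FALSE] - matrix(ca[i, ], length(nb), 3, byrow = TRUE)) %*% dir[i, ]
    up[i] <- sum(dots > 0)
    down[i] <- length(nb) - up[i]
  }
  tag <- if (variant == "cb") "HSE.CB" else "HSE.pCB"
  m <- cbind(up, down)
  colnames(m) <- paste0(tag, c(".up", ".down"))
  rownames(m) <- residue_ids(model)
  m
}

# --- residue depth -----------------------------------------------------------
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Sampled solvent-accessible surface (Shrake-Rupley style): points on the
# probe-expanded sphere of each atom, minus points buried inside any other
# expanded sphere.
sas_points <- function(xyz, radii, probe = 1.4, n_points = 240) {
  sp <- sphere_points(n_points)
  n <- nrow(xyz)
  keep <- list()
  for (i in seq_len(n)) {
    pts <- sp * (radii[i] + probe)
    pts <- sweep(pts, 2, xyz[i, ], "+")
    ok <- rep(TRUE, nrow(pts))
    for (j in seq_len(n)) {
      if (j == i) next
      dj <- sqrt(colSums((t(pts) - xyz[j, ])^2))
      ok <- ok & dj >= (radii[j] + probe - 1e-9)
      if (!any(ok)) break
    }
    if (any(ok)) keep[[length(keep) + 1]] <- pts[ok, , drop = FALSE]
  }
  do.call(rbind, keep)
}

sf_residue_depth <- function(model, probe = 1.4, n_points = 240, ...) {
  at <- model$atoms
  xyz <- cbind(at$x, at$y, at$z)
  radii <- atom_radius(at$element)
  surf <- sas_points(xyz, radii, probe, n_points)
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  rkey <- paste(model$residues$chain, model$residues$resno,
                model$residues$insert, sep = "|")
  depth <- vapply(rkey, function(k) {
    ii <- which(key == k)
    mean(vapply(ii, function(a) {
      d <- sqrt(colSums((t(surf) - xyz[a, ])^2))
      max(0, min(d) - (radii[a] + probe))
    }, numeric(1)))
  }, numeric(1))
  m <- matrix(depth, ncol = 1, dimnames = list(residue_ids(model), "Depth"))
  m
}

# --- atom composition shells -------------------------------------------------
sf_shell_atoms <- function(model, targets = NULL, cumulative = FALSE,
                           r0 = 0, delta = 2, nshell = 15, ...) {
  tg <- resolve_targets(model, targets)
  at <- model$atoms
  lv <- c("C", "N", "O", "S", "other")
  cats <- ifelse(at$element %in% c("C", "N", "O", "S"), at$element, "other")
  pts <- cbind(at$x, at$y, at$z)
  # exclude the target residue's own atoms
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  rkey <- paste(model$residues$chain, model$residues$resno,
                model$residues$insert, sep = "|")
  pre <- paste0("AtomC", if (cumulative) ".t2" else ".t1")
  out <- matrix(0, nrow(tg$centers), nshell * length(lv))
  colnames(out) <- paste0(pre, ".s", rep(seq_len(nshell), each = length(lv)),
                          ".", rep(lv, nshell))
  for (t in seq_len(nrow(tg$centers))) {
    keep <- seq_len(nrow(pts))
    if (!is.na(tg$idx[t])) keep <- keep[key != rkey[tg$idx[t]]]
    m1 <- shell_composition(tg$centers[t, , drop = FALSE],
                            pts[keep, , drop = FALSE], cats[keep], lv,
                            r0, delta, nshell, cumulative, prefix = pre)
    out[t, ] <- m1
  }
  rownames(out) <- tg$ids
  out
}

# --- contact-network indices -------------------------------------------------
sf_network <- function(model, cutoff = 8, ...) {
  ca <- res_coords(model)
  n <- nrow(ca)
  nm <- c("degree", "degree_centrality", "betweenness", "clustering",
          "closeness", "eigenvector")
  if (n == 1) {
    m <- matrix(0, 1, 6, dimnames = list(residue_ids(model), paste0("Net.", nm)))
    return(m)
  }
  d <- as.matrix(stats::dist(ca))
  adj <- (d <= cutoff) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, normalized = TRUE)
  clu <- igraph::transitivity(g, type = "local", isolates = "zero")
  # component-aware closeness (improved formula)
  sp <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    dd <- sp[i, -i]
    reach <- dd[is.finite(dd)]
    if (!length(reach)) return(0)
    (length(reach) / sum(reach)) * (length(reach) / (n - 1))
  }, numeric(1))
  eig <- if (igraph::ecount(g) > 0) {
    igraph::eigen_centrality(g)$vector
  } else rep(0, n)
  m <- cbind(deg, deg / (n - 1), btw, clu, clo, eig)
  colnames(m) <- paste0("Net.", nm)
  rownames(m) <- residue_ids(model)
  m
}

#' Compute structure descriptors
#'
#' @param model an `omega_structure` from [read_structure()].
#' @param descriptor one of the 14 registered structure sets (see
#'   `list_descriptors("structure")`).
#' @param targets optional target sites: residue strings `"chain:resno"` or
#'   an n x 3 matrix of coordinates; default all residues.
#' @param ... shell scheme (`r0`, `delta`, `nshell`), `radius` (HSE),
#'   `cutoff` (network), `probe`/`n_points` (depth).
#' @return a feature tibble (one row per target/residue).
#' @export
calc_structure_features <- function(model, descriptor, targets = NULL, ...) {
  stopifnot(inherits(model, "omega_structure"))
  if (!descriptor %in% STRUCTURE_DESCRIPTORS) {
    stop("unknown structure descriptor: ", descriptor)
  }
  m <- switch(descriptor,
    AAC_type1 = sf_shell_residue(model, targets, "aa", FALSE, ...),
    AAC_type2 = sf_shell_residue(model, targets, "aa", TRUE, ...),
    GAAC_type1 = sf_shell_residue(model, targets, "group5", FALSE, ...),
    GAAC_type2 = sf_shell_residue(model, targets, "group5", TRUE, ...),
    SS3_type1 = sf_shell_ss(model, targets, 3, FALSE, ...),
    SS3_type2 = sf_shell_ss(model, targets, 3, TRUE, ...),
    SS8_type1 = sf_shell_ss(model, targets, 8, FALSE, ...),
    SS8_type2 = sf_shell_ss(model, targets, 8, TRUE, ...),
    HSE_CB = sf_hse(model, "cb", ...),
    HSE_pseudoCB = sf_hse(model, "pseudo_cb", ...),
    Residue_depth = sf_residue_depth(model, ...),
    AC_type1 = sf_shell_atoms(model, targets, FALSE, ...),
    AC_type2 = sf_shell_atoms(model, targets, TRUE, ...),
    Network = sf_network(model, ...)
  )
  feature_tbl(m, rownames(m))
}
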