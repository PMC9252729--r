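# Structure model: PDB/mmCIF parsing via bio3d plus backbone geometry
# helpers shared by the descriptors and the fixture generator.

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")
AA3_TO_1 <- stats::setNames(names(AA3), AA3)

vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) v / vnorm(v)
vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# place atom D given A, B, C with |C-D| = len, angle(B,C,D) = ang (deg) and
# torsion(A,B,C,D) = tor (deg)
nerf_place <- function(A, B, C, len, ang, tor) {
  ang <- ang * pi / 180; tor <- tor * pi / 180
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- cbind(bc, vcross(n, bc), n)
  d <- len * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + as.vector(m %*% d)
}

# pseudo-C-beta from backbone N, CA, C (also used for glycine)
pseudo_cb <- function(N, CA, C) {
  b <- CA - N
  c_ <- C - CA
  a <- vcross(b, c_)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * c_ + CA
}

#' Parse a protein structure
#'
#' Reads PDB or mmCIF (by file extension, `.cif`), keeps the first model
#' only, resolves alternate locations to the highest occupancy (ties to
#' `'A'`), and drops waters/hetero groups from the residue table. Glycine
#' (or any residue missing C-beta) gets a pseudo-C-beta synthesized from
#' backbone geometry.
#'
#' @param path a PDB/mmCIF file, or a character vector of PDB lines.
#' @return an object of class `omega_structure` with `$atoms` (tibble:
#'   chain, resno, insert, resid, elety, element, x, y, z) and `$residues`
#'   (one row per residue with CA and CB coordinates).
#' @export
read_structure <- function(path) {
  if (length(path) > 1 || grepl("\n", path[[1]], fixed = TRUE)) {
    tmp <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(path, "\n")), tmp)
    path <- tmp
  }
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no protein atoms in structure")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  # altloc resolution
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ii) {
      if (length(ii) == 1) return(ii)
      o <- at$o[ii]; o[is.na(o)] <- 1
      best <- ii[o == max(o)]
      if (length(best) > 1) {
        pref <- best[at$alt[best] == "A"]
        best <- if (length(pref)) pref[[1]] else best[[1]]
      }
      best
    }))
    at <- at[sort(keep), , drop = FALSE]
  }
  at <- at[at$resid %in% names(AA3_TO_1), , drop = FALSE]
  if (nrow(at) == 0) stop("zero standard protein residues")
  atoms <- tibble::tibble(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
    x = at$x, y = at$y, z = at$z)
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) stop("non-finite coordinates")
  model <- structure(list(atoms = atoms), class = "omega_structure")
  model$residues <- build_residue_table(atoms)
  model
}

build_residue_table <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  ord <- !duplicated(key)
  res <- atoms[ord, c("chain", "resno", "insert", "resid")]
  res$key <- key[ord]
  get_atom <- function(k, name) {
    i <- which(key == k & atoms$elety == name)
    if (length(i) == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(atoms$x[i[1]], atoms$y[i[1]], atoms$z[i[1]])
  }
  coords <- lapply(res$key, function(k) {
    ca <- get_atom(k, "CA"); n <- get_atom(k, "N"); c_ <- get_atom(k, "C")
    o <- get_atom(k, "O"); cb <- get_atom(k, "CB")
    cb_flag <- FALSE
    if (any(is.na(cb)) && !any(is.na(c(n, ca, c_)))) {
      cb <- pseudo_cb(n, ca, c_); cb_flag <- TRUE
    }
    list(ca = ca, n = n, c = c_, o = o, cb = cb, cb_synth = cb_flag)
  })
  res$ca_x <- vapply(coords, function(p) p$ca[1], numeric(1))
  res$ca_y <- vapply(coords, function(p) p$ca[2], numeric(1))
  res$ca_z <- vapply(coords, function(p) p$ca[3], numeric(1))
  res$n_x <- vapply(coords, function(p) p$n[1], numeric(1))
  res$n_y <- vapply(coords, function(p) p$n[2], numeric(1))
  res$n_z <- vapply(coords, function(p) p$n[3], numeric(1))
  res$c_x <- vapply(coords, function(p) p$c[1], numeric(1))
  res$c_y <- vapply(coords, function(p) p$c[2], numeric(1))
  res$c_z <- vapply(coords, function(p) p$c[3], numeric(1))
  res$o_x <- vapply(coords, function(p) p$o[1], numeric(1))
  res$o_y <- vapply(coords, function(p) p$o[2], numeric(1))
  res$o_z <- vapply(coords, function(p) p$o[3], numeric(1))
  res$cb_x <- vapply(coords, function(p) p$cb[1], numeric(1))
  res$cb_y <- vapply(coords, function(p) p$cb[2], numeric(1))
  res$cb_z <- vapply(coords, function(p) p$cb[3], numeric(1))
  res$cb_synth <- vapply(coords, function(p) p$cb_synth, logical(1))
  res$aa1 <- unname(AA3_TO_1[res$resid])
  tibble::as_tibble(res)
}

#' @export
print.omega_structure <- function(x, ...) {
  cat("<structure model: ", nrow(x$residues), " residue(s), ",
      nrow(x$atoms), " atom(s)>\n", sep = "")
  invisible(x)
}

residue_ids <- function(model) {
  r <- model$residues
  paste0(r$chain, ":", r$resno, ifelse(nzchar(r$insert), paste0(":", r$insert), ""))
}

res_coords <- function(model, which = "ca") {
  r <- model$residues
  m <- cbind(r[[paste0(which, "_x")]], r[[paste0(which, "_y")]],
             r[[paste0(which, "_z")]])
  rownames(m) <- residue_ids(model)
  m
}

# resolve target selector: NULL = all residues; character "chain:resno";
# numeric matrix of explicit xyz sites
resolve_targets <- function(model, targets) {
  ids <- residue_ids(model)
  if (is.null(targets)) {
    return(list(idx = seq_along(ids), centers = res_coords(model), ids = ids))
  }
  if (is.numeric(targets)) {
    m <- matrix(targets, ncol = 3)
    return(list(idx = rep(NA_integer_, nrow(m)), centers = m,
                ids = paste0("site", seq_len(nrow(m)))))
  }
  short <- paste0(model$residues$chain, ":", model$residues$resno)
  idx <- match(targets, ids)
  idx[is.na(idx)] <- match(targets[is.na(idx)], short)
  if (any(is.na(idx))) stop("target(s) not in model: ",
                            paste(targets[is.na(idx)], collapse = ", "))
  list(idx = idx, centers = res_coords(model)[idx, , drop = FALSE], ids = ids[idx])
}

# --- backbone builder (fixtures) ---------------------------------------------
# Build an all-backbone + CB chain from per-residue (phi, psi); omega = 180.
build_backbone <- function(aa_seq, phi, psi) {
  n <- length(aa_seq)
  stopifnot(length(phi) == n, length(psi) == n)
  Npos <- CApos <- Cpos <- Opos <- CBpos <- matrix(NA_real_, n, 3)
  Npos[1, ] <- c(0, 0, 0)
  CApos[1, ] <- c(1.458, 0, 0)
  # first C placed in the xy-plane at the ideal N-CA-C angle
  ang <- 111.2 * pi / 180
  Cpos[1, ] <- CApos[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    Npos[i, ] <- nerf_place(Npos[i - 1, ], CApos[i - 1, ], Cpos[i - 1, ],
                            1.329, 116.2, psi[i - 1])
    CApos[i, ] <- nerf_place(CApos[i - 1, ], Cpos[i - 1, ], Npos[i, ],
                             1.458, 121.7, 180)
    Cpos[i, ] <- nerf_place(Cpos[i - 1, ], Npos[i, ], CApos[i, ],
                            1.525, 111.2, phi[i])
  }
  for (i in 1:n) {
    tor <- psi[i] + 180
    Opos[i, ] <- nerf_place(Npos[i, ], CApos[i, ], Cpos[i, ], 1.231, 120.8, tor)
    CBpos[i, ] <- pseudo_cb(Npos[i, ], CApos[i, ], Cpos[i, ])
  }
  list(N = Npos, CA = CApos, C = Cpos, O = Opos, CB = CBpos)
}

format_pdb_atom <- function(serial, name, resid, chain, resno, xyz, element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resid, chain, resno, xyz[1], xyz[2], xyz[3], element)
}

backbone_to_pdb <- function(aa_seq, bb, chain = "A") {
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(aa_seq)) {
    resid <- AA3[[aa_seq[[i]]]]
    atoms <- list(N = c(bb$N[i, ], "N"), CA = c(bb$CA[i, ], "C"),
                  C = c(bb$C[i, ], "C"), O = c(bb$O[i, ], "O"))
    if (aa_seq[[i]] != "G") atoms$CB <- c(bb$CB[i, ], "C")
    for (nm in names(atoms)) {
      serial <- serial + 1L
      a <- atoms[[nm]]
      lines <- c(lines, format_pdb_atom(serial, nm, resid, chain, i,
                                        as.numeric(a[1:3]), a[4]))
    }
  }
  c(lines, "TER", "END")
}
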