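# Ligand parsing and the molecular graph.
#
# Chemistry perception (SMILES/SDF parsing, aromaticity, Gasteiger partial
# charges, SMARTS matching, MACCS/path fingerprints) is delegated to
# ChemmineR/ChemmineOB (OpenBabel). The graph object built here carries the
# per-atom quantities the descriptor blocks need: element, explicit-H count,
# aromaticity, partial charge, and the heavy-atom bond list.

#' Parse ligands from SMILES or SDF
#'
#' @param input for `format = "smiles"`: a character vector of SMILES (names
#'   become ids) or a path to a file with one SMILES per line (optional
#'   `SMILES<tab>id`); for `format = "sdf"`: an SDF file path.
#' @param format `"smiles"` or `"sdf"`.
#' @return an object of class `omega_mols`: parsed molecules plus a report
#'   of entries that failed to parse (`$invalid`, by input index).
#' @export
read_molecules <- function(input, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "smiles") {
    if (length(input) == 1 && file.exists(input)) input <- readLines(input)
    input <- input[nzchar(trimws(input))]
    parts <- strsplit(input, "\t")
    entries <- vapply(parts, `[[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][[2]] else {
        nm <- names(input)[i]
        if (!is.null(nm) && nzchar(nm)) nm else paste0("mol", i)
      }
    }, character(1))
  } else {
    if (!file.exists(input)) stop("no such file: ", input)
    lines <- readLines(input)
    ends <- grep("^\\$\\$\\$\\$", lines)
    starts <- c(1, utils::head(ends, -1) + 1)
    entries <- lapply(seq_along(ends), function(i) lines[starts[i]:ends[i]])
    ids <- vapply(seq_along(entries), function(i) {
      ttl <- trimws(entries[[i]][[1]])
      if (nzchar(ttl)) ttl else paste0("mol", i)
    }, character(1))
  }
  # per-entry conversion to a normalized SDF (explicit H, 2-D coordinates)
  sdf_blocks <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    sdf_blocks[[i]] <- obabel_to_sdf(entries[[i]], format, ids[[i]])
  }
  ok <- !vapply(sdf_blocks, is.null, logical(1))
  invalid <- which(!ok)
  if (!any(ok)) stop("no valid molecules in input")
  ids <- make.unique(ids[ok], sep = "_")
  sdf_text <- unlist(sdf_blocks[ok])
  sdf <- suppressWarnings(ChemmineR::read.SDFset(sdf_text))
  ChemmineR::cid(sdf) <- ids
  graphs <- mol_graphs_from_sdf(sdf)
  structure(list(sdf = sdf, graphs = graphs, ids = ids, invalid = invalid),
            class = "omega_mols")
}

# one entry (SMILES string or SDF block) -> normalized SDF block or NULL
obabel_to_sdf <- function(entry, format, title) {
  tmp_in <- tempfile(fileext = if (format == "smiles") ".smi" else ".sdf")
  tmp_out <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tmp_in, tmp_out)))
  writeLines(if (format == "smiles") entry else entry, tmp_in)
  status <- suppressWarnings(system2("obabel",
    c(tmp_in, "-osdf", "-h", "--gen2d", "--title", shQuote(title), "-O", tmp_out),
    stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(tmp_out)) return(NULL)
  out <- readLines(tmp_out)
  if (!length(grep("^\\$\\$\\$\\$", out))) return(NULL)
  # reject empty molecules (counts line "  0  0 ...")
  counts <- suppressWarnings(as.integer(substr(out[[4]], 1, 3)))
  if (is.na(counts) || counts < 1) return(NULL)
  out
}

#' @export
print.omega_mols <- function(x, ...) {
  cat("<molecule set: ", length(x$ids), " molecule(s)",
      if (length(x$invalid)) paste0(", ", length(x$invalid), " invalid input entr(y/ies)"),
      ">\n", sep = "")
  invisible(x)
}

#' @export
length.omega_mols <- function(x) length(x$ids)

# Convert the normalized SDFset through OpenBabel to mol2 with Gasteiger
# charges, then parse atoms/bonds. Hydrogens are already explicit.
mol_graphs_from_sdf <- function(sdf) {
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".mol2")
  ChemmineR::write.SDF(sdf, tmp_in)
  status <- suppressWarnings(system2("obabel",
    c(tmp_in, "-omol2", "--partialcharge", "gasteiger", "-O", tmp_out),
    stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(tmp_out)) {
    stop("OpenBabel conversion failed")
  }
  lines <- readLines(tmp_out)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  mols <- lapply(seq_along(starts), function(i) {
    end <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    parse_mol2_block(lines[starts[i]:end])
  })
  if (length(mols) != length(sdf)) stop("mol2 conversion count mismatch")
  names(mols) <- ChemmineR::cid(sdf)
  mols
}

parse_mol2_block <- function(block) {
  a0 <- grep("^@<TRIPOS>ATOM", block)
  b0 <- grep("^@<TRIPOS>BOND", block)
  sec_end <- function(start) {
    nxt <- grep("^@<TRIPOS>", block)
    nxt <- nxt[nxt > start]
    if (length(nxt)) nxt[[1]] - 1 else length(block)
  }
  atom_lines <- block[(a0 + 1):sec_end(a0)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- do.call(rbind, strsplit(trimws(atom_lines), "\\s+"))
  type <- af[, 6]
  element <- sub("\\..*$", "", type)
  atoms <- data.frame(
    element = element,
    x = as.numeric(af[, 3]), y = as.numeric(af[, 4]), z = as.numeric(af[, 5]),
    type = type,
    aromatic = grepl("\\.ar$", type),
    charge = as.numeric(af[, 9]),
    stringsAsFactors = FALSE)
  bonds <- if (length(b0)) {
    bl <- block[(b0 + 1):sec_end(b0)]
    bl <- bl[nzchar(trimws(bl))]
    if (length(bl)) {
      bf <- do.call(rbind, strsplit(trimws(bl), "\\s+"))
      data.frame(a = as.integer(bf[, 2]), b = as.integer(bf[, 3]),
                 type = bf[, 4], stringsAsFactors = FALSE)
    } else data.frame(a = integer(), b = integer(), type = character())
  } else data.frame(a = integer(), b = integer(), type = character())
  bonds$order <- ifelse(bonds$type == "ar", 1.5,
                        ifelse(bonds$type == "am", 1,
                               suppressWarnings(as.numeric(bonds$type))))
  bonds$order[is.na(bonds$order)] <- 1
  bonds$aromatic <- bonds$type == "ar"
  build_mol_graph(atoms, bonds)
}

build_mol_graph <- function(atoms, bonds) {
  n <- nrow(atoms)
  heavy <- which(atoms$element != "H")
  nH <- integer(n)
  hq <- numeric(n)  # summed partial charge of attached hydrogens
  deg_all <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    deg_all[a] <- deg_all[a] + 1L; deg_all[b] <- deg_all[b] + 1L
    if (atoms$element[b] == "H") { nH[a] <- nH[a] + 1L; hq[a] <- hq[a] + atoms$charge[b] }
    if (atoms$element[a] == "H") { nH[b] <- nH[b] + 1L; hq[b] <- hq[b] + atoms$charge[a] }
  }
  hmap <- match(seq_len(n), heavy)
  hb <- bonds[atoms$element[bonds$a] != "H" & atoms$element[bonds$b] != "H", ,
              drop = FALSE]
  hb$a <- hmap[hb$a]; hb$b <- hmap[hb$b]
  ha <- atoms[heavy, , drop = FALSE]
  ha$nH <- nH[heavy]
  ha$charge_h <- ha$charge + hq[heavy]  # charge with hydrogens summed in
  ha$degree <- 0L
  for (k in seq_len(nrow(hb))) {
    ha$degree[hb$a[k]] <- ha$degree[hb$a[k]] + 1L
    ha$degree[hb$b[k]] <- ha$degree[hb$b[k]] + 1L
  }
  g <- igraph::make_empty_graph(n = nrow(ha), directed = FALSE)
  if (nrow(hb)) g <- igraph::add_edges(g, as.vector(t(as.matrix(hb[, c("a", "b")]))))
  ring_atoms <- rep(FALSE, nrow(ha))
  if (nrow(hb)) {
    # atoms on any cycle: edges whose removal keeps endpoints connected
    for (k in seq_len(nrow(hb))) {
      g2 <- igraph::delete_edges(g, k)
      if (igraph::distances(g2, v = hb$a[k], to = hb$b[k]) < Inf) {
        ring_atoms[c(hb$a[k], hb$b[k])] <- TRUE
      }
    }
  }
  list(atoms = ha, bonds = hb, graph = g, ring_atom = ring_atoms,
       n_heavy = nrow(ha))
}

mol_dist <- function(mol) {
  d <- igraph::distances(mol$graph)
  d
}

ring_count <- function(mol) {
  comp <- igraph::components(mol$graph)$no
  nrow(mol$bonds) - mol$n_heavy + comp
}
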