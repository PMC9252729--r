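# Seeded fixture generation: random sequence sets, a toy multi-residue
# structure built from ideal backbone geometry, and a small SMILES panel.
# All randomness is drawn from a local RNG so the caller's stream is
# untouched; identical seeds give byte-identical outputs.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a seeded random sequence set
#'
#' @param seed integer seed; identical seeds give identical sets.
#' @param n_seq number of sequences (>= 1).
#' @param seq_len sequence length (>= 3); all sequences share it so that
#'   windowed/positional descriptors apply.
#' @param kind `protein`, `dna` or `rna`.
#' @param labelled attach alternating "1"/"0" class labels.
#' @return an [seq_set()] tibble.
#' @export
fixture_sequences <- function(seed = 1, n_seq = 10, seq_len = 50,
                              kind = "protein", labelled = TRUE) {
  if (n_seq < 1 || seq_len < 3) stop("invalid fixture sizes")
  alpha <- ALPHABETS[[match.arg(kind, c("protein", "dna", "rna"))]]
  idx <- seq.int(n_seq)
  seqs <- with_local_seed(seed, {
    vapply(idx, function(i) {
      paste(sample(alpha, seq_len, replace = TRUE), collapse = "")
    }, character(1))
  })
  seq_set(sprintf("seq%03d", idx), seqs, kind,
          label = if (labelled) rep(c("1", "0"), length.out = n_seq) else NULL)
}

FIXTURE_AA <- strsplit("MKCHDEWAFLSTYRVQ", "")[[1]]  # varied, incl. C/H/D/E

#' Generate a toy protein structure as PDB text
#'
#' A single-chain model with full backbone (N, CA, C, O) and C-beta atoms
#' built from ideal peptide geometry. Conformations: `helix`
#' (phi = -57, psi = -47), `extended` (phi = -139, psi = 135) or `mixed`
#' (helix then extended halves with jittered torsions).
#'
#' @param seed seed for torsion jitter (mixed conformation only).
#' @param n_res number of residues (>= 12 recommended; the residue panel
#'   cycles through 16 amino-acid types including CYS/HIS/ASP/GLU).
#' @param conformation `helix`, `extended` or `mixed`.
#' @return character vector of PDB lines.
#' @export
fixture_structure <- function(seed = 1, n_res = 16,
                              conformation = c("helix", "extended", "mixed")) {
  conformation <- match.arg(conformation)
  if (n_res < 4) stop("need at least 4 residues")
  aa <- rep(FIXTURE_AA, length.out = n_res)
  tor <- switch(conformation,
    helix = list(phi = rep(-57, n_res), psi = rep(-47, n_res)),
    extended = list(phi = rep(-139, n_res), psi = rep(135, n_res)),
    mixed = with_local_seed(seed, {
      half <- floor(n_res / 2)
      phi <- c(rep(-57, half), rep(-139, n_res - half)) + stats::runif(n_res, -5, 5)
      psi <- c(rep(-47, half), rep(135, n_res - half)) + stats::runif(n_res, -5, 5)
      list(phi = phi, psi = psi)
    }))
  bb <- build_backbone(aa, tor$phi, tor$psi)
  backbone_to_pdb(aa, bb)
}

#' Write a two-model PDB fixture (second model rigidly shifted)
#' @inheritParams fixture_structure
#' @return character vector of PDB lines containing MODEL 1 and MODEL 2.
#' @export
fixture_structure_two_models <- function(seed = 1, n_res = 12) {
  m1 <- fixture_structure(seed, n_res, "helix")
  body1 <- m1[!m1 %in% c("TER", "END")]
  shift <- function(line) {
    x <- as.numeric(substr(line, 31, 38)) + 50
    paste0(substr(line, 1, 30), sprintf("%8.3f", x), substr(line, 39, nchar(line)))
  }
  n_extra <- max(4, n_res - 4)
  m2 <- fixture_structure(seed, n_extra, "helix")
  body2 <- vapply(m2[!m2 %in% c("TER", "END")], shift, character(1),
                  USE.NAMES = FALSE)
  c("MODEL     1", body1, "ENDMDL", "MODEL     2", body2, "ENDMDL", "END")
}

#' Fixture SMILES panel
#'
#' Methane, benzene and several small ring/heteroatom molecules sufficient
#' to exercise every ligand descriptor block.
#' @return named character vector of SMILES.
#' @export
fixture_smiles <- function() {
  c(methane = "C", benzene = "c1ccccc1", pyridine = "c1ccncc1",
    furan = "c1ccoc1", ethanol = "CCO", butane = "CCCC",
    acetic_acid = "CC(=O)O", aniline = "Nc1ccccc1")
}

#' Generate the full fixture bundle on disk
#'
#' Writes seeded FASTA files (protein/dna/rna), the toy structure PDB and a
#' SMILES list under `dir`.
#'
#' @param seed integer seed.
#' @param dir output directory (created if missing).
#' @param n_seq,seq_len sequence-set dimensions.
#' @return invisible named list of file paths.
#' @export
generate_fixtures <- function(seed = 1, dir = tempfile("fixtures"),
                              n_seq = 10, seq_len = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (kind in c("protein", "dna", "rna")) {
    p <- file.path(dir, paste0(kind, ".fasta"))
    write_fasta(fixture_sequences(seed, n_seq, seq_len, kind), p)
    paths[[kind]] <- p
  }
  paths$structure <- file.path(dir, "structure.pdb")
  writeLines(fixture_structure(seed), paths$structure)
  paths$smiles <- file.path(dir, "ligands.smi")
  smi <- fixture_smiles()
  writeLines(paste(smi, names(smi), sep = "\t"), paths$smiles)
  invisible(paths)
}
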