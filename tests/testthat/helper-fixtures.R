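# Shared fixtures, memoised so expensive objects are built once per run.

fx <- local({
  cache <- list()
  function(name, builder) {
    if (is.null(cache[[name]])) cache[[name]] <<- builder()
    cache[[name]]
  }
})

fx_protein <- function(n = 6, len = 30, seed = 11) {
  fx(paste0("p", n, "_", len, "_", seed),
     function() fixture_sequences(seed, n, len, "protein"))
}
fx_dna <- function(n = 6, len = 30, seed = 11) {
  fx(paste0("d", n, "_", len, "_", seed),
     function() fixture_sequences(seed, n, len, "dna"))
}
fx_rna <- function(n = 6, len = 30, seed = 11) {
  fx(paste0("r", n, "_", len, "_", seed),
     function() fixture_sequences(seed, n, len, "rna"))
}
fx_helix <- function() {
  fx("helix", function() read_structure(paste(fixture_structure(1, 16, "helix"),
                                              collapse = "\n")))
}
fx_mixed <- function() {
  fx("mixed", function() read_structure(paste(fixture_structure(3, 14, "mixed"),
                                              collapse = "\n")))
}
fx_mols <- function() {
  fx("mols", function() read_molecules(fixture_smiles(), "smiles"))
}

# a single-letter protein sequence set (for degenerate cases)
one_seq <- function(s, kind = "protein") seq_set("q1", s, kind)

# minimal CA-only PDB text from a table of (resid, x, y, z); one residue per row
ca_only_pdb <- function(resid, xyz) {
  lines <- vapply(seq_along(resid), function(i) {
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, resid[[i]], i, xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  c(lines, "END")
}

# exact rigid rotation + translation applied to a parsed structure model
transform_model <- function(model, angle = 0.7, shift = c(10, -5, 3)) {
  R1 <- matrix(c(cos(angle), -sin(angle), 0,
                 sin(angle), cos(angle), 0,
                 0, 0, 1), 3, byrow = TRUE)
  R2 <- matrix(c(1, 0, 0,
                 0, cos(0.4), -sin(0.4),
                 0, sin(0.4), cos(0.4)), 3, byrow = TRUE)
  R <- R1 %*% R2
  xyz <- cbind(model$atoms$x, model$atoms$y, model$atoms$z) %*% t(R)
  model$atoms$x <- xyz[, 1] + shift[1]
  model$atoms$y <- xyz[, 2] + shift[2]
  model$atoms$z <- xyz[, 3] + shift[3]
  model$residues <- omegafeat:::build_residue_table(model$atoms)
  model
}

feat_mat <- function(tbl) feature_values(tbl)

# two well-separated labelled Gaussian blobs
blob_tbl <- function(seed = 42, n = 10, p = 4, sep = 8) {
  set.seed(seed)
  m <- rbind(matrix(stats::rnorm(n * p, 0), n),
             matrix(stats::rnorm(n * p, sep), n))
  feature_tbl(m, sprintf("s%02d", seq_len(2 * n)), rep(c("a", "b"), each = n))
}
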