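# Fingerprint families: MACCS structural keys and path-based bits through
# OpenBabel; circular (Morgan-style) hashing and E-state atom-type counts
# implemented over the molecular graph.

# deterministic integer hashing kept inside double precision
mix_hash <- function(values) {
  h <- 5381
  for (v in values) {
    h <- (h * 33 + v) %% 2147483647
  }
  h
}

morgan_bits <- function(mol, radius = 2, nbits = 2048) {
  n <- mol$n_heavy
  z <- ATOMIC_Z[mol$atoms$element]; z[is.na(z)] <- 0
  inv <- vapply(seq_len(n), function(i) {
    mix_hash(c(z[i], mol$atoms$degree[i], mol$atoms$nH[i],
               as.integer(mol$atoms$aromatic[i]), as.integer(mol$ring_atom[i])))
  }, numeric(1))
  adj <- igraph::as_adj_list(mol$graph)
  bond_order <- function(i, j) {
    k <- which((mol$bonds$a == i & mol$bonds$b == j) |
                 (mol$bonds$a == j & mol$bonds$b == i))
    round(mol$bonds$order[k[1]] * 10)
  }
  all_ids <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(i) {
      nbs <- as.integer(adj[[i]])
      if (!length(nbs)) return(mix_hash(c(r, inv[i])))
      pairs <- cbind(vapply(nbs, bond_order, numeric(1), i = i), inv[nbs])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      mix_hash(c(r, inv[i], as.vector(t(pairs))))
    }, numeric(1))
    all_ids <- c(all_ids, inv)
  }
  bits <- unique(all_ids %% nbits) + 1
  v <- numeric(nbits)
  v[bits] <- 1
  v
}

# E-state atom-type keys: element x aromatic x heavy-degree (79 pinned slots)
ESTATE_TYPES <- local({
  els <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  keys <- c()
  for (el in els) {
    for (ar in 0:1) {
      for (dg in 1:4) {
        if (ar == 1 && !el %in% c("C", "N", "O", "S")) next
        keys <- c(keys, paste(el, ar, dg, sep = "."))
      }
    }
  }
  keys <- c(keys, "other")
  length(keys) <- 79
  keys[is.na(keys)] <- paste0("reserved", seq_len(sum(is.na(keys))))
  keys
})

estate_type_counts <- function(mol) {
  key <- paste(mol$atoms$element, as.integer(mol$atoms$aromatic),
               pmin(mol$atoms$degree, 4), sep = ".")
  key[!key %in% ESTATE_TYPES] <- "other"
  count_on(key, ESTATE_TYPES)
}

ligand_fingerprints <- function(mols, family, radius = 2, nbits = 2048, ...) {
  m <- switch(family,
    maccs = {
      fp <- ChemmineR::fingerprintOB(mols$sdf, "MACCS")
      mm <- fp@fpma[, seq_len(166), drop = FALSE]
      colnames(mm) <- paste0("MACCS.", seq_len(166))
      mm
    },
    topological_fp = {
      fp <- ChemmineR::fingerprintOB(mols$sdf, "FP2")
      mm <- fp@fpma
      colnames(mm) <- paste0("FP2.", seq_len(ncol(mm)))
      mm
    },
    morgan = {
      mm <- do.call(rbind, lapply(mols$graphs, morgan_bits,
                                  radius = radius, nbits = nbits))
      colnames(mm) <- paste0("Morgan.", seq_len(nbits))
      mm
    },
    estate_fp = {
      mm <- do.call(rbind, lapply(mols$graphs, estate_type_counts))
      colnames(mm) <- paste0("EStateFP.", ESTATE_TYPES)
      mm
    },
    stop("unknown fingerprint family: ", family)
  )
  rownames(m) <- mols$ids
  feature_tbl(m, mols$ids)
}

#' Tanimoto similarity between two fingerprint rows
#' @param a,b numeric 0/1 vectors (or count vectors, compared as presence).
#' @export
tanimoto <- function(a, b) {
  a <- a != 0; b <- b != 0
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}
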