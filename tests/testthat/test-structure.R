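test_that("structure parsing: first model only, altloc and error contracts", {
  model <- fx_helix()
  expect_equal(nrow(model$residues), 16)
  expect_false(any(model$residues$cb_synth[model$residues$aa1 != "G"]))

  two <- read_structure(paste(fixture_structure_two_models(1, 12), collapse = "\n"))
  expect_equal(nrow(two$residues), 12)  # model 2 discarded

  f <- withr::local_tempfile(lines = "")
  expect_error(read_structure(f), ".")

  # altloc: highest occupancy wins, ties go to 'A'
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.60  0.00           C",
    "END")
  m <- read_structure(paste(lines, collapse = "\n"))
  expect_equal(m$residues$ca_x, 5)
})

test_that("shell membership follows the half-open convention and hand geometry", {
  # target ALA at origin, single ALA neighbour at 5 A
  pdb <- ca_only_pdb(c("ALA", "ALA"), rbind(c(0, 0, 0), c(5, 0, 0)))
  m <- read_structure(paste(pdb, collapse = "\n"))
  tb <- calc_structure_features(m, "AAC_type1", targets = "A:1",
                                r0 = 0, delta = 10, nshell = 1)
  v <- feat_mat(tb)[1, ]
  expect_equal(unname(v["AAC.t1.s1.A"]), 1)
  expect_equal(sum(v), 1)

  # neighbour at exactly r0 + s*delta falls in the NEXT shell
  pdb2 <- ca_only_pdb(c("ALA", "GLY"), rbind(c(0, 0, 0), c(4, 0, 0)))
  m2 <- read_structure(paste(pdb2, collapse = "\n"))
  tb2 <- calc_structure_features(m2, "AAC_type1", targets = "A:1",
                                 r0 = 0, delta = 2, nshell = 3)
  v2 <- feat_mat(tb2)[1, ]
  expect_equal(unname(v2["AAC.t1.s3.G"]), 1)
  expect_true(all(v2[grep("s2", names(v2))] == 0))
  expect_error(calc_structure_features(m2, "AAC_type1", targets = "B:9"),
               "not in model")
})

test_that("cumulative shells are monotone and brute-force checkable", {
  model <- fx_mixed()
  ca <- omegafeat:::res_coords(model)
  t1 <- feat_mat(calc_structure_features(model, "AAC_type2", nshell = 6))
  # counts are monotone: cumulative frequency * cumulative total
  for (ri in seq_len(nrow(ca))) {
    d <- sqrt(colSums((t(ca) - ca[ri, ])^2))[-ri]
    for (aa in c("A", "K", "C")) {
      col <- paste0("AAC.t2.s", 1:6, ".", aa)
      tot <- sapply(1:6, function(s) sum(d < s * 2))
      cnt <- t1[ri, col] * tot
      expect_true(all(diff(cnt) > -1e-9))
    }
  }
  # brute-force frequency check for one target and shell
  d <- sqrt(colSums((t(ca) - ca[1, ])^2))[-1]
  aa_others <- model$residues$aa1[-1]
  within <- aa_others[d < 12]
  got <- t1[1, paste0("AAC.t2.s6.", sort(unique(within)))]
  expected <- table(within) / length(within)
  expect_equal(unname(got[paste0("AAC.t2.s6.", names(expected))]),
               unname(as.numeric(expected)), tolerance = 1e-9)

  # atom-composition shells against exhaustive pairwise distances
  at <- model$atoms
  a1 <- feat_mat(calc_structure_features(model, "AC_type1", nshell = 4))
  key <- paste(at$chain, at$resno, at$insert)
  for (ri in c(1, 5)) {
    rk <- paste(model$residues$chain[ri], model$residues$resno[ri],
                model$residues$insert[ri])
    keep <- key != rk
    dd <- sqrt((at$x[keep] - ca[ri, 1])^2 + (at$y[keep] - ca[ri, 2])^2 +
                 (at$z[keep] - ca[ri, 3])^2)
    el <- ifelse(at$element[keep] %in% c("C", "N", "O", "S"),
                 at$element[keep], "other")
    in2 <- dd >= 2 & dd < 4
    if (sum(in2)) {
      for (e in c("C", "N", "O")) {
        expect_equal(unname(a1[ri, paste0("AtomC.t1.s2.", e)]),
                     sum(el[in2] == e) / sum(in2), tolerance = 1e-9)
      }
    }
  }
})

test_that("secondary-structure assignment distinguishes helix from strand", {
  ss_h <- assign_secondary_structure(fx_helix())
  inner <- ss_h$ss8[3:13]
  expect_true(mean(inner == "H") > 0.8)

  ext <- read_structure(paste(fixture_structure(1, 16, "extended"), collapse = "\n"))
  ss_e <- assign_secondary_structure(ext)
  expect_false(any(ss_e$ss8 == "H"))

  # 3-state collapse is the fixed mapping
  expect_true(all(ss_h$ss3[ss_h$ss8 %in% c("H", "G", "I")] == "H"))
  expect_true(all(ss_e$ss3[ss_e$ss8 %in% c("E", "B")] == "E"))
  expect_true(all(ss_h$ss3 %in% c("H", "E", "C")))
})

test_that("secondary-structure shells: all-helix fixture and state collapse", {
  model <- fx_helix()
  t3 <- feat_mat(calc_structure_features(model, "SS3_type1", nshell = 5))
  # interior residues see mostly-helix shells
  nonzero <- rowSums(t3) > 0
  hel <- t3[, grep("\\.H$", colnames(t3))]
  expect_true(mean(rowSums(hel)[nonzero] / rowSums(t3)[nonzero]) > 0.7)
  # per-shell blocks sum to 1 when non-empty
  t8 <- feat_mat(calc_structure_features(model, "SS8_type1", nshell = 5))
  for (s in 1:5) {
    block <- t8[, grep(paste0("\\.s", s, "\\."), colnames(t8))]
    sums <- rowSums(block)
    expect_true(all(abs(sums[sums > 0] - 1) < 1e-9))
  }
  # SS3 cumulative equals SS8 cumulative after collapsing states
  c3 <- feat_mat(calc_structure_features(model, "SS3_type2", nshell = 5))
  c8 <- feat_mat(calc_structure_features(model, "SS8_type2", nshell = 5))
  for (s in 1:5) {
    h3 <- c3[, paste0("SS3.t2.s", s, ".H")]
    h8 <- rowSums(c8[, paste0("SS8.t2.s", s, ".", c("H", "G", "I"))])
    expect_equal(unname(h3), unname(h8), tolerance = 1e-9)
  }
})

test_that("half-sphere exposure: dot-product geometry and partition identity", {
  # residue with CB straight up, one neighbour above, one far away
  lines <- c(
    "ATOM      1  N   ALA A   1       1.400   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      -1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CB  ALA A   1       0.000   0.000   1.500  1.00  0.00           C",
    "ATOM      5  CA  GLY A   2       0.000   0.000   5.000  1.00  0.00           C",
    "ATOM      6  CA  GLY A   3       0.000   0.000  20.000  1.00  0.00           C",
    "END")
  m <- read_structure(paste(lines, collapse = "\n"))
  v <- feat_mat(calc_structure_features(m, "HSE_CB"))
  expect_equal(unname(v[1, c("HSE.CB.up", "HSE.CB.down")]), c(1, 0))

  # partition identity on the fixture for both variants
  model <- fx_mixed()
  ca <- omegafeat:::res_coords(model)
  n13 <- sapply(seq_len(nrow(ca)), function(i) {
    d <- sqrt(colSums((t(ca) - ca[i, ])^2))
    sum(d <= 13) - 1
  })
  for (desc in c("HSE_CB", "HSE_pseudoCB")) {
    hv <- feat_mat(calc_structure_features(model, desc))
    expect_equal(unname(rowSums(hv)), n13)
  }
})

test_that("residue depth: isolated atom, buried center, sampling stability", {
  single <- read_structure(paste(ca_only_pdb("ALA", matrix(c(0, 0, 0), 1)),
                                 collapse = "\n"))
  expect_equal(feat_mat(calc_structure_features(single, "Residue_depth"))[1, 1],
               0, tolerance = 1e-9)

  # 27-atom cube: center strictly deeper than a corner
  g <- as.matrix(expand.grid(x = c(0, 2, 4), y = c(0, 2, 4), z = c(0, 2, 4)))
  cube <- read_structure(paste(ca_only_pdb(rep("ALA", 27), g), collapse = "\n"))
  d <- feat_mat(calc_structure_features(cube, "Residue_depth", n_points = 200))[, 1]
  center <- which(g[, 1] == 2 & g[, 2] == 2 & g[, 3] == 2)
  corner <- which(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0)
  expect_gt(d[center], d[corner])

  # doubling the sampling density moves depths by < 0.2 A
  model <- fx_helix()
  d1 <- feat_mat(calc_structure_features(model, "Residue_depth", n_points = 240))[, 1]
  d2 <- feat_mat(calc_structure_features(model, "Residue_depth", n_points = 480))[, 1]
  expect_lt(max(abs(d1 - d2)), 0.2)
})

test_that("contact-network indices match an independent computation", {
  # 3 collinear residues 5 A apart, cutoff 8
  tri <- read_structure(paste(ca_only_pdb(rep("ALA", 3),
                                          rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))),
                              collapse = "\n"))
  v <- feat_mat(calc_structure_features(tri, "Network", cutoff = 8))
  expect_equal(unname(v[, "Net.degree"]), c(1, 2, 1))
  expect_equal(unname(v[2, "Net.betweenness"]), 1)

  # triangle: clustering coefficient 1 everywhere
  tee <- read_structure(paste(ca_only_pdb(rep("ALA", 3),
                                          rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 4, 0))),
                              collapse = "\n"))
  vt <- feat_mat(calc_structure_features(tee, "Network", cutoff = 8))
  expect_true(all(vt[, "Net.clustering"] == 1))

  # independent adjacency/BFS oracle on seeded random structures
  bfs_dist <- function(adj, s) {
    n <- nrow(adj); d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      u <- q[[1]]; q <- q[-1]
      for (v2 in which(adj[u, ] == 1)) {
        if (d[v2] == Inf) { d[v2] <- d[u] + 1; q <- c(q, v2) }
      }
    }
    d
  }
  for (seed in 1:10) {
    xyz <- with(list(), {
      set.seed(seed + 100)
      matrix(stats::runif(3 * 9, 0, 14), ncol = 3)
    })
    m <- read_structure(paste(ca_only_pdb(rep("ALA", 9), xyz), collapse = "\n"))
    got <- feat_mat(calc_structure_features(m, "Network", cutoff = 8))
    dd <- as.matrix(stats::dist(xyz))
    adj <- (dd <= 8) * 1; diag(adj) <- 0
    n <- 9
    expect_equal(unname(got[, "Net.degree"]), unname(rowSums(adj)))
    expect_equal(unname(got[, "Net.degree_centrality"]),
                 unname(rowSums(adj)) / (n - 1), tolerance = 1e-9)
    sp <- t(sapply(1:n, function(s) bfs_dist(adj, s)))
    clo <- sapply(1:n, function(i) {
      r <- sp[i, -i]; r <- r[is.finite(r)]
      if (!length(r)) 0 else (length(r) / sum(r)) * (length(r) / (n - 1))
    })
    expect_equal(unname(got[, "Net.closeness"]), clo, tolerance = 1e-9)
    # local clustering from triangle counts
    clu <- sapply(1:n, function(i) {
      nb <- which(adj[i, ] == 1)
      if (length(nb) < 2) return(0)
      sum(adj[nb, nb]) / (length(nb) * (length(nb) - 1))
    })
    expect_equal(unname(got[, "Net.clustering"]), clu, tolerance = 1e-9)
  }

  singleres <- read_structure(paste(ca_only_pdb("ALA", matrix(0, 1, 3)),
                                    collapse = "\n"))
  expect_true(all(feat_mat(calc_structure_features(singleres, "Network")) == 0))
})

test_that("all structure descriptors are rigid-motion invariant", {
  pdb <- fixture_structure(2, 14, "mixed")
  m1 <- read_structure(paste(pdb, collapse = "\n"))
  m2 <- transform_model(m1)
  for (desc in list_descriptors("structure")$name) {
    np <- if (desc == "Residue_depth") list(n_points = 160) else list()
    a <- feat_mat(do.call(calc_structure_features,
                          c(list(m1, desc, nshell = 5), np)))
    b <- feat_mat(do.call(calc_structure_features,
                          c(list(m2, desc, nshell = 5), np)))
    tol <- if (desc == "Residue_depth") 0.2 else 1e-9
    expect_lt(max(abs(a - b)), tol, label = paste("rigid motion:", desc))
  }
})
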