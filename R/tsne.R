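# t-distributed stochastic neighbour embedding, exact-gradient
# implementation with PCA initialisation. Sized for the small feature sets
# this package analyses (hundreds of samples); seed-reproducible through
# the caller's RNG state.

tsne_perplexity_probs <- function(d2, perplexity) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p <- exp(-di * beta); p <- p / sum(p)
    P[i, -i] <- p
  }
  P
}

tsne_fit <- function(m, n_components = 2, perplexity = NULL, max_iter = 400,
                     eta = 100, momentum = 0.8) {
  n <- nrow(m)
  if (is.null(perplexity)) perplexity <- max(2, min(30, floor((n - 1) / 3)))
  if (3 * perplexity > n - 1) perplexity <- max(1, floor((n - 1) / 3))
  d2 <- as.matrix(stats::dist(m))^2
  P <- tsne_perplexity_probs(d2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  # PCA initialisation plus a small seeded jitter
  init <- stats::prcomp(m, center = TRUE)$x
  ncomp <- min(n_components, ncol(init))
  Y <- matrix(0, n, n_components)
  Y[, seq_len(ncomp)] <- init[, seq_len(ncomp)]
  Y <- Y / max(1e-12, stats::sd(as.vector(Y))) * 1e-2
  Y <- Y + matrix(stats::rnorm(n * n_components, sd = 1e-4), n)
  upd <- matrix(0, n, n_components)
  Pex <- P * 4  # early exaggeration
  for (it in seq_len(max_iter)) {
    Pit <- if (it <= 100) Pex else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    G <- 4 * ((Pit - Q) * num)
    grad <- t(vapply(seq_len(n), function(i) {
      colSums((matrix(Y[i, ], n, n_components, byrow = TRUE) - Y) * G[i, ])
    }, numeric(n_components)))
    upd <- momentum * upd - eta * grad
    Y <- Y + upd
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- paste0("TSNE", seq_len(n_components))
  rownames(Y) <- rownames(m)
  Y
}
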