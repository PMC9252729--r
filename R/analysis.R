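# Feature analysis: 2 normalizations, 10 clustering algorithms and 3
# dimensionality reductions over feature tibbles. Fitted objects carry
# broom-style tidy()/glance() methods and ggplot2 autoplot().

#' Normalize a feature tibble
#'
#' `zscore` rescales every feature column to mean 0 and population standard
#' deviation 1 (idempotent); `minmax` to the range 0..1. Constant columns
#' map to all-zeros under both methods.
#'
#' @param tbl feature tibble.
#' @param method `"zscore"` or `"minmax"`.
#' @return feature tibble of identical shape.
#' @export
normalize_features <- function(tbl, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  m <- feature_values(tbl)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty feature matrix")
  if (method == "zscore" && nrow(m) < 2) stop("zscore needs >= 2 samples")
  out <- apply(m, 2, function(col) {
    if (method == "zscore") {
      mu <- mean(col)
      sdev <- sqrt(mean((col - mu)^2))
      if (sdev == 0) rep(0, length(col)) else (col - mu) / sdev
    } else {
      rng <- max(col) - min(col)
      if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
    }
  })
  out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  feature_tbl(out, tbl$id, feature_labels(tbl))
}

# --- in-package clustering primitives ---------------------------------------
dbscan_fit <- function(m, eps = 0.5, min_pts = 5) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  labels <- rep(0L, n)  # 0 = unvisited, -1 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    nb <- which(d[i, ] <= eps)
    if (length(nb) < min_pts) { labels[i] <- -1L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cl
      if (labels[j] != 0L) next
      labels[j] <- cl
      nbj <- which(d[j, ] <= eps)
      if (length(nbj) >= min_pts) queue <- c(queue, setdiff(nbj, j))
    }
  }
  labels[labels == -1L] <- -1L
  labels
}

minibatch_kmeans_fit <- function(m, k, batch = 10, iters = 100) {
  n <- nrow(m)
  centers <- m[sample.int(n, k), , drop = FALSE]
  counts <- rep(0, k)
  for (it in seq_len(iters)) {
    idx <- sample.int(n, min(batch, n))
    for (i in idx) {
      dc <- colSums((t(centers) - m[i, ])^2)
      c_i <- which.min(dc)
      counts[c_i] <- counts[c_i] + 1
      eta <- 1 / counts[c_i]
      centers[c_i, ] <- (1 - eta) * centers[c_i, ] + eta * m[i, ]
    }
  }
  apply(m, 1, function(x) which.min(colSums((t(centers) - x)^2)))
}

markov_cluster_fit <- function(m, inflation = 2, expansion = 2,
                               prune = 1e-5, max_iter = 100, sigma = NULL) {
  n <- nrow(m)
  d2 <- as.matrix(stats::dist(m))^2
  if (is.null(sigma)) {
    pos <- d2[upper.tri(d2)]
    sigma <- if (length(pos) && stats::median(pos) > 0) stats::median(pos) else 1
  }
  A <- exp(-d2 / sigma)
  # keep each node's k nearest similarities (symmetrized) so the walk
  # operates on a sparse similarity graph
  k_nn <- max(3L, ceiling(log(n)) + 1L)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    keep[i, ord[seq_len(min(n, k_nn + 1L))]] <- TRUE
  }
  A[!(keep | t(keep))] <- 0
  diag(A) <- 1  # self loops
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M
    for (e in seq_len(expansion - 1)) M2 <- M2 %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2, pmax(colSums(M2), .Machine$double.eps), "/")
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; break }
    M <- M2
  }
  # attractors: rows with positive diagonal; cluster = attractor set reached
  attract <- M > 1e-6
  g <- igraph::graph_from_adjacency_matrix((attract | t(attract)) * 1,
                                           mode = "undirected")
  igraph::components(g)$membership
}

affinity_propagation_fit <- function(m, damping = 0.9, max_iter = 200,
                                     preference = NULL) {
  n <- nrow(m)
  S <- -as.matrix(stats::dist(m))^2
  if (is.null(preference)) preference <- stats::median(S[upper.tri(S)])
  diag(S) <- preference
  R <- A <- matrix(0, n, n)
  for (it in seq_len(max_iter)) {
    AS <- A + S
    max1 <- apply(AS, 1, function(r) {
      i1 <- which.max(r); m1 <- r[i1]; r[i1] <- -Inf
      c(i1, m1, max(r))
    })
    Rn <- S - matrix(max1[2, ], n, n)
    Rn[cbind(seq_len(n), max1[1, ])] <- S[cbind(seq_len(n), max1[1, ])] - max1[3, ]
    R <- damping * R + (1 - damping) * Rn
    Rp <- pmax(R, 0)
    cs <- colSums(Rp)
    An <- pmin(matrix(cs, n, n, byrow = TRUE) - Rp +
                 matrix(diag(R), n, n, byrow = TRUE) -
                 matrix(diag(Rp), n, n, byrow = TRUE), 0)
    diag(An) <- cs - diag(Rp)
    A <- damping * A + (1 - damping) * An
  }
  ex <- which(diag(R + A) > 0)
  if (!length(ex)) ex <- which.max(diag(R + A))
  assign_to <- apply(S[, ex, drop = FALSE], 1, which.max)
  assign_to[ex] <- seq_along(ex)
  as.integer(factor(assign_to))
}

mean_shift_fit <- function(m, bandwidth = NULL, max_iter = 100, tol = 1e-4) {
  n <- nrow(m)
  if (is.null(bandwidth)) {
    d <- stats::dist(m)
    bandwidth <- max(stats::quantile(d, 0.3), 1e-6)
  }
  modes <- m
  for (i in seq_len(n)) {
    x <- m[i, ]
    for (it in seq_len(max_iter)) {
      w <- exp(-colSums((t(m) - x)^2) / (2 * bandwidth^2))
      newx <- colSums(m * w) / sum(w)
      if (sqrt(sum((newx - x)^2)) < tol) { x <- newx; break }
      x <- newx
    }
    modes[i, ] <- x
  }
  # merge modes closer than bandwidth/2
  labels <- rep(NA_integer_, n)
  centers <- NULL
  for (i in seq_len(n)) {
    if (!is.null(centers)) {
      dd <- sqrt(rowSums((centers - matrix(modes[i, ], nrow(centers), ncol(m),
                                           byrow = TRUE))^2))
      j <- which(dd < bandwidth / 2)
      if (length(j)) { labels[i] <- j[[1]]; next }
    }
    centers <- rbind(centers, modes[i, ])
    labels[i] <- nrow(centers)
  }
  labels
}

#' Cluster a feature tibble
#'
#' Ten algorithms: `kmeans`, `minibatch_kmeans`, `gaussian_mixture`,
#' `hierarchical_agglomerative` (cut at `k`), `spectral`,
#' `markov_clustering`, `hclust_tree_cut` (cut at height `h`),
#' `affinity_propagation`, `mean_shift` and `dbscan` (noise id -1).
#' Results are deterministic for a fixed `seed`.
#'
#' @param tbl feature tibble.
#' @param method algorithm name.
#' @param k number of clusters (methods that need it).
#' @param seed integer seed for the stochastic algorithms.
#' @param ... algorithm parameters (`eps`, `min_pts`, `h`, `bandwidth`,
#'   `inflation`, `expansion`, `prune`, `damping`, `preference`, `batch`).
#' @return an object of class `omega_cluster`.
#' @export
cluster_features <- function(tbl, method, k = 2, seed = 1, ...) {
  methods10 <- list_analysis_algorithms()
  methods10 <- methods10$name[methods10$type == "cluster"]
  if (!method %in% methods10) stop("unknown clustering method: ", method)
  m <- feature_values(tbl)
  if (any(!is.finite(m))) stop("non-finite values in feature matrix")
  if (k > nrow(m)) stop("k larger than the number of samples")
  dots <- list(...)
  ids <- with_local_seed(seed, {
    switch(method,
      kmeans = stats::kmeans(m, centers = k, nstart = 10)$cluster,
      minibatch_kmeans = do.call(minibatch_kmeans_fit, c(list(m, k), dots)),
      gaussian_mixture = {
        mclustBIC <- mclust::mclustBIC  # visible to Mclust's deferred eval
        fit <- mclust::Mclust(m, G = k, verbose = FALSE)
        fit$classification
      },
      hierarchical_agglomerative = stats::cutree(
        stats::hclust(stats::dist(m), method = "ward.D2"), k = k),
      spectral = {
        if (nrow(m) <= k) stop("spectral clustering needs more samples than k")
        gamma <- if (!is.null(dots$gamma)) dots$gamma else 1 / ncol(m)
        as.integer(kernlab::specc(m, centers = k,
                                  kernel = "rbfdot", kpar = list(sigma = gamma)))
      },
      markov_clustering = do.call(markov_cluster_fit, c(list(m), dots)),
      hclust_tree_cut = {
        hc <- stats::hclust(stats::dist(m), method = "average")
        h <- if (!is.null(dots$h)) dots$h else mean(hc$height)
        stats::cutree(hc, h = h)
      },
      affinity_propagation = do.call(affinity_propagation_fit, c(list(m), dots)),
      mean_shift = do.call(mean_shift_fit, c(list(m), dots)),
      dbscan = do.call(dbscan_fit, c(list(m), dots))
    )
  })
  structure(list(cluster = as.integer(unname(ids)), ids = tbl$id,
                 method = method, k = k, seed = seed, params = dots),
            class = "omega_cluster")
}

#' @export
print.omega_cluster <- function(x, ...) {
  cat("<", x$method, " clustering: ", length(unique(x$cluster[x$cluster != -1])),
      " cluster(s), ", sum(x$cluster == -1), " noise point(s)>\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy omega_cluster
#' @export
tidy.omega_cluster <- function(x, ...) {
  tibble::tibble(id = x$ids, cluster = x$cluster)
}

#' @method glance omega_cluster
#' @export
glance.omega_cluster <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n = length(x$ids),
                 n_clusters = length(unique(x$cluster[x$cluster != -1])),
                 n_noise = sum(x$cluster == -1),
                 seed = x$seed)
}

# --- dimensionality reduction ------------------------------------------------

#' Reduce a feature tibble to a low-dimensional embedding
#'
#' `pca` (orthonormal components, non-increasing explained variance),
#' `tsne` (seed-reproducible stochastic embedding) and `lda` (supervised;
#' needs labels, `n_components <= classes - 1`).
#'
#' @param tbl feature tibble; `lda` uses its `label` column.
#' @param method `pca`, `tsne` or `lda`.
#' @param n_components embedding dimensionality.
#' @param seed integer seed.
#' @param ... t-SNE parameters (`perplexity`, `max_iter`).
#' @return an object of class `omega_reduction`.
#' @export
reduce_features <- function(tbl, method = c("pca", "tsne", "lda"),
                            n_components = 2, seed = 1, ...) {
  method <- match.arg(method)
  m <- feature_values(tbl)
  if (n_components > ncol(m)) stop("n_components exceeds the feature count")
  labels <- feature_labels(tbl)
  res <- with_local_seed(seed, {
    switch(method,
      pca = {
        p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
        ncomp <- min(n_components, ncol(p$x))
        list(coords = p$x[, seq_len(ncomp), drop = FALSE],
             explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(ncomp)],
             rotation = p$rotation[, seq_len(ncomp), drop = FALSE])
      },
      tsne = {
        list(coords = tsne_fit(m, n_components = n_components, ...),
             explained = NULL)
      },
      lda = {
        if (is.null(labels) || any(is.na(labels))) {
          stop("lda requires a fully labelled feature tibble")
        }
        ncl <- length(unique(labels))
        if (n_components > ncl - 1) stop("lda: n_components must be <= classes - 1")
        keep <- which(apply(m, 2, stats::var) > 1e-12)
        fit <- MASS::lda(m[, keep, drop = FALSE], grouping = factor(labels))
        sc <- stats::predict(fit)$x[, seq_len(n_components), drop = FALSE]
        list(coords = sc, explained = (fit$svd^2 / sum(fit$svd^2))[seq_len(n_components)])
      })
  })
  coords <- as.matrix(res$coords)
  colnames(coords) <- paste0(toupper(method), seq_len(ncol(coords)))
  structure(list(coords = coords, ids = tbl$id, labels = labels,
                 method = method, explained = res$explained, seed = seed),
            class = "omega_reduction")
}

#' @export
print.omega_reduction <- function(x, ...) {
  cat("<", x$method, " embedding: ", nrow(x$coords), " samples x ",
      ncol(x$coords), " component(s)>\n", sep = "")
  invisible(x)
}

#' @method tidy omega_reduction
#' @export
tidy.omega_reduction <- function(x, ...) {
  out <- tibble::as_tibble(x$coords)
  out <- dplyr::bind_cols(tibble::tibble(id = x$ids), out)
  if (!is.null(x$labels)) out$label <- x$labels
  out
}

#' @method glance omega_reduction
#' @export
glance.omega_reduction <- function(x, ...) {
  tibble::tibble(method = x$method, n = nrow(x$coords),
                 n_components = ncol(x$coords),
                 explained_variance = if (is.null(x$explained)) NA_real_ else
                   sum(x$explained),
                 seed = x$seed)
}
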