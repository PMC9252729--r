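# The nine plot kinds, ggplot2-based, written to PNG/JPG/PDF/TIFF.

utils::globalVariables(c("value", "feature", "id", "label", "x", "y", "xend",
                         "yend", "cluster", "comp1", "comp2"))

long_features <- function(tbl, max_features = NULL) {
  keep <- setdiff(names(tbl), c("id", "label"))
  if (!is.null(max_features)) keep <- keep[seq_len(min(length(keep), max_features))]
  out <- tidyr::pivot_longer(tbl[, c(intersect(names(tbl), c("id", "label")), keep)],
                             dplyr::all_of(keep),
                             names_to = "feature", values_to = "value")
  out
}

fd_bins <- function(x) {
  h <- 2 * stats::IQR(x) / max(1, length(x))^(1 / 3)
  if (h <= 0) return(10L)
  max(10L, ceiling((max(x) - min(x)) / h))
}

plot_histogram <- function(tbl, feature = NULL, ...) {
  lf <- long_features(tbl, if (is.null(feature)) 1 else NULL)
  if (!is.null(feature)) lf <- lf[lf$feature == feature, , drop = FALSE]
  bins <- fd_bins(lf$value)
  p <- ggplot2::ggplot(lf, ggplot2::aes(x = value))
  p <- if ("label" %in% names(lf) && !all(is.na(lf$label))) {
    p + ggplot2::geom_histogram(ggplot2::aes(fill = label), bins = bins,
                                position = "identity", alpha = 0.6)
  } else p + ggplot2::geom_histogram(bins = bins)
  p + ggplot2::facet_wrap(~feature, scales = "free") + ggplot2::theme_minimal()
}

plot_kde <- function(tbl, feature = NULL, ...) {
  lf <- long_features(tbl, if (is.null(feature)) 1 else NULL)
  if (!is.null(feature)) lf <- lf[lf$feature == feature, , drop = FALSE]
  p <- ggplot2::ggplot(lf, ggplot2::aes(x = value))
  p <- if ("label" %in% names(lf) && !all(is.na(lf$label))) {
    p + ggplot2::geom_density(ggplot2::aes(colour = label), bw = "nrd")
  } else p + ggplot2::geom_density(bw = "nrd")
  p + ggplot2::facet_wrap(~feature, scales = "free") + ggplot2::theme_minimal()
}

plot_heatmap <- function(tbl, max_features = 50, ...) {
  lf <- long_features(tbl, max_features)
  ggplot2::ggplot(lf, ggplot2::aes(x = feature, y = id, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5))
}

plot_boxplot <- function(tbl, max_features = 20, ...) {
  lf <- long_features(tbl, max_features)
  ggplot2::ggplot(lf, ggplot2::aes(x = feature, y = value)) +
    ggplot2::geom_boxplot() + ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

plot_line <- function(tbl, max_features = 50, ...) {
  lf <- long_features(tbl, max_features)
  lf$feature <- factor(lf$feature, levels = unique(lf$feature))
  ggplot2::ggplot(lf, ggplot2::aes(x = feature, y = value, group = id,
                                   colour = id)) +
    ggplot2::geom_line() + ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none")
}

plot_scatter <- function(x, colour_by = NULL, ...) {
  df <- if (inherits(x, "omega_reduction")) tidy(x) else x
  num <- setdiff(names(df), c("id", "label", "cluster"))
  if (length(num) < 2) stop("scatter needs a 2-D embedding")
  df$comp1 <- df[[num[1]]]; df$comp2 <- df[[num[2]]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = comp1, y = comp2))
  if (!is.null(colour_by) && colour_by %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data[[colour_by]])))
  } else if ("label" %in% names(df) && !all(is.na(df$label))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = label))
  } else p <- p + ggplot2::geom_point()
  p + ggplot2::labs(x = num[1], y = num[2]) + ggplot2::theme_minimal()
}

# samples on a rim; edges where pairwise Pearson correlation >= threshold
plot_circular <- function(tbl, threshold = 0.75,
                          metric = c("pearson", "euclidean", "cosine"), ...) {
  metric <- match.arg(metric)
  m <- feature_values(tbl)
  n <- nrow(m)
  sim <- switch(metric,
    pearson = stats::cor(t(m)),
    cosine = {
      nm <- m / sqrt(rowSums(m^2))
      nm %*% t(nm)
    },
    euclidean = {
      d <- as.matrix(stats::dist(m))
      1 - d / max(d, 1e-12)
    })
  ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  nodes <- tibble::tibble(id = tbl$id, x = cos(ang), y = sin(ang))
  edges <- NULL
  if (n > 1) {
    idx <- which(upper.tri(sim) & sim >= threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- tibble::tibble(x = nodes$x[idx[, 1]], y = nodes$y[idx[, 1]],
                              xend = nodes$x[idx[, 2]], yend = nodes$y[idx[, 2]])
    }
  }
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = x, y = y))
  if (!is.null(edges)) {
    p <- p + ggplot2::geom_segment(data = edges,
                                   ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
                                   colour = "steelblue", alpha = 0.6)
  }
  p + ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = id), nudge_y = 0.08, size = 2.5) +
    ggplot2::coord_equal() + ggplot2::theme_void()
}

# static backbone-trace projection of a structure model
plot_structure3d <- function(model, ...) {
  stopifnot(inherits(model, "omega_structure"))
  ca <- res_coords(model)
  # orthographic projection onto the two principal axes, depth as colour
  p <- stats::prcomp(ca)
  df <- tibble::tibble(x = p$x[, 1], y = p$x[, 2],
                       depth = if (ncol(p$x) > 2) p$x[, 3] else 0,
                       id = residue_ids(model))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = depth)) +
    ggplot2::geom_path(linewidth = 1) + ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() + ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "PC1 (Å)", y = "PC2 (Å)", colour = "depth (Å)")
}

# 2-D ligand depiction from the generated coordinates
plot_ligand2d <- function(mols, index = 1, ...) {
  stopifnot(inherits(mols, "omega_mols"))
  g <- mols$graphs[[index]]
  a <- g$atoms
  b <- g$bonds
  edges <- tibble::tibble(x = a$x[b$a], y = a$y[b$a],
                          xend = a$x[b$b], yend = a$y[b$b],
                          aromatic = b$aromatic)
  nodes <- tibble::tibble(x = a$x, y = a$y, element = a$element)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = x, y = y, xend = xend, yend = yend,
                                       linetype = aromatic)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = x, y = y, colour = element), size = 4) +
    ggplot2::geom_text(data = nodes[nodes$element != "C", ],
                       ggplot2::aes(x = x, y = y, label = element), size = 3) +
    ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(title = mols$ids[[index]])
}

#' Render one of the nine registered plot kinds to a file
#'
#' @param x a feature tibble, `omega_reduction`, `omega_cluster`-annotated
#'   tibble, `omega_structure` (for `structure3d`) or `omega_mols` (for
#'   `ligand2d`).
#' @param kind one of [list_plot_kinds()].
#' @param file output path; the extension (png/jpg/pdf/tiff) picks the device.
#' @param ... kind-specific options (`feature`, `threshold`, `metric`,
#'   `colour_by`, `max_features`, `index`, `width`, `height`).
#' @return the file path, invisibly.
#' @export
render_plot <- function(x, kind, file, ...) {
  if (!kind %in% list_plot_kinds()) stop("unknown plot kind: ", kind)
  dots <- list(...)
  if (is.data.frame(x) && nrow(x) == 0) stop("empty input")
  p <- switch(kind,
    histogram = plot_histogram(x, ...),
    kde = plot_kde(x, ...),
    heatmap = plot_heatmap(x, ...),
    boxplot = plot_boxplot(x, ...),
    line = plot_line(x, ...),
    scatter = plot_scatter(x, ...),
    circular = plot_circular(x, ...),
    structure3d = plot_structure3d(x, ...),
    ligand2d = plot_ligand2d(x, ...))
  ext <- tolower(sub("^.*\\.", "", file))
  if (!ext %in% c("png", "jpg", "jpeg", "pdf", "tiff", "tif")) {
    stop("unsupported image format: ", ext)
  }
  width <- if (!is.null(dots$width)) dots$width else 6
  height <- if (!is.null(dots$height)) dots$height else 5
  suppressMessages(ggplot2::ggsave(file, p, width = width, height = height,
                                   dpi = 120))
  invisible(file)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot omega_reduction
#' @export
autoplot.omega_reduction <- function(object, ...) plot_scatter(object, ...)

#' @method autoplot omega_cluster
#' @export
autoplot.omega_cluster <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(cluster))) +
    ggplot2::geom_bar() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "cluster", y = "samples")
}

#' @method autoplot omega_structure
#' @export
autoplot.omega_structure <- function(object, ...) plot_structure3d(object, ...)
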