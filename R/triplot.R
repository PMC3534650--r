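#' Group centroids and 95% confidence ellipses
#'
#' Per group of 2-D points: the centroid is the mean; the ellipse comes from
#' the eigendecomposition of the group covariance matrix with semi-axes
#' scaled by the 95% quantile of a chi-square with 2 degrees of freedom (the
#' bivariate-normal confidence region). Groups with fewer than 3 points get
#' a centroid only.
#'
#' @param points samples-by-2 coordinate matrix.
#' @param labels group label per row.
#' @param level confidence level (default 0.95).
#' @return data.frame with one row per group: centroid, semi-axes `a` >=
#'   `b` (NA when no ellipse), rotation angle (radians) and point count.
#' @export
group_centroid_ellipse <- function(points, labels, level = 0.95) {
  stopifnot(ncol(points) == 2L, nrow(points) == length(labels))
  q <- stats::qchisq(level, df = 2)
  groups <- unique(as.character(labels))
  out <- lapply(groups, function(g) {
    p <- points[labels == g, , drop = FALSE]
    ctr <- colMeans(p)
    if (nrow(p) < 3L) {
      ccam_log("group '", g, "' has <3 samples: centroid only")
      return(data.frame(group = g, cx = ctr[1], cy = ctr[2],
                        a = NA_real_, b = NA_real_, angle = NA_real_,
                        n = nrow(p)))
    }
    cv <- stats::cov(p)
    eg <- eigen(cv, symmetric = TRUE)
    ev <- pmax(eg$values, 0)  # rank-deficient covariance: semi-axis 0
    data.frame(group = g, cx = ctr[1], cy = ctr[2],
               a = sqrt(q * ev[1]), b = sqrt(q * ev[2]),
               angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
               n = nrow(p))
  })
  do.call(rbind, out)
}

#' Nearest environment arrow by angular distance
#'
#' Samples and environment arrows live in spaces of different size, so
#' Euclidean distance between levels is not meaningful; the angular distance
#' (arc cosine of the cosine similarity between coordinate vectors) is used
#' instead to relate samples to explanatory profiles.
#'
#' @param res a fitted `ccam` object.
#' @param dims number of leading axes used (default 2).
#' @return data.frame with `sample_id`, `nearest` (population label) and
#'   `angle` (radians).
#' @export
nearest_arrow <- function(res, dims = 2) {
  k <- length(res$lambdas)
  if (dims > k) stop("dims exceeds the number of positive axes (", k, ")",
                     call. = FALSE)
  S <- res$sample_scores[, seq_len(dims), drop = FALSE]
  B <- res$env_biplot[, seq_len(dims), drop = FALSE]
  Sn <- S / sqrt(rowSums(S^2))
  Bn <- B / sqrt(rowSums(B^2))
  cosim <- Sn %*% t(Bn)
  ang <- acos(pmin(pmax(cosim, -1), 1))
  j <- apply(ang, 1L, which.min)
  data.frame(sample_id = rownames(S), nearest = rownames(B)[j],
             angle = ang[cbind(seq_len(nrow(S)), j)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Render a triplot and write its coordinates
#'
#' Writes the plotted coordinates (the testable artifact) as TSV files plus
#' a static PNG; axis labels report each axis's percentage of the
#' constrained inertia. The nearest-arrow assignment of every sample by
#' angular distance is written alongside.
#'
#' @param res a fitted `ccam` object.
#' @param dir output directory.
#' @param dims 2 (default) or 3 displayed axes.
#' @param groups optional sample group labels for centroids/ellipses (2-D
#'   only).
#' @param image write a PNG (default TRUE; coordinates are always written).
#' @return the directory, invisibly.
#' @export
render_triplot <- function(res, dir, dims = 2, groups = NULL,
                           image = TRUE) {
  k <- length(res$lambdas)
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3", call. = FALSE)
  if (dims > k) {
    stop("requested ", dims, " axes but only ", k, " positive axes exist",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ax <- seq_len(dims)
  write_tsv_table(res$gene_scores_wa[, ax, drop = FALSE],
                  file.path(dir, "triplot_genes.tsv"), row_label = "gene_id")
  write_tsv_table(res$sample_scores[, ax, drop = FALSE],
                  file.path(dir, "triplot_samples.tsv"),
                  row_label = "sample_id")
  write_tsv_table(res$env_biplot[, ax, drop = FALSE],
                  file.path(dir, "triplot_env.tsv"), row_label = "population")
  na <- nearest_arrow(res, dims = dims)
  write_tsv_table(na, file.path(dir, "nearest_arrow.tsv"))
  if (!is.null(groups) && dims == 2) {
    ce <- group_centroid_ellipse(res$sample_scores[, 1:2, drop = FALSE],
                                 groups)
    write_tsv_table(ce, file.path(dir, "centroids_ellipses.tsv"))
  }
  if (image && dims == 2) {
    png(file.path(dir, "triplot.png"), width = 900, height = 900)
    on.exit(dev.off())
    plot_triplot_2d(res, groups)
  }
  invisible(dir)
}

# base-graphics 2-D triplot: grey genes, coloured samples, blue arrows
plot_triplot_2d <- function(res, groups = NULL) {
  g <- res$gene_scores_wa[, 1:2, drop = FALSE]
  s <- res$sample_scores[, 1:2, drop = FALSE]
  b <- res$env_biplot[, 1:2, drop = FALSE]
  sc <- max(abs(s)) * 0.9
  b_disp <- b * sc / max(abs(b))
  lim <- range(c(g, s, b_disp))
  labs <- sprintf("Axis%d (%.1f%% of constrained inertia)", 1:2,
                  100 * res$axis_fractions[1:2])
  plot(g, pch = 16, col = "grey80", cex = 0.5, xlim = lim, ylim = lim,
       xlab = labs[1], ylab = labs[2], asp = 1)
  abline(h = 0, v = 0, col = "grey60", lty = 3)
  if (is.null(groups)) {
    points(s, pch = 16, col = "black", cex = 0.8)
  } else {
    f <- factor(groups)
    cols <- rainbow(nlevels(f))
    points(s, pch = 16, col = cols[f], cex = 0.8)
    legend("topright", legend = levels(f), col = cols, pch = 16, bty = "n")
  }
  arrows(0, 0, b_disp[, 1], b_disp[, 2], col = "blue", length = 0.1)
  text(b_disp * 1.06, labels = rownames(b), col = "blue", cex = 0.9)
}

#' Overlay a clinical covariate on sample coordinates
#'
#' Recolors the sample points of a fitted map by a clinical covariate;
#' missing values are rendered neutral (grey) and logged. The companion TSV
#' carries the coordinates and the covariate.
#'
#' @param res a fitted `ccam` object.
#' @param covariate named vector (names = sample ids) of a categorical or
#'   ordinal covariate.
#' @param dir output directory.
#' @param name covariate name used in file names and the legend.
#' @param image write a PNG (default TRUE).
#' @return the TSV path, invisibly.
#' @export
overlay_clinical <- function(res, covariate, dir, name = "covariate",
                             image = TRUE) {
  s <- res$sample_scores[, 1:2, drop = FALSE]
  v <- covariate[rownames(s)]
  if (all(is.na(v))) stop("covariate missing for all plotted samples",
                          call. = FALSE)
  n_miss <- sum(is.na(v))
  if (n_miss) ccam_log(n_miss, " sample(s) missing '", name,
                       "': rendered neutral")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(sample_id = rownames(s), Axis1 = s[, 1], Axis2 = s[, 2],
                    value = as.character(v), stringsAsFactors = FALSE)
  path <- file.path(dir, paste0("overlay_", name, ".tsv"))
  write_tsv_table(tab, path)
  if (image) {
    png(file.path(dir, paste0("overlay_", name, ".png")),
        width = 900, height = 900)
    on.exit(dev.off())
    f <- factor(v)  # ordinal covariates keep their rank order of levels
    cols <- rainbow(nlevels(f))
    col <- ifelse(is.na(v), "grey80", cols[f])
    labs <- sprintf("Axis%d (%.1f%% of constrained inertia)", 1:2,
                    100 * res$axis_fractions[1:2])
    plot(s, pch = 16, col = col, xlab = labs[1], ylab = labs[2], asp = 1)
    legend("topright", legend = levels(f), col = cols, pch = 16, bty = "n",
           title = name)
  }
  invisible(path)
}
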