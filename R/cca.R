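#' Chi-square-metric standardization of a nonnegative matrix
#'
#' The matrix is divided by its grand total to give `P`; row masses `r` and
#' column masses `c` are the margins of `P`; the standardized residual matrix
#' is \eqn{\bar{Q} = D_r^{-1/2}(P - r c^T)D_c^{-1/2}}. The sum of squares of
#' \eqn{\bar{Q}} is the total inertia (the Pearson chi-square statistic of
#' the table divided by its grand total).
#'
#' @param s nonnegative numeric matrix with positive row and column sums.
#' @return list with `P`, `r`, `c`, `Qbar`, `grand_total`.
#' @export
chi_square_form <- function(s) {
  if (any(s < 0)) {
    stop("negative entries: apply shift_nonnegative() first", call. = FALSE)
  }
  tot <- sum(s)
  if (tot <= 0) stop("matrix has zero grand total", call. = FALSE)
  P <- s / tot
  r <- rowSums(P)
  cc <- colSums(P)
  if (any(r == 0)) stop("all-zero gene row(s) present", call. = FALSE)
  if (any(cc == 0)) stop("all-zero sample column(s) present", call. = FALSE)
  Qbar <- (P - tcrossprod(r, cc)) / sqrt(tcrossprod(r, cc))
  list(P = P, r = r, c = cc, Qbar = Qbar, grand_total = tot)
}

#' Build the environment (explanatory) matrix from a reference dataset
#'
#' Column `j` is the per-gene mean over the samples of population `j` in the
#' (already z-scored) reference matrix. Weighted standardization against the
#' main matrix's row masses happens later, inside [cca_fit()].
#'
#' @param ref z-scored gene-by-sample reference matrix, genes aligned with
#'   the main matrix.
#' @param group population label per column of `ref`.
#' @param populations which populations to use (default: all, in order of
#'   first appearance).
#' @return genes-by-populations matrix `Z`.
#' @export
build_environment <- function(ref, group, populations = NULL) {
  validate_expr(ref, "reference matrix")
  group <- as.character(group)
  if (length(group) != ncol(ref)) {
    stop("one population label per reference sample is required",
         call. = FALSE)
  }
  if (is.null(populations)) populations <- unique(group)
  unknown <- setdiff(populations, group)
  if (length(unknown)) {
    stop("unknown population label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  Z <- vapply(populations,
              function(p) rowMeans(ref[, group == p, drop = FALSE]),
              numeric(nrow(ref)))
  dimnames(Z) <- list(rownames(ref), populations)
  Z
}

#' Screen environment columns for collinearity
#'
#' Reports the pairwise Pearson correlation matrix and a variance inflation
#' factor per column, flagging |r| above `r_max` and VIF above `vif_max`.
#' Highly collinear explanatory profiles should be dropped before fitting.
#'
#' @param Z genes-by-populations environment matrix.
#' @param r_max correlation flag threshold (default 0.95).
#' @param vif_max VIF flag threshold (default 10).
#' @return list with `correlation`, `vif` (Inf for exactly dependent
#'   columns), `flagged_pairs`, `flagged_vif`.
#' @export
check_env_collinearity <- function(Z, r_max = 0.95, vif_max = 10) {
  if (ncol(Z) < 2L) stop("need at least 2 populations", call. = FALSE)
  R <- cor(Z)
  vif <- vapply(seq_len(ncol(Z)), function(j) {
    others <- Z[, -j, drop = FALSE]
    fit <- lm.fit(cbind(1, others), Z[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((Z[, j] - mean(Z[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(Z)
  pairs <- which(abs(R) > r_max & upper.tri(R), arr.ind = TRUE)
  flagged_pairs <- if (nrow(pairs)) {
    data.frame(var1 = colnames(Z)[pairs[, 1]],
               var2 = colnames(Z)[pairs[, 2]],
               r = R[pairs], stringsAsFactors = FALSE)
  } else {
    data.frame(var1 = character(), var2 = character(), r = numeric())
  }
  list(correlation = R, vif = vif, flagged_pairs = flagged_pairs,
       flagged_vif = names(vif)[!is.finite(vif) | vif > vif_max])
}

# r-weighted standardization of the environment columns: each column gets
# weighted mean 0 and weighted variance 1 under the row masses r.
weighted_standardize <- function(Z, r) {
  mu <- as.vector(crossprod(Z, r))
  Zc <- sweep(Z, 2L, mu)
  v <- as.vector(crossprod(Zc^2, r))
  if (any(v <= 0)) {
    stop("environment column(s) constant under row weights: ",
         paste(colnames(Z)[v <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(Zc, 2L, sqrt(v), "/")
}

#' Canonical correspondence analysis of a main matrix on environment profiles
#'
#' The main matrix is put in chi-square form, the environment columns are
#' standardized with the row masses as weights, and the standardized residual
#' matrix is projected onto the weighted environment space:
#' \eqn{Z_w = D_r^{1/2} Z_{std}}, \eqn{H = Z_w (Z_w^T Z_w)^{-1} Z_w^T},
#' \eqn{Q_c = H \bar{Q}}. The SVD \eqn{Q_c = U \Lambda V^T} (positive
#' singular values, descending) yields the axes. Sample (column) scores are
#' \eqn{D_c^{-1/2} V}; constrained (lc) gene scores are \eqn{D_r^{-1/2} U};
#' weighted-average (wa) gene scores on axis k are
#' \eqn{(D_r^{-1} P \, \mathrm{samplescore}_k)/\lambda_k}. Eigenvalues are
#' \eqn{\lambda_k^2}; their sum is the constrained inertia, and the ratio of
#' constrained to total inertia is %Explained.
#'
#' @param s nonnegative gene-by-sample main matrix ("dataset to be
#'   explained").
#' @param Z genes-by-populations environment matrix (rows aligned with `s`).
#' @param scaling triplot scaling: 0 leaves all scores as standard
#'   coordinates, 1 multiplies gene scores by the singular values, 2
#'   (default) multiplies sample scores.
#' @param rank_tol singular values below `rank_tol * lambda_1` are treated
#'   as zero.
#' @return object of class `ccam`, a list with elements `U`, `V`, `lambdas`,
#'   `eigenvalues`, `gene_scores_lc`, `gene_scores_wa`, `sample_scores`,
#'   `env_biplot`, `inertia_total`, `inertia_constrained`,
#'   `percent_explained`, `axis_fractions`, `scaling`, `chi_form`, `Zstd`.
#' @export
cca_fit <- function(s, Z, scaling = 2, rank_tol = 1e-12) {
  validate_expr(s, "main matrix")
  if (!identical(rownames(s), rownames(Z))) {
    stop("gene rows of the main and environment matrices differ; ",
         "use align_genes()", call. = FALSE)
  }
  if (!scaling %in% c(0, 1, 2)) stop("scaling must be 0, 1 or 2",
                                     call. = FALSE)
  if (ncol(Z) >= ncol(s)) {
    stop("overfit: the number of explanatory variables (", ncol(Z),
         ") must be less than the number of samples (", ncol(s), ")",
         call. = FALSE)
  }
  cf <- chi_square_form(s)
  Zstd <- weighted_standardize(Z, cf$r)
  Zw <- Zstd * sqrt(cf$r)
  G <- crossprod(Zw)
  qz <- qr(Zw)
  if (qz$rank < ncol(Zw)) {
    aliased <- colnames(Zw)[qz$pivot[(qz$rank + 1L):ncol(Zw)]]
    stop("environment columns are linearly dependent under the row ",
         "weights (aliased: ", paste(aliased, collapse = ", "),
         "); drop collinear populations (see check_env_collinearity)",
         call. = FALSE)
  }
  Ginv <- solve(G)
  # H Qbar without forming the n_genes x n_genes projector
  Qc <- Zw %*% (Ginv %*% crossprod(Zw, cf$Qbar))

  sv <- svd(Qc)
  keep <- sv$d > rank_tol * sv$d[1] & sv$d > 0
  if (!any(keep)) {
    lam <- numeric(0)
    U <- matrix(0, nrow(s), 0)
    V <- matrix(0, ncol(s), 0)
  } else {
    lam <- sv$d[keep]
    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
  }
  k <- length(lam)
  axnames <- if (k) paste0("Axis", seq_len(k)) else character(0)

  sample_std <- V / sqrt(cf$c)            # D_c^{-1/2} V
  gene_lc <- U / sqrt(cf$r)               # D_r^{-1/2} U
  gene_wa <- if (k) {
    sweep((cf$P %*% sample_std) / cf$r, 2L, lam, "/")
  } else matrix(0, nrow(s), 0)

  inertia_total <- sum(cf$Qbar^2)
  inertia_constrained <- sum(lam^2)

  res <- structure(list(
    U = U, V = V, lambdas = lam, eigenvalues = lam^2,
    gene_scores_lc = gene_lc, gene_scores_wa = gene_wa,
    sample_scores = sample_std, env_biplot = NULL,
    inertia_total = inertia_total,
    inertia_constrained = inertia_constrained,
    percent_explained = 100 * inertia_constrained / inertia_total,
    axis_fractions = if (k) lam^2 / inertia_constrained else numeric(0),
    scaling = scaling, chi_form = cf, Zstd = Zstd
  ), class = "ccam")

  res$env_biplot <- env_arrow_scores(res)

  # deterministic sign convention: orient each axis so the environment
  # arrow with the largest absolute loading points positive
  if (k) {
    for (a in seq_len(k)) {
      b <- res$env_biplot[, a]
      if (b[which.max(abs(b))] < 0) {
        res$U[, a] <- -res$U[, a]
        res$V[, a] <- -res$V[, a]
        res$gene_scores_lc[, a] <- -res$gene_scores_lc[, a]
        res$gene_scores_wa[, a] <- -res$gene_scores_wa[, a]
        res$sample_scores[, a] <- -res$sample_scores[, a]
        res$env_biplot[, a] <- -res$env_biplot[, a]
      }
    }
  }

  # apply the display scaling after sign fixing
  if (k && scaling == 1) {
    res$gene_scores_lc <- sweep(res$gene_scores_lc, 2L, lam, "*")
    res$gene_scores_wa <- sweep(res$gene_scores_wa, 2L, lam, "*")
  } else if (k && scaling == 2) {
    res$sample_scores <- sweep(res$sample_scores, 2L, lam, "*")
  }

  dn <- function(m, rn) { dimnames(m) <- list(rn, axnames); m }
  res$gene_scores_lc <- dn(res$gene_scores_lc, rownames(s))
  res$gene_scores_wa <- dn(res$gene_scores_wa, rownames(s))
  res$sample_scores <- dn(res$sample_scores, colnames(s))
  res$env_biplot <- dn(res$env_biplot, colnames(Z))
  res
}

#' Environment arrow (biplot) scores
#'
#' Arrow coordinates are the weighted (by row mass) Pearson correlations
#' between each standardized environment column and the weighted-average gene
#' scores of each axis — equivalently the standardized regression coefficient
#' of a single-regressor weighted regression of the axis on the column.
#'
#' @param res a fitted `ccam` object.
#' @param Zstd optional standardized environment matrix (defaults to the one
#'   stored in `res`).
#' @return populations-by-axes matrix `B`.
#' @export
env_arrow_scores <- function(res, Zstd = NULL) {
  if (is.null(Zstd)) Zstd <- res$Zstd
  r <- res$chi_form$r
  k <- length(res$lambdas)
  if (k == 0L) return(matrix(0, ncol(Zstd), 0))
  # wa scores in standard coordinates, independent of the display scaling
  sample_std <- res$V / sqrt(res$chi_form$c)
  wa <- sweep((res$chi_form$P %*% sample_std) / r, 2L, res$lambdas, "/")
  B <- vapply(seq_len(k), function(a) {
    w <- wa[, a]
    wm <- sum(r * w)
    wc <- w - wm
    denom <- sqrt(sum(r * wc^2))
    as.vector(crossprod(Zstd, r * wc)) / denom
  }, numeric(ncol(Zstd)))
  B <- matrix(B, nrow = ncol(Zstd))
  rownames(B) <- colnames(Zstd)
  B
}

#' Share of constrained inertia shown in the first axes
#'
#' @param res a fitted `ccam` object.
#' @param dims number of displayed axes.
#' @return percentage in (0, 100].
#' @export
percent_visualised <- function(res, dims) {
  k <- length(res$eigenvalues)
  if (dims < 1 || dims > k) {
    stop("dims must be between 1 and ", k, call. = FALSE)
  }
  100 * sum(res$eigenvalues[seq_len(dims)]) / res$inertia_constrained
}

#' Inertia decomposition report
#'
#' Total inertia splits into the constrained part (captured by the regression
#' on the environment profiles) and the unconstrained remainder. %Explained
#' is comparable between fits only when the same genes and the same main
#' matrix are used, so the report carries a fingerprint of both.
#'
#' @param res a fitted `ccam` object.
#' @return list with `total`, `constrained`, `unconstrained`,
#'   `percent_explained`, `axis_eigenvalues`, `axis_fractions`,
#'   `fingerprint`.
#' @export
decompose_inertia <- function(res) {
  cf <- res$chi_form
  fp <- sprintf("%d genes x %d samples; grand total %.10g",
                nrow(cf$P), ncol(cf$P), cf$grand_total)
  list(
    total = res$inertia_total,
    constrained = res$inertia_constrained,
    unconstrained = res$inertia_total - res$inertia_constrained,
    percent_explained = res$percent_explained,
    axis_eigenvalues = res$eigenvalues,
    axis_fractions = res$axis_fractions,
    fingerprint = fp
  )
}

#' @export
print.ccam <- function(x, ...) {
  cat("Canonical correspondence analysis (chi-square metric)\n")
  cat(sprintf("  %d genes x %d samples, %d environment variables\n",
              nrow(x$gene_scores_wa), nrow(x$sample_scores),
              nrow(x$env_biplot)))
  cat(sprintf("  Total inertia:       %.6g\n", x$inertia_total))
  cat(sprintf("  Constrained inertia: %.6g (%%Explained = %.2f)\n",
              x$inertia_constrained, x$percent_explained))
  k <- length(x$eigenvalues)
  if (k) {
    cat("  Eigenvalues (share of constrained inertia):\n")
    for (a in seq_len(min(k, 6L))) {
      cat(sprintf("    Axis%-2d %.6g (%.1f%%)\n", a, x$eigenvalues[a],
                  100 * x$axis_fractions[a]))
    }
    if (k > 6L) cat("    ...\n")
  }
  invisible(x)
}
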