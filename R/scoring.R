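#' Pick the axis most associated with a population of interest
#'
#' Interpreting the axes through their relationship with the explanatory
#' variables is the first map-analysis step; this helper returns the axis
#' whose biplot arrow for the given population has the largest absolute
#' loading (e.g. the stemness axis when passed the stem-cell population).
#'
#' @param res a fitted `ccam` object.
#' @param population row name of `res$env_biplot`.
#' @return axis index.
#' @export
select_axis <- function(res, population) {
  if (!population %in% rownames(res$env_biplot)) {
    stop("unknown population: ", population, call. = FALSE)
  }
  which.max(abs(res$env_biplot[population, ]))
}

#' Build an axis-derived prognostic score model
#'
#' Genes are ranked by their weighted-average (wa) score on one ordination
#' axis; the `n_top` highest and `n_bottom` lowest genes define the model
#' (the pattern of the HSC-CMP score: high-scoring genes mark one end of the
#' axis, low-scoring genes the other). Ties are broken by gene identifier.
#'
#' @param res a fitted `ccam` object.
#' @param axis axis number (default 1).
#' @param n_top,n_bottom list sizes (default 100 each). When fewer genes are
#'   available the lists are truncated with a warning, split by wa-score
#'   sign.
#' @return object of class `ccam_axis_score`: list with `axis`, `top_genes`,
#'   `bottom_genes`, `combination`.
#' @export
build_axis_score <- function(res, axis = 1, n_top = 100, n_bottom = 100) {
  k <- length(res$lambdas)
  if (axis < 1 || axis > k) stop("axis must be between 1 and ", k,
                                 call. = FALSE)
  wa <- res$gene_scores_wa[, axis]
  lists <- axis_gene_lists(wa, n_top, n_bottom)
  structure(list(axis = axis, top_genes = lists$top,
                 bottom_genes = lists$bottom,
                 combination = "mean_difference"),
            class = "ccam_axis_score")
}

# rank a named wa-score vector into disjoint top/bottom gene lists;
# ties broken by gene identifier
axis_gene_lists <- function(wa, n_top, n_bottom) {
  genes <- names(wa)
  desc <- genes[order(-wa, genes)]
  asc <- genes[order(wa, genes)]
  n <- length(genes)
  if (n < n_top + n_bottom) {
    warning("only ", n, " genes available; splitting by wa-score sign",
            call. = FALSE)
    top <- head(desc[wa[desc] > 0], n_top)
    bottom <- head(asc[wa[asc] <= 0], n_bottom)
  } else {
    top <- desc[seq_len(n_top)]
    bottom <- head(setdiff(asc, top), n_bottom)
  }
  list(top = top, bottom = bottom)
}

#' Score samples with an axis score model
#'
#' The matrix is z-scored per gene; each sample's score is the mean of its
#' z-scores over the top genes minus the mean over the bottom genes, then
#' z-scaled across samples. The combination rule is monotone in the same
#' direction as the wa ranking and robust to unequal list sizes.
#'
#' @param model a `ccam_axis_score`.
#' @param x gene-by-sample expression matrix containing at least one top and
#'   one bottom gene.
#' @param scale z-scale the final scores across samples (default TRUE).
#' @return named numeric vector of per-sample scores.
#' @export
score_samples <- function(model, x, scale = TRUE) {
  top <- intersect(model$top_genes, rownames(x))
  bottom <- intersect(model$bottom_genes, rownames(x))
  if (length(top) < 1L || length(bottom) < 1L) {
    stop("need at least one top and one bottom gene present in the matrix",
         call. = FALSE)
  }
  z <- zscore_genes(x)
  top <- intersect(top, rownames(z))
  bottom <- intersect(bottom, rownames(z))
  sc <- colMeans(z[top, , drop = FALSE]) -
    colMeans(z[bottom, , drop = FALSE])
  if (scale) {
    s <- sd(sc)
    if (!is.finite(s) || s == 0) {
      stop("scores are constant across samples; z-scaling is undefined",
           call. = FALSE)
    }
    sc <- (sc - mean(sc)) / s
  }
  sc
}

#' Stratify scores at percentile cuts
#'
#' Samples are assigned ordinal strata `1..k+1` by `k` strictly increasing
#' percentile cuts; a score exactly equal to a cut value goes to the lower
#' stratum. Cut values (type-7 quantiles) are recorded in the result.
#'
#' @param scores named numeric vector (finite).
#' @param cuts percentiles in (0, 100), strictly increasing; the defaults of
#'   the prognostic analyses are `c(50)` (median split) and `c(50, 95)`.
#' @return data.frame with `sample_id`, `score`, `stratum` (ordered factor);
#'   attribute `cut_values`.
#' @export
stratify <- function(scores, cuts = 50) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (any(cuts <= 0 | cuts >= 100) || is.unsorted(cuts, strictly = TRUE)) {
    stop("cuts must be strictly increasing percentiles in (0, 100)",
         call. = FALSE)
  }
  cv <- quantile(scores, probs = cuts / 100, type = 7, names = FALSE)
  stratum <- vapply(scores, function(s) sum(s > cv), numeric(1)) + 1L
  out <- data.frame(
    sample_id = if (is.null(names(scores))) seq_along(scores)
                else names(scores),
    score = unname(scores),
    stratum = factor(stratum, levels = seq_len(length(cuts) + 1L),
                     ordered = TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "cut_values") <- cv
  attr(out, "cuts") <- cuts
  out
}
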