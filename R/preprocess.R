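#' Validate a gene-by-sample expression matrix
#'
#' The package represents expression data as a plain numeric matrix with
#' unique gene identifiers as row names and unique sample identifiers as
#' column names; no missing values are allowed.
#'
#' @param x numeric matrix.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
validate_expr <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) == 0L || ncol(x) == 0L) {
    stop(what, " is empty", call. = FALSE)
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop(what, " must have unique gene identifiers as row names", call. = FALSE)
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop(what, " must have unique sample identifiers as column names",
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(what, " contains missing or non-finite values", call. = FALSE)
  }
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Expects gene identifiers in the first column and sample identifiers in the
#' header row. Duplicate gene rows are collapsed by their mean (and logged).
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
load_expression <- function(path, sep = "\t") {
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty expression matrix in ", path, call. = FALSE)
  }
  genes <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(NULL, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value %s at row %d (gene '%s'), column '%s' of %s",
        dQuote(body[[j]][bad[1L]]), bad[1L], genes[bad[1L]],
        colnames(body)[j], path), call. = FALSE)
    }
    vals[, j] <- v
  }
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    ccam_log(ndup, " duplicate gene row(s) collapsed by mean")
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    rownames(vals) <- unique(genes)
  } else {
    rownames(vals) <- genes
  }
  validate_expr(vals)
  vals
}

#' Read a sample annotation table
#'
#' Columns: `sample_id`, `group`, optional `batch`, plus any clinical columns.
#'
#' @param path path to a TSV file.
#' @return data.frame keyed by `sample_id`.
#' @export
load_annotation <- function(path) {
  ann <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(ann))) {
    stop("annotation must contain 'sample_id' and 'group' columns",
         call. = FALSE)
  }
  if (anyDuplicated(ann$sample_id)) {
    stop("duplicate sample_id in annotation", call. = FALSE)
  }
  ann
}

#' Restrict two expression matrices to their common genes
#'
#' Cross-platform matching is by exact identifier intersection; both outputs
#' share the same row order (sorted identifiers).
#'
#' @param a,b numeric gene-by-sample matrices.
#' @return list with elements `a` and `b`, rows restricted and ordered alike.
#' @export
align_genes <- function(a, b) {
  validate_expr(a, "first matrix")
  validate_expr(b, "second matrix")
  common <- sort(intersect(rownames(a), rownames(b)))
  if (length(common) == 0L) {
    stop("no genes shared between the two matrices", call. = FALSE)
  }
  ccam_log(length(common), " genes in common")
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}

#' Z-score each gene across samples
#'
#' Rows are centred and scaled to unit standard deviation (denominator n-1).
#' Constant rows are dropped with a log message.
#'
#' @param x numeric gene-by-sample matrix with at least two samples.
#' @return matrix with row means 0 and row sds 1.
#' @export
zscore_genes <- function(x) {
  validate_expr(x)
  if (ncol(x) < 2L) stop("z-scoring needs at least 2 samples", call. = FALSE)
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  keep <- s > 0
  if (!all(keep)) {
    ccam_log(sum(!keep), " constant gene(s) dropped before z-scoring")
    if (!any(keep)) stop("all genes constant; nothing to z-score",
                         call. = FALSE)
  }
  (x[keep, , drop = FALSE] - mu[keep]) / s[keep]
}

#' Shift a matrix to nonnegative values
#'
#' The chi-square metric of correspondence analysis requires nonnegative
#' entries. `global_min` subtracts the (negative) matrix minimum from every
#' entry; `clip_zero` truncates negatives at zero.
#'
#' @param x numeric matrix.
#' @param mode `"global_min"` (default) or `"clip_zero"`.
#' @return nonnegative matrix; the applied shift is logged.
#' @export
shift_nonnegative <- function(x, mode = c("global_min", "clip_zero")) {
  mode <- match.arg(mode)
  mn <- min(x)
  if (mn >= 0) return(x)
  if (mode == "global_min") {
    ccam_log("shifted all values by ", format(-mn, digits = 6))
    x - mn
  } else {
    ccam_log(sum(x < 0), " negative value(s) clipped to 0")
    pmax(x, 0)
  }
}

#' Empirical-Bayes batch adjustment (parametric location/scale)
#'
#' Per-gene batch means and variances are shrunk towards across-gene priors
#' (normal prior for locations, inverse-gamma for scales, moment-matched),
#' then the data are recentred and rescaled to the pooled reference: the
#' standard parametric location/scale model for removing additive and
#' multiplicative batch effects. A single batch is returned unchanged.
#'
#' @param x numeric gene-by-sample matrix.
#' @param batch character/factor of batch labels, one per column of `x`.
#' @param eps variance floor guarding degenerate (zero within-batch variance)
#'   input.
#' @return adjusted matrix of the same shape and dimnames.
#' @export
batch_adjust <- function(x, batch, eps = 1e-8) {
  validate_expr(x)
  batch <- as.character(batch)
  if (length(batch) != ncol(x)) {
    stop("one batch label per sample is required", call. = FALSE)
  }
  tab <- table(batch)
  if (any(tab < 2L)) {
    stop("batch(es) with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  if (length(tab) == 1L) return(x)

  levels_b <- names(tab)
  n <- ncol(x)
  idx <- lapply(levels_b, function(b) which(batch == b))
  nb <- lengths(idx)

  # batch-wise gene means, pooled reference and pooled residual variance
  bmeans <- vapply(idx, function(i) rowMeans(x[, i, drop = FALSE]),
                   numeric(nrow(x)))
  grand <- as.vector(bmeans %*% (nb / n))
  resid <- x - bmeans[, match(batch, levels_b)]
  var_pooled <- pmax(rowMeans(resid^2), eps)

  s <- (x - grand) / sqrt(var_pooled)

  gamma_hat <- vapply(idx, function(i) rowMeans(s[, i, drop = FALSE]),
                      numeric(nrow(x)))
  delta_hat <- vapply(idx, function(i) apply(s[, i, drop = FALSE], 1L, var),
                      numeric(nrow(x)))
  delta_hat <- pmax(delta_hat, eps)

  # moment-matched hyperpriors per batch
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2L, var)
  a_prior <- apply(delta_hat, 2L, function(d) {
    m <- mean(d); v <- var(d); (2 * v + m^2) / max(v, eps)
  })
  b_prior <- apply(delta_hat, 2L, function(d) {
    m <- mean(d); v <- var(d); (m * v + m^3) / max(v, eps)
  })

  adj <- s
  for (k in seq_along(levels_b)) {
    i <- idx[[k]]
    sk <- s[, i, drop = FALSE]
    g_star <- gamma_hat[, k]
    d_star <- delta_hat[, k]
    # iterate the standard EB posterior-mean equations to convergence
    for (it in 1:100) {
      g_new <- (nb[k] * t2[k] * gamma_hat[, k] + d_star * gamma_bar[k]) /
        (nb[k] * t2[k] + d_star)
      ss <- rowSums((sk - g_new)^2)
      d_new <- (0.5 * ss + b_prior[k]) / (nb[k] / 2 + a_prior[k] - 1)
      d_new <- pmax(d_new, eps)
      if (max(abs(g_new - g_star), abs(d_new - d_star)) < 1e-8) {
        g_star <- g_new; d_star <- d_new; break
      }
      g_star <- g_new; d_star <- d_new
    }
    adj[, i] <- (sk - g_star) / sqrt(d_star)
  }
  adj * sqrt(var_pooled) + grand
}
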