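#' Moderated two-sample t-statistics (one population vs the rest)
#'
#' Ordinary equal-variance two-sample statistics are computed per gene, the
#' gene-wise variances are modelled as scaled inverse-chi-square draws around
#' a shared prior variance `s0_sq` with `d0` prior degrees of freedom, and
#' the posterior variance \eqn{\tilde{s}^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 +
#' d_g)} replaces the sample variance in the t denominator. The hyperparameters
#' are estimated by moment-matching the distribution of \eqn{\log s_g^2}
#' (digamma/trigamma inversion). P-values use a t reference with `d0 + d_g`
#' degrees of freedom and are Benjamini-Hochberg adjusted across genes.
#'
#' @param x numeric gene-by-sample matrix (log-like scale).
#' @param group character/factor group label per column of `x`.
#' @param target the group contrasted against all remaining samples.
#' @param d0 optional fixed prior degrees of freedom, overriding estimation;
#'   `0` gives ordinary t-statistics, `Inf` full shrinkage to `s0_sq`.
#' @return data.frame with one row per gene: `gene_id`, `mean_diff`, `s2_g`,
#'   `d_g`, `t_mod`, `p_raw`, `p_adj`; attributes `d0` and `s0_sq`.
#' @export
moderated_t <- function(x, group, target, d0 = NULL) {
  validate_expr(x)
  group <- as.character(group)
  if (length(group) != ncol(x)) stop("one group label per sample is required",
                                     call. = FALSE)
  in1 <- group == target
  n1 <- sum(in1); n2 <- sum(!in1)
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf("need >=2 samples per side; got %d vs %d for '%s'",
                 n1, n2, target), call. = FALSE)
  }
  x1 <- x[, in1, drop = FALSE]
  x2 <- x[, !in1, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  dg <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / dg

  if (is.null(d0)) {
    fit <- fit_scaled_invchisq(s2, dg)
    d0 <- fit$d0
    s0_sq <- fit$s0_sq
  } else {
    s0_sq <- if (is.finite(d0) && d0 == 0) mean(s2) else {
      fit_scaled_invchisq(s2, dg)$s0_sq
    }
  }

  stilde2 <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(stilde2 * (1 / n1 + 1 / n2))
  tmod <- (m1 - m2) / se
  df_total <- min(d0 + dg, 1e6)  # t(1e6) is normal to machine precision
  p <- 2 * pt(abs(tmod), df = df_total, lower.tail = FALSE)
  out <- data.frame(
    gene_id = rownames(x),
    mean_diff = m1 - m2,
    s2_g = s2,
    d_g = dg,
    t_mod = tmod,
    p_raw = p,
    p_adj = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

# Moment-match d0 and s0_sq of the scaled inverse-chi-square variance prior
# from observed sample variances s2 with d degrees of freedom each, via the
# distribution of log(s2): E[log s2] and Var[log s2] involve digamma/trigamma.
fit_scaled_invchisq <- function(s2, d) {
  ok <- s2 > 0
  if (!any(ok)) stop("all gene variances are zero", call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- mean(e)
  # excess spread of log-variances beyond the chi-square sampling noise
  excess <- mean((e - ev)^2) * length(e) / max(length(e) - 1L, 1L) -
    trigamma(d / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(ev)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x by Newton iteration on 1/trigamma (approx linear).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Select the provisional signature genes of one population
#'
#' Keeps genes over-expressed in the population (`t_mod > 0`) passing the
#' adjusted-p threshold, ranked by decreasing `t_mod` (ties broken by gene
#' identifier) and truncated to `top_k`.
#'
#' @param stats data.frame from [moderated_t()].
#' @param max_p_adj adjusted-p cutoff (default 1e-5).
#' @param top_k maximum number of genes retained (default 200; `Inf` keeps
#'   all passing genes).
#' @param mean_profile optional named per-gene means in the population,
#'   stored for later scoring.
#' @param population population label carried in the result.
#' @return object of class `ccam_signature`: list with `population`,
#'   `gene_ids`, `threshold_used`, `mean_profile`.
#' @export
select_signature <- function(stats, max_p_adj = 1e-5, top_k = 200,
                             mean_profile = NULL, population = "population") {
  keep <- stats$t_mod > 0 & stats$p_adj <= max_p_adj
  if (!any(keep)) {
    stop("no genes pass p_adj <= ", max_p_adj,
         "; consider relaxing the threshold", call. = FALSE)
  }
  sub <- stats[keep, , drop = FALSE]
  ord <- order(-sub$t_mod, sub$gene_id)
  genes <- sub$gene_id[ord]
  if (is.finite(top_k) && length(genes) > top_k) genes <- genes[seq_len(top_k)]
  prof <- if (!is.null(mean_profile)) mean_profile[genes] else NULL
  structure(list(population = population, gene_ids = genes,
                 threshold_used = max_p_adj, mean_profile = prof),
            class = "ccam_signature")
}

#' Build signatures for every population of a reference dataset
#'
#' One-vs-rest [moderated_t()] per population followed by
#' [select_signature()]; mean profiles are the per-population gene means.
#'
#' @inheritParams moderated_t
#' @inheritParams select_signature
#' @param populations which populations to build signatures for (default:
#'   all groups present). The one-vs-rest contrast always uses every sample.
#' @return named list of `ccam_signature` objects.
#' @export
build_signatures <- function(x, group, max_p_adj = 1e-5, top_k = 200,
                             populations = NULL) {
  pops <- if (is.null(populations)) unique(as.character(group)) else {
    populations
  }
  missing_p <- setdiff(pops, group)
  if (length(missing_p)) {
    stop("unknown population(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(pops, function(p) {
    st <- moderated_t(x, group, p)
    prof <- rowMeans(x[, group == p, drop = FALSE])
    select_signature(st, max_p_adj = max_p_adj, top_k = top_k,
                     mean_profile = prof, population = p)
  })
  names(out) <- pops
  out
}

#' Score samples against a gene signature
#'
#' Each sample's expression over the signature genes is correlated (Pearson)
#' with the signature's mean profile; the per-sample correlations are then
#' scaled to mean zero and unit standard deviation across samples, because
#' the interest lies in comparing samples with each other.
#'
#' @param x numeric gene-by-sample matrix containing the signature genes.
#' @param sig a `ccam_signature` with a `mean_profile`.
#' @param scale z-scale the scores across samples (default TRUE).
#' @return named numeric vector of per-sample scores; samples whose
#'   signature-gene vector has zero variance get `NA` (reported via message).
#' @export
signature_score <- function(x, sig, scale = TRUE) {
  genes <- intersect(sig$gene_ids, rownames(x))
  if (length(genes) < 3L) {
    stop("fewer than 3 signature genes present in the matrix", call. = FALSE)
  }
  prof <- sig$mean_profile[genes]
  sub <- x[genes, , drop = FALSE]
  sds <- apply(sub, 2L, sd)
  r <- rep(NA_real_, ncol(sub))
  names(r) <- colnames(sub)
  ok <- sds > 0
  if (!all(ok)) {
    ccam_log(sum(!ok), " sample(s) with zero variance over signature genes; ",
             "score undefined")
  }
  if (any(ok)) r[ok] <- as.vector(cor(sub[, ok, drop = FALSE], prof))
  if (scale) {
    mu <- mean(r, na.rm = TRUE)
    s <- sd(r[!is.na(r)])
    if (!is.finite(s) || s == 0) stop("signature scores are constant",
                                      call. = FALSE)
    r <- (r - mu) / s
  }
  r
}

#' Score matrix over all signatures
#'
#' @param x gene-by-sample matrix to score.
#' @param sigs named list of signatures from [build_signatures()].
#' @return populations-by-samples matrix of z-scaled scores.
#' @export
signature_score_matrix <- function(x, sigs) {
  m <- t(vapply(sigs, function(s) signature_score(x, s),
                numeric(ncol(x))))
  rownames(m) <- names(sigs)
  m
}

#' Cluster signatures by their score profiles
#'
#' Hierarchical clustering with distance 1 - Pearson correlation between the
#' population rows of a signature score matrix, average linkage.
#'
#' @param scores populations-by-samples score matrix.
#' @param h optional height at which flat clusters are cut.
#' @return list with `hclust` (the dendrogram) and `clusters` (flat labels,
#'   or NULL when `h` not given).
#' @export
cluster_signatures <- function(scores, h = NULL) {
  if (nrow(scores) < 2L) stop("need at least 2 populations", call. = FALSE)
  d <- as.dist(1 - cor(t(scores)))
  hc <- hclust(d, method = "average")
  cl <- if (!is.null(h)) cutree(hc, h = h) else NULL
  list(hclust = hc, clusters = cl)
}
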