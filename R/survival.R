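#' Construct a survival table
#'
#' @param sample_id identifiers.
#' @param time nonnegative follow-up times (one unit throughout).
#' @param event 0/1 event indicator (1 = event observed).
#' @param stratum optional ordinal stratum labels.
#' @param covariates optional data.frame of numeric/ordinal covariates.
#' @return data.frame of class `ccam_survtab`.
#' @export
survival_table <- function(sample_id, time, event, stratum = NULL,
                           covariates = NULL) {
  if (any(time < 0)) stop("times must be nonnegative", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  out <- data.frame(sample_id = sample_id, time = as.numeric(time),
                    event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(stratum)) out$stratum <- stratum
  if (!is.null(covariates)) out <- cbind(out, covariates)
  class(out) <- c("ccam_survtab", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @return data.frame with distinct event times (`time`), numbers at risk
#'   (`n_risk`), events (`n_event`) and the survival probability
#'   (`survival`). All-censored input yields zero rows (survival 1
#'   throughout).
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least one subject", call. = FALSE)
  ev_times <- sort(unique(time[event == 1]))
  surv <- 1
  out <- data.frame(time = ev_times,
                    n_risk = rep(NA_real_, length(ev_times)),
                    n_event = rep(NA_real_, length(ev_times)),
                    survival = rep(NA_real_, length(ev_times)))
  for (i in seq_along(ev_times)) {
    tt <- ev_times[i]
    n_risk <- sum(time >= tt)
    n_event <- sum(time == tt & event == 1)
    surv <- surv * (1 - n_event / n_risk)
    out$n_risk[i] <- n_risk
    out$n_event[i] <- n_event
    out$survival[i] <- surv
  }
  out
}

#' K-sample log-rank test
#'
#' Hypergeometric-variance formulation: at every distinct event time the
#' observed events per group are compared with their expectation under the
#' null of identical hazards, and the chi-square statistic
#' \eqn{(O-E)^T V^{-} (O-E)} over the first k-1 groups is referred to a
#' chi-square distribution with k-1 degrees of freedom.
#'
#' @param time,event follow-up data.
#' @param group stratum labels (>= 2 levels; at least one event overall).
#' @return list with `statistic`, `df`, `p_value`, `observed`, `expected`,
#'   `method`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  levs <- sort(unique(group))
  k <- length(levs)
  if (k < 2L) stop("need at least 2 strata", call. = FALSE)
  if (sum(event) < 1L) stop("need at least one event", call. = FALSE)

  gi <- match(group, levs)
  ev_times <- sort(unique(time[event == 1]))
  O <- numeric(k)
  E <- numeric(k)
  V <- matrix(0, k, k)
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    nj <- tabulate(gi[at_risk], nbins = k)
    d <- sum(time == tt & event == 1)
    dj <- tabulate(gi[time == tt & event == 1], nbins = k)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      # hypergeometric covariance of the per-group event counts
      frac <- nj / n
      Vt <- d * (n - d) / (n - 1) * (diag(frac, k) - tcrossprod(frac))
      V <- V + Vt
    }
  }
  idx <- seq_len(k - 1L)
  ome <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  Vinv <- tryCatch(solve(Vi), error = function(e) NULL)
  stat <- if (is.null(Vinv)) {
    qr_v <- qr(Vi)
    as.numeric(t(ome) %*% qr.coef(qr_v, ome))
  } else {
    as.numeric(t(ome) %*% Vinv %*% ome)
  }
  if (!is.finite(stat)) stat <- 0
  names(O) <- names(E) <- levs
  list(statistic = stat, df = k - 1L,
       p_value = pchisq(stat, df = k - 1L, lower.tail = FALSE),
       observed = O, expected = E, method = "log-rank")
}

#' Cox proportional hazards regression
#'
#' Thin contract over the partial-likelihood fitter of the survival package
#' (Efron tie handling). Reports hazard ratios, 95% confidence intervals and
#' Wald p-values per covariate; set `univariate = TRUE` to fit each
#' covariate separately.
#'
#' @param tab data.frame with `time`, `event` and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param univariate fit one model per covariate instead of a joint model.
#' @return data.frame with `covariate`, `coef`, `hazard_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`, `model`.
#' @export
cox_ph <- function(tab, covariates, univariate = FALSE) {
  for (cv in covariates) {
    v <- tab[[cv]]
    if (is.null(v)) stop("covariate not found: ", cv, call. = FALSE)
    if (length(unique(v)) < 2L) stop("covariate is constant: ", cv,
                                     call. = FALSE)
  }
  if (sum(tab$event) < length(covariates)) {
    stop("fewer events than covariates", call. = FALSE)
  }
  fit_one <- function(cvs, label) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(sprintf("`%s`", cvs), collapse = " + ")))
    fit <- survival::coxph(fml, data = tab, ties = "efron")
    if (any(!is.finite(fit$coefficients)) ||
        any(abs(fit$coefficients) > 20)) {
      stop("Cox model did not converge (possible separation) for ",
           label, call. = FALSE)
    }
    s <- summary(fit)
    data.frame(covariate = rownames(s$coefficients),
               coef = s$coefficients[, "coef"],
               hazard_ratio = s$coefficients[, "exp(coef)"],
               ci_lower = s$conf.int[, "lower .95"],
               ci_upper = s$conf.int[, "upper .95"],
               p_value = s$coefficients[, "Pr(>|z|)"],
               model = label, stringsAsFactors = FALSE, row.names = NULL)
  }
  if (univariate) {
    do.call(rbind, lapply(covariates, function(cv)
      fit_one(cv, paste0("univariate:", cv))))
  } else {
    fit_one(covariates, "multivariate")
  }
}

#' Rank-based group comparison
#'
#' Kruskal-Wallis for multiple groups, Mann-Whitney (Wilcoxon rank-sum) for
#' two, both with tie correction; optional Bonferroni adjustment multiplies
#' the p-value by the number of pairwise comparisons.
#'
#' @param scores numeric vector.
#' @param groups group label per score (>= 2 non-empty groups).
#' @param method `"kruskal_wallis"` or `"mann_whitney"`.
#' @param bonferroni apply the Bonferroni correction.
#' @return list with `statistic`, `df` (NA for Mann-Whitney), `p_raw`,
#'   `p_adjusted`, `method`.
#' @export
group_compare <- function(scores, groups,
                          method = c("kruskal_wallis", "mann_whitney"),
                          bonferroni = FALSE) {
  method <- match.arg(method)
  groups <- as.factor(as.character(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_pairs <- choose(k, 2L)
  if (method == "kruskal_wallis") {
    ht <- kruskal.test(scores, groups)
    stat <- unname(ht$statistic); df <- unname(ht$parameter)
  } else {
    if (k != 2L) stop("mann_whitney requires exactly 2 groups",
                      call. = FALSE)
    ht <- wilcox.test(scores[groups == levels(groups)[1L]],
                      scores[groups == levels(groups)[2L]],
                      exact = NULL, correct = TRUE)
    stat <- unname(ht$statistic); df <- NA_real_
  }
  p <- ht$p.value
  list(statistic = stat, df = df, p_raw = p,
       p_adjusted = if (bonferroni) min(1, p * n_pairs) else p,
       method = method)
}
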