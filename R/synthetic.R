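#' Configuration for the synthetic data generator
#'
#' The generator emulates a sorted-reference / disease-cohort design: the
#' reference dataset has population-specific marker blocks; disease samples
#' are noisy Dirichlet mixtures of the population mean profiles (the
#' maturation-arrest premise: each patient's transcriptome is a combination
#' of normal-counterpart programs); survival times follow a proportional-
#' hazards law in the mixture weight of a designated ("stem-like") target
#' population.
#'
#' @param n_genes number of genes (default 1000).
#' @param n_populations number of populations used in the disease mixtures
#'   and as explanatory variables (default 5, named after the
#'   haematopoietic populations HSC, MEP, CMP, GMP, ProB).
#' @param n_extra_populations additional reference-only populations
#'   (default 2, named NM and MatB). Real sorted references carry many more
#'   populations than the few chosen as explanatory variables; without the
#'   extra ones the per-gene z-scoring of the reference makes the chosen
#'   population means exactly collinear.
#' @param n_replicates reference samples per population (default 6).
#' @param markers_per_population size of each population's marker block
#'   (default 100, the typical scale of a population signature and the size
#'   of the axis-score gene lists).
#' @param marker_effect mean shift of a marker in its population, in sd
#'   units (default 3).
#' @param noise_sd residual noise sd (default 0.5).
#' @param n_disease_samples disease cohort size (default 200).
#' @param mixture_concentration Dirichlet concentration of the mixture
#'   weights; a scalar gives a symmetric Dirichlet, a vector (recycled to
#'   `n_populations`) an asymmetric one. The default `NULL` expands to
#'   `c(1, 0.3, 0.3, ...)`: the cohort varies chiefly along the degree of
#'   maturation arrest towards the target population (the severity
#'   continuum that dominates the first ordination axis), with sparse
#'   involvement of the other programs.
#' @param batch_shift_sd sd of per-gene additive batch shifts in the disease
#'   cohort; 0 (default) disables batches.
#' @param n_batches number of disease batches when `batch_shift_sd > 0`.
#' @param hazard_coefficient log hazard ratio per unit mixture weight of the
#'   target population (default 1.5).
#' @param target_population index of the population driving hazard
#'   (default 1, i.e. HSC).
#' @param baseline_hazard event rate at weight zero (default 0.1 per time
#'   unit).
#' @param censoring_rate desired fraction of censored subjects (default
#'   0.3).
#' @param seed integer seed (mandatory).
#' @return list of class `ccam_config`.
#' @export
synthetic_config <- function(n_genes = 1000, n_populations = 5,
                             n_extra_populations = 2,
                             n_replicates = 6, markers_per_population = 100,
                             marker_effect = 3, noise_sd = 0.5,
                             n_disease_samples = 200,
                             mixture_concentration = NULL,
                             batch_shift_sd = 0, n_batches = 2,
                             hazard_coefficient = 1.5,
                             target_population = 1,
                             baseline_hazard = 0.1,
                             censoring_rate = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n_total <- n_populations + n_extra_populations
  if (markers_per_population * n_total > n_genes) {
    stop("marker blocks exceed the number of genes", call. = FALSE)
  }
  if (is.null(mixture_concentration)) {
    mixture_concentration <- c(1, rep(0.3, n_populations - 1L))
    if (target_population != 1L) {
      mixture_concentration <- rep(0.3, n_populations)
      mixture_concentration[target_population] <- 1
    }
  }
  mixture_concentration <- rep_len(mixture_concentration, n_populations)
  stopifnot(n_genes > 0, n_populations > 0, n_extra_populations >= 0,
            n_replicates > 1, noise_sd >= 0, n_disease_samples > 0,
            all(mixture_concentration > 0), censoring_rate >= 0,
            censoring_rate < 1)
  pops <- c("HSC", "MEP", "CMP", "GMP", "ProB")
  pop_names <- if (n_populations <= 5L) pops[seq_len(n_populations)] else {
    c(pops, paste0("Pop", seq_len(n_populations - 5L)))
  }
  extra <- c("NM", "MatB")
  extra_names <- if (n_extra_populations == 0L) character(0) else {
    if (n_extra_populations <= 2L) extra[seq_len(n_extra_populations)] else {
      c(extra, paste0("Extra", seq_len(n_extra_populations - 2L)))
    }
  }
  structure(list(
    n_genes = n_genes, n_populations = n_populations,
    n_extra_populations = n_extra_populations,
    n_replicates = n_replicates,
    markers_per_population = markers_per_population,
    marker_effect = marker_effect, noise_sd = noise_sd,
    n_disease_samples = n_disease_samples,
    mixture_concentration = mixture_concentration,
    batch_shift_sd = batch_shift_sd, n_batches = n_batches,
    hazard_coefficient = hazard_coefficient,
    target_population = target_population,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate, seed = as.integer(seed),
    population_names = pop_names,
    all_population_names = c(pop_names, extra_names)
  ), class = "ccam_config")
}

# run code with a deterministic, isolated RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# mean profiles (baseline + marker blocks) for every reference population,
# mixture populations first, reference-only extras after
population_profiles <- function(cfg) {
  with_seed(cfg$seed, {
    baseline <- rnorm(cfg$n_genes, 0, 1)
    n_total <- length(cfg$all_population_names)
    marker_of <- rep(NA_integer_, cfg$n_genes)
    m <- cfg$markers_per_population
    profiles <- matrix(baseline, cfg$n_genes, n_total)
    for (j in seq_len(n_total)) {
      block <- ((j - 1L) * m + 1L):(j * m)
      marker_of[block] <- j
      profiles[block, j] <- profiles[block, j] + cfg$marker_effect
    }
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    dimnames(profiles) <- list(genes, cfg$all_population_names)
    list(profiles = profiles, marker_of = setNames(marker_of, genes))
  })
}

#' Generate the synthetic reference dataset
#'
#' Per population, `n_replicates` samples equal to the population mean
#' profile plus independent Gaussian noise.
#'
#' @param cfg a `ccam_config`.
#' @return list with `expr` (gene-by-sample matrix), `annotation`
#'   (data.frame: sample_id, group) and `truth` (marker assignment and
#'   population profiles).
#' @export
make_reference <- function(cfg) {
  pp <- population_profiles(cfg)
  n_total <- length(cfg$all_population_names)
  n <- n_total * cfg$n_replicates
  with_seed(cfg$seed + 1L, {
    group <- rep(cfg$all_population_names, each = cfg$n_replicates)
    expr <- pp$profiles[, rep(seq_len(n_total),
                              each = cfg$n_replicates)] +
      matrix(rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n)
    colnames(expr) <- sprintf("ref%03d", seq_len(n))
    ann <- data.frame(sample_id = colnames(expr), group = group,
                      stringsAsFactors = FALSE)
    list(expr = expr, annotation = ann,
         truth = list(marker_of = pp$marker_of, profiles = pp$profiles))
  })
}

#' Generate the synthetic disease cohort
#'
#' Each disease sample is a Dirichlet-weighted mixture of the population
#' mean profiles plus Gaussian noise, optionally with an additive per-gene
#' batch shift.
#'
#' @param cfg a `ccam_config`.
#' @return list with `expr`, `annotation` (sample_id, group = dominant
#'   population, batch) and `truth` (`weights`: samples x populations,
#'   `dominant`, `batch`).
#' @export
make_disease <- function(cfg) {
  pp <- population_profiles(cfg)
  n <- cfg$n_disease_samples
  with_seed(cfg$seed + 2L, {
    a <- rep_len(cfg$mixture_concentration, cfg$n_populations)
    g <- matrix(rgamma(n * cfg$n_populations, shape = rep(a, each = n),
                       rate = 1),
                n, cfg$n_populations)
    w <- g / rowSums(g)
    colnames(w) <- cfg$population_names
    mix_profiles <- pp$profiles[, cfg$population_names, drop = FALSE]
    expr <- mix_profiles %*% t(w) +
      matrix(rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n)
    batch <- rep("b1", n)
    if (cfg$batch_shift_sd > 0 && cfg$n_batches > 1L) {
      batch <- paste0("b", rep_len(seq_len(cfg$n_batches), n))
      shifts <- matrix(rnorm(cfg$n_genes * cfg$n_batches, 0,
                             cfg$batch_shift_sd),
                       cfg$n_genes, cfg$n_batches)
      expr <- expr + shifts[, as.integer(sub("^b", "", batch))]
    }
    colnames(expr) <- sprintf("pt%03d", seq_len(n))
    rownames(w) <- colnames(expr)
    dominant <- cfg$population_names[max.col(w, ties.method = "first")]
    ann <- data.frame(sample_id = colnames(expr), group = dominant,
                      batch = batch, stringsAsFactors = FALSE)
    list(expr = expr, annotation = ann,
         truth = list(weights = w, dominant = dominant, batch = batch,
                      profiles = pp$profiles, marker_of = pp$marker_of))
  })
}

#' Generate survival outcomes tied to the mixture ground truth
#'
#' Event times are exponential with hazard `baseline_hazard *
#' exp(hazard_coefficient * w_target)`; censoring is independent
#' exponential with its rate tuned (by root finding on the expected
#' censored fraction) to the requested `censoring_rate`.
#'
#' @param cfg a `ccam_config`.
#' @param disease_truth the `truth` element of [make_disease()].
#' @return a `ccam_survtab` with `sample_id`, `time`, `event` and the true
#'   target weight as covariate `w_target`.
#' @export
make_survival <- function(cfg, disease_truth) {
  w <- disease_truth$weights[, cfg$target_population]
  h <- cfg$baseline_hazard * exp(cfg$hazard_coefficient * w)
  with_seed(cfg$seed + 3L, {
    t_event <- rexp(length(h), rate = h)
    if (cfg$censoring_rate <= 0) {
      time <- t_event
      event <- rep(1L, length(h))
    } else {
      # P(censored) for exponential censoring at rate hc: mean(hc/(hc+h))
      f <- function(hc) mean(hc / (hc + h)) - cfg$censoring_rate
      hc <- uniroot(f, lower = 1e-10, upper = 1e6)$root
      t_cens <- rexp(length(h), rate = hc)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    survival_table(names(w), time, event,
                   covariates = data.frame(w_target = unname(w)))
  })
}
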