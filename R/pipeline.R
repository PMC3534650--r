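#' Full constrained-ordination pipeline on paired datasets
#'
#' The canonical analysis sequence: align the two matrices on shared genes;
#' z-score the reference and filter genes by its one-vs-rest moderated-t
#' signatures (an unsupervised choice with respect to the disease data);
#' average the z-scored reference per population into the environment
#' matrix; z-score the disease matrix and shift it nonnegative; fit the
#' constrained ordination; derive the axis score model and stratify the
#' cohort.
#'
#' @param disease gene-by-sample disease matrix (normalized, log-like).
#' @param ref gene-by-sample reference matrix (normalized, log-like).
#' @param ref_group population label per reference sample.
#' @param populations populations used as explanatory variables (default:
#'   all).
#' @param max_p_adj,top_k signature thresholds (see [select_signature()]).
#' @param axis axis for the prognostic score (default 1).
#' @param n_top,n_bottom axis-score list sizes (default 100).
#' @param cuts stratification percentiles (default 50).
#' @param scaling triplot scaling (default 2).
#' @param shift_mode nonnegativity mode for the disease matrix (see
#'   [shift_nonnegative()]).
#' @return list with `fit` (the `ccam` object), `signatures`, `genes_used`,
#'   `env`, `axis_model`, `scores`, `strata`.
#' @export
ccam_pipeline <- function(disease, ref, ref_group, populations = NULL,
                          max_p_adj = 1e-5, top_k = 200, axis = 1,
                          n_top = 100, n_bottom = 100, cuts = 50,
                          scaling = 2, shift_mode = "global_min") {
  al <- align_genes(disease, ref)
  refz <- zscore_genes(al$b)
  grp <- ref_group[match(colnames(refz), colnames(ref))]

  # gene filter uses only the populations chosen as explanatory variables
  sigs <- build_signatures(refz, grp, max_p_adj = max_p_adj, top_k = top_k,
                           populations = populations)
  genes_used <- sort(unique(unlist(lapply(sigs, `[[`, "gene_ids"))))
  genes_used <- intersect(rownames(al$a), genes_used)
  if (length(genes_used) < 10L) {
    stop("fewer than 10 genes survive the signature filter", call. = FALSE)
  }

  env <- build_environment(refz[genes_used, , drop = FALSE], grp,
                           populations = populations)
  dz <- zscore_genes(al$a[genes_used, , drop = FALSE])
  env <- env[rownames(dz), , drop = FALSE]
  dnn <- shift_nonnegative(dz, mode = shift_mode)

  fit <- cca_fit(dnn, env, scaling = scaling)
  model <- build_axis_score(fit, axis = axis, n_top = n_top,
                            n_bottom = n_bottom)
  scores <- score_samples(model, al$a)
  strata <- stratify(scores, cuts = cuts)
  list(fit = fit, signatures = sigs, genes_used = rownames(dz), env = env,
       axis_model = model, scores = scores, strata = strata)
}
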