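#' Write a numeric table as TSV with fixed formatting
#'
#' All floats are written with 6 significant digits by default so that
#' repeated runs with identical inputs produce byte-identical files.
#'
#' @param x matrix or data.frame.
#' @param path output file.
#' @param digits significant digits (default 6).
#' @param row_label header for the row-name column when `x` has row names.
#' @export
write_tsv_table <- function(x, path, digits = 6, row_label = "id") {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                 format = "g"))
  if (!is.null(rownames(x)) &&
      !identical(rownames(x), as.character(seq_len(nrow(x))))) {
    df <- cbind(setNames(data.frame(rownames(x),
                                    stringsAsFactors = FALSE), row_label),
                df)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV (genes in rows)
#' @param x gene-by-sample matrix.
#' @param path output file.
#' @param digits significant digits.
#' @export
write_expression <- function(x, path, digits = 6) {
  write_tsv_table(x, path, digits = digits, row_label = "gene_id")
}

#' Export all score tables and the inertia report of a fit
#'
#' Writes `gene_scores_wa.tsv`, `gene_scores_lc.tsv`, `sample_scores.tsv`,
#' `env_arrows.tsv` and `inertia.yaml` into a directory.
#'
#' @param res a fitted `ccam` object.
#' @param dir output directory (created if absent).
#' @export
export_cca <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(res$gene_scores_wa, file.path(dir, "gene_scores_wa.tsv"),
                  row_label = "gene_id")
  write_tsv_table(res$gene_scores_lc, file.path(dir, "gene_scores_lc.tsv"),
                  row_label = "gene_id")
  write_tsv_table(res$sample_scores, file.path(dir, "sample_scores.tsv"),
                  row_label = "sample_id")
  write_tsv_table(res$env_biplot, file.path(dir, "env_arrows.tsv"),
                  row_label = "population")
  dec <- decompose_inertia(res)
  dec$axis_eigenvalues <- as.numeric(format(dec$axis_eigenvalues,
                                            digits = 10))
  dec$axis_fractions <- as.numeric(format(dec$axis_fractions, digits = 10))
  yaml::write_yaml(dec, file.path(dir, "inertia.yaml"),
                   precision = 10)
  invisible(dir)
}
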