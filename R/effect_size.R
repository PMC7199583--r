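# Per-study effect sizes: the log2 fold-change (case mean - control mean on
# the log2 scale) with a Welch-style unpooled standard error,
# se = sqrt(s2_case/n_case + s2_control/n_control). The unpooled form is
# robust to unequal group variances and to extreme group imbalance
# (arms in public cohorts range from 4 to 443 samples).

.row_var <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

#' Compute log2 fold-change effect sizes for all genes of one study
#'
#' @param study An [expression_study()].
#' @param genes Optional character vector restricting to these genes (all
#'   must be present).
#' @return A `data.frame` with one row per gene: `gene`, `study_id`, `lfc`,
#'   `se`, `n_case`, `n_control`, `zero_variance` (logical flag, also set
#'   for singleton groups whose variance is taken as 0).
#' @export
compute_effects <- function(study, genes = NULL) {
  m <- study$matrix
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss))
      stop("gene(s) not found in study '", study$study_id, "': ",
           paste(miss, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  ctrl <- m[, study$sample_groups == "control", drop = FALSE]
  case <- m[, study$sample_groups == "case", drop = FALSE]
  if (ncol(ctrl) < 2L || ncol(case) < 2L)
    message("compute_effects: singleton group in study '", study$study_id,
            "'; its sample variance is taken as 0")
  lfc <- rowMeans(case) - rowMeans(ctrl)
  se <- sqrt(.row_var(case) / ncol(case) + .row_var(ctrl) / ncol(ctrl))
  data.frame(gene = rownames(m), study_id = study$study_id,
             lfc = unname(lfc), se = unname(se),
             n_case = ncol(case), n_control = ncol(ctrl),
             zero_variance = unname(se == 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compute the effect size of a single gene in one study
#'
#' @inheritParams compute_effects
#' @param gene Gene identifier; must be present in the study.
#' @return One-row `data.frame` as in [compute_effects()].
#' @export
compute_effect <- function(study, gene) {
  stopifnot(length(gene) == 1L)
  compute_effects(study, genes = gene)
}

#' Collect a gene's effect estimates across studies
#'
#' Studies lacking the gene are skipped with a message (array platforms
#' differ in gene coverage); a gene found in no study yields an empty
#' result with a warning.
#'
#' @param studies List of [expression_study()] objects.
#' @param gene Gene identifier.
#' @return `data.frame` with one row per study containing the gene.
#' @export
effects_for_gene <- function(studies, gene) {
  have <- vapply(studies, function(s) gene %in% rownames(s$matrix), logical(1L))
  if (!any(have)) {
    warning("gene '", gene, "' found in none of the ", length(studies),
            " studies")
    return(data.frame(gene = character(0), study_id = character(0),
                      lfc = numeric(0), se = numeric(0),
                      n_case = integer(0), n_control = integer(0),
                      zero_variance = logical(0)))
  }
  if (any(!have))
    message("effects_for_gene: gene '", gene, "' absent from ",
            sum(!have), " of ", length(studies), " studies; skipped")
  do.call(rbind, lapply(studies[have], compute_effect, gene = gene))
}
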