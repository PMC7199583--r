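# Study-level covariate regression: does a gene's per-study effect size
# depend on sample size, country of origin, or study age? Ordinary least
# squares of lfc on those three covariates, with per-factor p-values
# (partial F-tests, which for 1-df numeric terms coincide with the usual
# two-sided t-tests).

#' Regress a gene's per-study effect sizes on study covariates
#'
#' Fits `lfc ~ sample_size + study_age + country` by OLS across studies.
#' Sample size is total (case + control) by default; country enters as a
#' one-hot factor with the most frequent country as reference (ties broken
#' alphabetically), and is dropped with a warning when fewer than two
#' countries are present. Each factor's p-value is the partial F-test from
#' dropping that term.
#'
#' @param effects Per-study estimates for one gene (`data.frame` with
#'   `gene`, `study_id`, `lfc`, `se`).
#' @param metadata Study metadata `data.frame` with columns `study_id`,
#'   `n_control`, `n_case`, `country`, `study_age`.
#' @param sample_size `"total"` (default) or `"case"`: which count enters
#'   as the sample-size covariate.
#' @param weighted If `TRUE`, weight studies by `1/se^2` (inverse-variance
#'   weighted least squares); default unweighted.
#' @return An object of class `mlr_report`: list with `gene`, `k`,
#'   `factor_p` (named p-values per factor), `coefficients`, `r2`, and the
#'   underlying `lm` fit.
#' @export
fit_mlr <- function(effects, metadata,
                    sample_size = c("total", "case"), weighted = FALSE) {
  sample_size <- match.arg(sample_size)
  need <- c("study_id", "n_control", "n_case", "country", "study_age")
  stopifnot(all(need %in% names(metadata)))
  keep <- intersect(c("study_id", "gene", "lfc", "se"), names(effects))
  d <- merge(effects[, keep, drop = FALSE], metadata[, need], by = "study_id")
  d$size <- if (sample_size == "total") d$n_case + d$n_control else d$n_case
  k <- nrow(d)
  countries <- unique(d$country)
  use_country <- length(countries) >= 2L
  if (!use_country)
    warning("fit_mlr: single country '", countries,
            "'; country term dropped")
  if (use_country) {
    tab <- sort(table(d$country), decreasing = TRUE)
    ref <- sort(names(tab)[tab == max(tab)])[1L]
    d$country <- stats::relevel(factor(d$country), ref = ref)
  }
  n_terms <- 3L + if (use_country) nlevels(d$country) - 1L else 0L
  if (k < n_terms + 1L)
    stop("fit_mlr: ", k, " studies but at least ", n_terms + 1L,
         " required for ", n_terms, " model terms")
  form <- if (use_country) lfc ~ size + study_age + country
          else lfc ~ size + study_age
  w <- if (weighted) 1 / d$se^2 else NULL
  fit <- stats::lm(form, data = d, weights = w)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    warning("fit_mlr: rank-deficient design; aliased term(s) dropped: ",
            paste(aliased, collapse = ", "))
  }
  dr <- stats::drop1(fit, test = "F")
  p <- dr[["Pr(>F)"]][-1L]
  names(p) <- rownames(dr)[-1L]
  # an exact fit leaves zero residual SS and an undefined F ratio; the
  # corresponding tail probability is 0 at machine level
  rss <- sum(stats::residuals(fit)^2)
  p[is.na(p) & rss < 1e-25] <- 0
  names(p)[names(p) == "size"] <- "sample_size"
  structure(list(gene = effects$gene[1L], k = k, factor_p = p,
                 coefficients = stats::coef(fit),
                 r2 = summary(fit)$r.squared, fit = fit),
            class = "mlr_report")
}

#' @export
print.mlr_report <- function(x, ...) {
  cat(sprintf("Covariate regression for '%s' (%d studies, R^2 = %.3f)\n",
              x$gene, x$k, x$r2))
  for (f in names(x$factor_p))
    cat(sprintf("  %-12s p = %.4g\n", f, x$factor_p[[f]]))
  invisible(x)
}

#' Covariate regression across many genes, as a flat table
#'
#' @param studies List of [expression_study()] objects.
#' @param genes Genes to analyze.
#' @param metadata Study metadata (see [fit_mlr()]); defaults to the
#'   metadata carried on the studies themselves.
#' @param ... Passed to [fit_mlr()].
#' @return `data.frame` with one row per gene x factor: `gene`, `factor`,
#'   `coefficient` (NA for the multi-level country factor, whose single
#'   partial-F p summarizes all dummies), `p_value`, `k`, `r2`.
#' @export
mlr_table <- function(studies, genes, metadata = NULL, ...) {
  if (is.null(metadata)) metadata <- studies_metadata(studies)
  rows <- lapply(sort(unique(genes)), function(g) {
    eff <- suppressMessages(effects_for_gene(studies, g))
    if (nrow(eff) == 0L) return(NULL)
    rep_ <- suppressWarnings(fit_mlr(eff, metadata, ...))
    cf <- rep_$coefficients
    co <- c(sample_size = unname(cf["size"]), study_age = unname(cf["study_age"]),
            country = NA_real_)
    data.frame(gene = g, factor = names(rep_$factor_p),
               coefficient = unname(co[names(rep_$factor_p)]),
               p_value = unname(rep_$factor_p), k = rep_$k, r2 = rep_$r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), factor = character(0),
                      coefficient = numeric(0), p_value = numeric(0),
                      k = integer(0), r2 = numeric(0))
  rownames(out) <- NULL
  out
}

#' Extract the study-level metadata table from a list of studies
#' @param studies List of [expression_study()] objects.
#' @return `data.frame` with `study_id`, `n_control`, `n_case`, `country`,
#'   `study_age`.
#' @export
studies_metadata <- function(studies) {
  do.call(rbind, lapply(studies, function(s)
    data.frame(study_id = s$study_id, n_control = s$n_control,
               n_case = s$n_case, country = s$country,
               study_age = s$study_age, stringsAsFactors = FALSE)))
}
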