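# Mega-analysis: inverse-variance pooling of per-study log2 fold-changes.
#
# "Mega-analysis" (as opposed to meta-analysis) signals that effect sizes
# are computed from the original expression matrices, not lifted from
# publications. Heterogeneity across studies is quantified by Cochran's Q
# (the total variance), its expectation under homogeneity df = k - 1, the
# heterogeneity percentage ISq = 100 * (Q - df)/Q clamped to 0 when
# Q <= df, and Qp, the upper-tail chi-square probability of Q at df degrees
# of freedom. The model-selection rule is ISq-based: ISq = 0 -> fixed
# effects; ISq > 0 -> DerSimonian-Laird random effects.

# Degenerate (zero) standard errors would give a study infinite weight.
# They are replaced by one tenth of the smallest positive se among the
# gene's studies; a gene with no positive se at all falls back to equal
# weights.
.prepare_se <- function(effects, quiet = FALSE) {
  se <- effects$se
  zero <- se <= 0
  if (any(zero) && any(!zero)) {
    sub <- min(se[!zero]) / 10
    if (!quiet)
      message("mega-analysis: ", sum(zero), " zero-variance estimate(s) for ",
              "gene '", effects$gene[1L], "' given se = ", signif(sub, 4L))
    se[zero] <- sub
  }
  se
}

.two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  max(p, .Machine$double.xmin)  # p-values live in (0, 1]
}

.meta_result <- function(gene, k, pooled_lfc, pooled_se, p_value, model, tau2,
                         het = NULL) {
  structure(list(gene = gene, k = k, pooled_lfc = pooled_lfc,
                 pooled_se = pooled_se, p_value = p_value, model = model,
                 tau2 = tau2, het = het),
            class = "meta_result")
}

.pool <- function(lfc, w) {
  pooled <- sum(w * lfc) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(pooled = pooled, se = se, p = .two_sided_p(pooled / se))
}

#' Fixed-effects pooling of per-study effect sizes
#'
#' Inverse-variance weights `w_i = 1/se_i^2`; pooled estimate
#' `sum(w_i * lfc_i) / sum(w_i)` with standard error `1/sqrt(sum(w_i))`
#' and a two-sided normal (z) p-value.
#'
#' @param effects `data.frame` of per-study estimates for ONE gene, with
#'   columns `gene`, `lfc`, `se` (see [compute_effects()]).
#' @return A `meta_result` object with `model = "fixed"`, `tau2 = 0`.
#' @seealso [meta_analyze()] for the heterogeneity-driven model choice.
#' @export
fixed_effects <- function(effects) {
  if (nrow(effects) < 1L) stop("fixed_effects: no effect estimates supplied")
  se <- .prepare_se(effects)
  if (all(se <= 0)) {
    pooled <- mean(effects$lfc)
    return(.meta_result(effects$gene[1L], nrow(effects), pooled, 0,
                        if (pooled == 0) 1 else .Machine$double.xmin,
                        "fixed", 0))
  }
  fit <- .pool(effects$lfc, 1 / se^2)
  .meta_result(effects$gene[1L], nrow(effects), fit$pooled, fit$se, fit$p,
               "fixed", 0)
}

#' Cochran's Q heterogeneity diagnostics
#'
#' `Q = sum(w_i * (lfc_i - pooled_fixed)^2)` with fixed-effects weights;
#' `df = k - 1`; `ISq = 100 * (Q - df)/Q`, clamped to 0 whenever
#' `Q <= df`; `Qp` is the upper-tail probability of a chi-square with `df`
#' degrees of freedom at `Q` — the probability that the total variance is
#' due to within-study variance alone.
#'
#' @inheritParams fixed_effects
#' @return A list of class `heterogeneity` with elements `Q`, `df`, `ISq`,
#'   `Qp`.
#' @export
heterogeneity <- function(effects) {
  k <- nrow(effects)
  if (k < 2L)
    stop("heterogeneity requires at least 2 studies (got ", k, ")")
  se <- .prepare_se(effects, quiet = TRUE)
  if (all(se <= 0)) se <- rep(1, k)  # equal weights; Q then measures raw spread
  w <- 1 / se^2
  pooled <- sum(w * effects$lfc) / sum(w)
  Q <- sum(w * (effects$lfc - pooled)^2)
  df <- k - 1
  ISq <- if (Q <= df) 0 else 100 * (Q - df) / Q
  structure(list(Q = Q, df = df, ISq = ISq,
                 Qp = stats::pchisq(Q, df, lower.tail = FALSE)),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("Heterogeneity: Q = %.4g on df = %d (Qp = %.4g), ISq = %.2f%%\n",
              x$Q, x$df, x$Qp, x$ISq))
  invisible(x)
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' The between-study variance component is the moment estimator
#' `tau2 = max(0, (Q - df)/C)` with `C = sum(w) - sum(w^2)/sum(w)` and
#' fixed-effects weights `w`. Studies are then re-weighted as
#' `w*_i = 1/(se_i^2 + tau2)` and pooled as in [fixed_effects()].
#'
#' @inheritParams fixed_effects
#' @return A `meta_result` with `model = "random"` and the estimated
#'   `tau2`; heterogeneity diagnostics attached as `$het`.
#' @export
random_effects <- function(effects) {
  k <- nrow(effects)
  if (k < 2L)
    stop("random_effects requires at least 2 studies (got ", k, ")")
  het <- heterogeneity(effects)
  se <- .prepare_se(effects, quiet = TRUE)
  w <- 1 / se^2
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (het$Q - het$df) / C)
  fit <- .pool(effects$lfc, 1 / (se^2 + tau2))
  .meta_result(effects$gene[1L], k, fit$pooled, fit$se, fit$p,
               "random", tau2, het)
}

#' Pool one gene's effects with heterogeneity-driven model selection
#'
#' Computes [heterogeneity()]; if `ISq = 0` (i.e. `Q <= df`) the
#' fixed-effects model is selected, otherwise the DerSimonian-Laird
#' random-effects model. With a single study the fixed model is used and
#' heterogeneity is undefined (`$het` is `NULL`, flagged by
#' `$het_undefined`). `Qp` is reported but never gates the choice.
#'
#' @inheritParams fixed_effects
#' @return A `meta_result` object; see [fixed_effects()],
#'   [random_effects()].
#' @examples
#' eff <- data.frame(gene = "PPARG",
#'                   lfc = c(-0.5, -0.4, -0.6), se = c(0.1, 0.2, 0.15))
#' meta_analyze(eff)
#' @export
meta_analyze <- function(effects) {
  k <- nrow(effects)
  if (k < 1L) stop("meta_analyze: no effect estimates supplied")
  if (k == 1L) {
    res <- fixed_effects(effects)
    res$het_undefined <- TRUE
    return(res)
  }
  het <- heterogeneity(effects)
  res <- if (het$ISq == 0) fixed_effects(effects) else random_effects(effects)
  res$het <- het
  res$het_undefined <- FALSE
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Mega-analysis of '%s' (%d studies, %s-effects model)\n",
              x$gene, x$k, x$model))
  cat(sprintf("  pooled LFC = %.4f (se %.4f), p = %.4g\n",
              x$pooled_lfc, x$pooled_se, x$p_value))
  if (x$model == "random")
    cat(sprintf("  tau2 = %.4g\n", x$tau2))
  if (!is.null(x$het)) print(x$het)
  invisible(x)
}

#' @export
coef.meta_result <- function(object, ...) {
  stats::setNames(object$pooled_lfc, "pooled_lfc")
}

#' @export
confint.meta_result <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(object$pooled_lfc + c(-1, 1) * z * object$pooled_se, 1L, 2L,
              dimnames = list("pooled_lfc",
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2))))
  m
}

#' @export
summary.meta_result <- function(object, ...) {
  structure(list(result = object, ci = confint(object)),
            class = "summary.meta_result")
}

#' @export
print.summary.meta_result <- function(x, ...) {
  print(x$result)
  cat(sprintf("  95%% CI: [%.4f, %.4f]\n", x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Turn a meta_result into a one-row data frame
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return One-row `data.frame` with gene, k, pooled LFC/se/p, model, tau2
#'   and the heterogeneity statistics (NA when undefined).
#' @export
as.data.frame.meta_result <- function(x, ...) {
  data.frame(gene = x$gene, k = x$k, pooled_lfc = x$pooled_lfc,
             pooled_se = x$pooled_se, p_value = x$p_value, model = x$model,
             tau2 = x$tau2,
             Q = if (is.null(x$het)) NA_real_ else x$het$Q,
             df = if (is.null(x$het)) NA_real_ else x$het$df,
             ISq = if (is.null(x$het)) NA_real_ else x$het$ISq,
             Qp = if (is.null(x$het)) NA_real_ else x$het$Qp,
             stringsAsFactors = FALSE)
}

#' Mega-analysis over many genes
#'
#' Runs [meta_analyze()] on every requested gene across a list of studies,
#' skipping studies that lack the gene. A Benjamini-Hochberg column
#' (`p_bh`) across genes is appended as extra information; the per-gene
#' p-values themselves are reported raw.
#'
#' @param studies List of [expression_study()] objects.
#' @param genes Character vector of genes to pool; default: union of all
#'   genes observed in any study.
#' @return `data.frame`, one row per gene (columns as in
#'   [as.data.frame.meta_result()] plus `p_bh`), sorted by `gene`.
#' @export
mega_analyze_genes <- function(studies, genes = NULL) {
  if (is.null(genes))
    genes <- sort(unique(unlist(lapply(studies,
                                       function(s) rownames(s$matrix)))))
  genes <- sort(unique(genes))
  rows <- lapply(genes, function(g) {
    eff <- suppressMessages(effects_for_gene(studies, g))
    if (nrow(eff) == 0L) return(NULL)
    as.data.frame(meta_analyze(eff))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(0), k = integer(0),
                      pooled_lfc = numeric(0), pooled_se = numeric(0),
                      p_value = numeric(0), model = character(0),
                      tau2 = numeric(0), Q = numeric(0), df = numeric(0),
                      ISq = numeric(0), Qp = numeric(0), p_bh = numeric(0)))
  out$p_bh <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
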