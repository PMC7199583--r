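# Over-representation analysis: Fisher's exact (hypergeometric upper tail)
# enrichment of a query gene list in named gene sets, Benjamini-Hochberg
# FDR control, and Jaccard similarity between query and set.

#' Jaccard similarity from set size, query size and overlap
#'
#' `overlap / (set_size + query_size - overlap)`; the empty-sets case
#' (0/0) is 0 by convention. Vectorized.
#'
#' @param set_size,query_size,overlap Non-negative counts with
#'   `overlap <= min(set_size, query_size)`.
#' @return Similarity in \[0, 1\].
#' @examples
#' jaccard(544, 26, 17)  # 0.0307... -> prints as 0.031 at 3 decimals
#' @export
jaccard <- function(set_size, query_size, overlap) {
  if (any(overlap > pmin(set_size, query_size)))
    stop("overlap exceeds set or query size")
  denom <- set_size + query_size - overlap
  ifelse(denom == 0, 0, overlap / denom)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, computed on ranks so the
#' output is invariant to input order. Thin wrapper over
#' [stats::p.adjust()] with input validation.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Fisher's exact gene-set enrichment
#'
#' For each set, the p-value is the hypergeometric upper tail
#' `P(X >= overlap)` for a population of `N = |universe|` genes containing
#' `set_size` successes, from which `query_size` genes are drawn. Query
#' genes outside the universe are dropped with a warning; set sizes are
#' counted within the universe. A BH q-value column, an `fdr_pass` flag at
#' level `fdr_q`, and the Jaccard similarity (on the universe-restricted
#' sizes) are included.
#'
#' @param query Character vector of query gene identifiers.
#' @param sets A [gene_set_collection()].
#' @param universe Background gene vector; default: the collection's
#'   explicit universe, else the union of all set members.
#' @param fdr_q FDR level for the `fdr_pass` column (default 0.05).
#' @return `data.frame` of class `enrichment_result`, one row per set:
#'   `set_name`, `set_size`, `query_size`, `overlap`, `p_value`, `q_value`,
#'   `jaccard`, `fdr_pass`, `overlap_genes` (`;`-separated).
#' @export
fisher_enrich <- function(query, sets, universe = NULL, fdr_q = 0.05) {
  if (is.null(universe))
    universe <- if (!is.null(sets$universe)) sets$universe
                else unique(unlist(sets$sets, use.names = FALSE))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("fisher_enrich: empty universe")
  query <- unique(query)
  stray <- setdiff(query, universe)
  if (length(stray)) {
    warning("fisher_enrich: ", length(stray),
            " query gene(s) outside the universe dropped: ",
            paste(utils::head(stray, 5L), collapse = ", "))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  q_n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    ov <- intersect(query, members)
    m <- length(members)
    p <- stats::phyper(length(ov) - 1L, m, N - m, q_n, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = m, query_size = q_n,
               overlap = length(ov), p_value = p,
               jaccard = jaccard(m, q_n, length(ov)),
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_name = character(0), set_size = integer(0),
                      query_size = integer(0), overlap = integer(0),
                      p_value = numeric(0), jaccard = numeric(0),
                      overlap_genes = character(0))
  out$q_value <- bh_fdr(out$p_value)
  out$fdr_pass <- out$q_value <= fdr_q
  out <- out[, c("set_name", "set_size", "query_size", "overlap", "p_value",
                 "q_value", "jaccard", "fdr_pass", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter enrichment results by p-value and keep the top hits
#'
#' Keeps rows with `p_value < p_threshold`, sorts ascending by p with ties
#' broken by set name (deterministically), and truncates to `top_k` rows
#' when given.
#'
#' @param results An `enrichment_result` `data.frame`.
#' @param p_threshold Strict upper bound on p (default `1e-6`).
#' @param top_k Optional row cap after sorting.
#' @return The filtered, sorted subset.
#' @export
filter_and_rank <- function(results, p_threshold = 1e-6, top_k = NULL) {
  out <- results[results$p_value < p_threshold, , drop = FALSE]
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Count query genes covered by at least one surviving set
#'
#' @param results Enrichment rows (with their `overlap_genes` column), e.g.
#'   the output of [filter_and_rank()].
#' @param query The query gene vector.
#' @return Number of query genes appearing in >= 1 of the given sets.
#' @export
genes_covered <- function(results, query) {
  hit <- unique(unlist(strsplit(results$overlap_genes[
    nzchar(results$overlap_genes)], ";", fixed = TRUE)))
  length(intersect(unique(query), hit))
}
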