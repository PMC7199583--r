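# Classification of literature relations against disease direction.
#
# A regulator->target relation carries a polarity (positive = stimulates,
# negative = suppresses) and the target carries a literature-reported
# direction in disease (up_in_disease / down_in_disease, or the equivalent
# disease-role vocabulary promoter / inhibitor). A target whose regulator
# polarity OPPOSES its disease direction is "contradirectional": the
# regulator pushes against the disease phenotype.

.normalize_direction <- function(dir) {
  dir[dir == "promoter"] <- "up_in_disease"
  dir[dir == "inhibitor"] <- "down_in_disease"
  dir
}

#' Classify regulator-target relations as contradirectional or concordant
#'
#' A target is a *suppressed disease promoter* when the regulator affects it
#' negatively and the literature reports it upregulated in disease (or as a
#' disease promoter), and an *activated disease inhibitor* when the
#' regulator affects it positively and the literature reports it
#' downregulated in disease (or as a disease inhibitor). Same-direction
#' pairs are labeled `concordant_excluded`. Targets with unknown disease
#' direction are excluded and reported via the `"excluded"` attribute, as
#' are targets whose multiple relations conflict in polarity with tied
#' reference support.
#'
#' When a target carries several relations from the same regulator, the one
#' with the largest `n_refs` wins; a polarity conflict with tied `n_refs`
#' excludes the target.
#'
#' @param relations Relation `data.frame` (see [read_relation_table()]).
#' @param regulator Regulator gene identifier whose outgoing relations are
#'   classified.
#' @return A `data.frame` of class `classified_targets` with columns
#'   `gene`, `cls`, `literature_direction`, `regulator_polarity`, `n_refs`,
#'   `confirmed_by_expression` (initialized `"untested"`); excluded targets
#'   with reasons in `attr(, "excluded")`.
#' @export
classify_contradirectional <- function(relations, regulator) {
  rel <- relations[relations$regulator == regulator, , drop = FALSE]
  rel$disease_direction <- .normalize_direction(rel$disease_direction)
  excluded <- data.frame(gene = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (g in unique(rel$target)) {
    r <- rel[rel$target == g, , drop = FALSE]
    r <- r[r$n_refs == max(r$n_refs), , drop = FALSE]
    if (length(unique(r$polarity)) > 1L) {
      excluded <- rbind(excluded, data.frame(
        gene = g, reason = "conflicting polarity with tied reference support"))
      next
    }
    if (length(unique(r$disease_direction)) > 1L) {
      excluded <- rbind(excluded, data.frame(
        gene = g,
        reason = "conflicting disease direction with tied reference support"))
      next
    }
    r <- r[1L, , drop = FALSE]
    if (r$disease_direction == "unknown") {
      excluded <- rbind(excluded,
                        data.frame(gene = g, reason = "unknown disease direction"))
      next
    }
    cls <- if (r$polarity == "negative" && r$disease_direction == "up_in_disease")
      "suppressed_disease_promoter"
    else if (r$polarity == "positive" && r$disease_direction == "down_in_disease")
      "activated_disease_inhibitor"
    else
      "concordant_excluded"
    rows[[g]] <- data.frame(gene = g, cls = cls,
                            literature_direction = r$disease_direction,
                            regulator_polarity = r$polarity,
                            n_refs = r$n_refs,
                            confirmed_by_expression = "untested",
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), cls = character(0),
               literature_direction = character(0),
               regulator_polarity = character(0), n_refs = integer(0),
               confirmed_by_expression = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(excluded))
    message("classify_contradirectional: excluded ", nrow(excluded),
            " target(s): ",
            paste(excluded$gene, "(", excluded$reason, ")", collapse = "; "))
  attr(out, "excluded") <- excluded
  class(out) <- c("classified_targets", "data.frame")
  out
}

#' Confirm classified targets against pooled expression results
#'
#' A target is `confirmed` when its pooled log2 fold-change is significant
#' at `alpha` and its sign matches the literature direction (positive for
#' `up_in_disease`, negative for `down_in_disease`); `contradicted` when
#' significant with the opposite sign; `untested` otherwise (including
#' genes absent from the meta results).
#'
#' @param targets `classified_targets` from [classify_contradirectional()].
#' @param meta `data.frame` with columns `gene`, `pooled_lfc`, `p_value`
#'   (e.g. from [mega_analyze_genes()]).
#' @param alpha Per-gene significance level (default 0.05).
#' @return `targets` with `confirmed_by_expression` filled in.
#' @export
confirm_with_expression <- function(targets, meta, alpha = 0.05) {
  stopifnot(all(c("gene", "pooled_lfc", "p_value") %in% names(meta)))
  idx <- match(targets$gene, meta$gene)
  state <- rep("untested", nrow(targets))
  found <- !is.na(idx)
  if (any(found)) {
    lfc <- meta$pooled_lfc[idx[found]]
    p <- meta$p_value[idx[found]]
    expect <- ifelse(targets$literature_direction[found] == "up_in_disease",
                     1, -1)
    sig <- !is.na(p) & p <= alpha & sign(lfc) != 0
    st <- rep("untested", sum(found))
    st[sig & sign(lfc) == expect] <- "confirmed"
    st[sig & sign(lfc) == -expect] <- "contradicted"
    state[found] <- st
  }
  targets$confirmed_by_expression <- state
  targets
}

#' Summarize classified targets by class and confirmation state
#'
#' @param targets `classified_targets` `data.frame`.
#' @return A list with named integer vectors `classes` (all three class
#'   labels, zero-filled) and `confirmation`, plus `n_targets`. Counts
#'   partition the input: both vectors sum to `n_targets`.
#' @export
count_classes <- function(targets) {
  cls_levels <- c("suppressed_disease_promoter", "activated_disease_inhibitor",
                  "concordant_excluded")
  conf_levels <- c("confirmed", "contradicted", "untested")
  classes <- table(factor(targets$cls, levels = cls_levels))
  confirmation <- table(factor(targets$confirmed_by_expression,
                               levels = conf_levels))
  list(classes = stats::setNames(as.integer(classes), cls_levels),
       confirmation = stats::setNames(as.integer(confirmation), conf_levels),
       n_targets = nrow(targets))
}
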