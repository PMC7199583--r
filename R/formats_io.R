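#' Construct an expression study
#'
#' An `expression_study` bundles one cohort's log2 expression matrix
#' (genes x samples) with its case/control sample labels and study-level
#' metadata (country of origin, study age in years since deposition).
#'
#' @param study_id Character scalar identifying the cohort.
#' @param matrix Numeric matrix, genes in rows (rownames = gene identifiers,
#'   unique), samples in columns (colnames = sample identifiers). Values are
#'   log2 expression intensities.
#' @param sample_groups Character vector of `"control"`/`"case"` labels, one
#'   per sample column. May be named by sample identifier; if so it is
#'   reordered to match the matrix columns.
#' @param country Character scalar, country of origin (metadata).
#' @param study_age Integer scalar >= 0, years since the study was deposited.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `study_id`, `matrix`, `sample_groups`, `n_control`, `n_case`,
#'   `country`, `study_age`.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(c("TP53", "PPARG", "EGFR"), paste0("s", 1:4)))
#' expression_study("demo", m, c("control", "control", "case", "case"))
#' @export
expression_study <- function(study_id, matrix, sample_groups,
                             country = NA_character_,
                             study_age = NA_integer_) {
  stopifnot(is.character(study_id), length(study_id) == 1L,
            is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)))
    stop("expression matrix must have gene identifiers as rownames")
  if (anyDuplicated(rownames(matrix))) {
    dup <- unique(rownames(matrix)[duplicated(rownames(matrix))])
    stop("duplicate gene identifier(s) in study '", study_id, "': ",
         paste(dup, collapse = ", "))
  }
  if (!all(is.finite(matrix)))
    stop("non-finite expression values in study '", study_id, "'")
  if (!is.null(names(sample_groups)) && !is.null(colnames(matrix))) {
    missing <- setdiff(colnames(matrix), names(sample_groups))
    if (length(missing))
      stop("missing group label for sample(s): ",
           paste(missing, collapse = ", "))
    sample_groups <- sample_groups[colnames(matrix)]
  }
  sample_groups <- unname(as.character(sample_groups))
  if (length(sample_groups) != ncol(matrix))
    stop("sample_groups length (", length(sample_groups),
         ") does not match number of samples (", ncol(matrix), ")")
  bad <- setdiff(unique(sample_groups), c("control", "case"))
  if (length(bad))
    stop("group labels outside {control, case}: ", paste(bad, collapse = ", "))
  n_control <- sum(sample_groups == "control")
  n_case <- sum(sample_groups == "case")
  if (n_control < 1L || n_case < 1L)
    stop("study '", study_id, "' needs at least one control and one case sample")
  structure(
    list(study_id = study_id, matrix = matrix, sample_groups = sample_groups,
         n_control = n_control, n_case = n_case,
         country = as.character(country),
         study_age = as.integer(study_age)),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study '", x$study_id, "': ", nrow(x$matrix), " genes, ",
      x$n_control, " control / ", x$n_case, " case samples",
      if (!is.na(x$country)) paste0(" (", x$country,
                                    ", study age ", x$study_age, " y)"),
      "\n", sep = "")
  invisible(x)
}

#' Read an expression study from a TSV matrix plus sample-group map
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and gene identifiers in the first column. Groups come either from a
#' two-column tab-separated file (sample, group) or from a named character
#' vector. Every sample must carry a `"control"` or `"case"` label.
#'
#' @param path Path to the expression matrix TSV.
#' @param groups Path to a two-column sample-to-group TSV (no header
#'   required; a `sample<TAB>group` header line is tolerated), or a named
#'   character vector mapping sample identifiers to groups.
#' @param study_id Study identifier; defaults to the file name without
#'   extension.
#' @param country,study_age Study-level metadata (see
#'   [expression_study()]).
#' @param assume_log2 If `TRUE` (default) values are taken to be log2
#'   already; if `FALSE` a `log2(x + 1)` transform is applied on load.
#' @return An [expression_study()] object.
#' @export
read_expression_study <- function(path, groups, study_id = NULL,
                                  country = NA_character_,
                                  study_age = NA_integer_,
                                  assume_log2 = TRUE) {
  if (is.null(study_id))
    study_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression file '", path, "' has no sample columns")
  genes <- trimws(raw[[1L]])
  num <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                dimnames = list(genes, colnames(raw)[-1L]))
  for (j in seq_len(ncol(raw) - 1L)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("non-numeric or non-finite value in '", path, "' at gene '",
           genes[bad[1L]], "' (row ", bad[1L], "), sample '",
           colnames(raw)[j + 1L], "' (column ", j + 1L, ")")
    num[, j] <- v
  }
  if (!assume_log2) num <- log2(num + 1)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    g <- utils::read.delim(groups, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (identical(tolower(trimws(g[1L, 1L])), "sample"))
      g <- g[-1L, , drop = FALSE]
    groups <- stats::setNames(trimws(g[[2L]]), trimws(g[[1L]]))
  }
  expression_study(study_id, num, groups,
                   country = country, study_age = study_age)
}

#' Write an expression study back to its TSV representation
#'
#' @param study An [expression_study()].
#' @param path Matrix output path.
#' @param groups_path Optional path for the sample-to-group map.
#' @return Invisibly, `path`.
#' @export
write_expression_study <- function(study, path, groups_path = NULL) {
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(
      data.frame(sample = colnames(study$matrix),
                 group = study$sample_groups),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member gene
#'   identifiers). Members are de-duplicated within each set.
#' @param universe Optional explicit background gene vector; must contain
#'   every set member.
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) && is.null(names(sets)))
    stop("sets must be named")
  sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  if (!is.null(universe)) {
    universe <- unique(trimws(as.character(universe)))
    stray <- setdiff(unique(unlist(sets, use.names = FALSE)), universe)
    if (length(stray))
      stop("universe is missing set member(s): ",
           paste(utils::head(stray, 5L), collapse = ", "))
  }
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("Gene-set collection: ", length(x$sets), " sets",
      if (length(sizes)) paste0(" (sizes ", min(sizes), "-", max(sizes), ")"),
      if (!is.null(x$universe)) paste0(", explicit universe of ",
                                       length(x$universe), " genes"),
      "\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Lines with fewer than three fields are a format error;
#' duplicate members within a line are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()] (universe unset).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list(); desc <- character(0)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has ", length(f), " field(s); at least 3 required")
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " ('", f[1L],
              "'): duplicate members de-duplicated")
      members <- unique(members)
    }
    sets[[trimws(f[1L])]] <- members
    desc[trimws(f[1L])] <- f[2L]
  }
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  nm <- names(collection$sets)
  desc <- collection$descriptions
  lines <- vapply(seq_along(collection$sets), function(i) {
    d <- if (!is.null(desc) && !is.na(desc[nm[i]])) desc[[nm[i]]] else "na"
    paste(c(nm[i], d, collection$sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# Polarity vocabulary: the field's edge notation writes "-|" for a negative
# (inhibitory) effect and "-+>" for a positive (stimulatory) one.
.parse_polarity <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("-|", "negative", "neg", "-")] <- "negative"
  out[x %in% c("-+>", "positive", "pos", "+")] <- "positive"
  out
}

.direction_vocab <- c("up_in_disease", "down_in_disease",
                      "promoter", "inhibitor", "unknown")

#' Read a literature relation table
#'
#' Five tab-separated columns: `regulator`, `target`, `polarity`,
#' `disease_direction`, `n_refs`. Polarity accepts the edge notations
#' `-|` (negative) and `-+>` (positive) as well as the words
#' `negative`/`positive`. Rows whose polarity cannot be resolved are
#' rejected (only polarity-bearing relations are admitted) and reported in
#' the `"rejected"` attribute; unknown disease direction is allowed.
#'
#' @param path Path to the relation TSV (header row required).
#' @return A `data.frame` with columns `regulator`, `target`, `polarity`,
#'   `disease_direction`, `n_refs`; rejected rows (with a `reason` column)
#'   in `attr(, "rejected")`.
#' @export
read_relation_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("regulator", "target", "polarity", "disease_direction", "n_refs")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("relation table is missing column(s): ", paste(miss, collapse = ", "))
  df$regulator <- trimws(df$regulator)
  df$target <- trimws(df$target)
  raw_pol <- df$polarity
  df$polarity <- .parse_polarity(df$polarity)
  df$n_refs <- suppressWarnings(as.integer(df$n_refs))
  dir <- tolower(trimws(df$disease_direction))
  odd <- !(dir %in% .direction_vocab)
  if (any(odd)) {
    message("read_relation_table: ", sum(odd),
            " row(s) with unrecognized disease_direction set to 'unknown'")
    dir[odd] <- "unknown"
  }
  df$disease_direction <- dir
  bad_pol <- is.na(df$polarity)
  bad_ref <- is.na(df$n_refs) | df$n_refs < 1L
  drop <- bad_pol | bad_ref
  rejected <- df[drop, need, drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(bad_pol[drop],
                              paste0("unrecognized polarity '",
                                     raw_pol[drop], "'"),
                              "n_refs missing or < 1")
    message("read_relation_table: rejected ", nrow(rejected),
            " row(s): ", paste(unique(rejected$reason), collapse = "; "))
  }
  out <- df[!drop, need, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a relation table
#' @param relations Relation `data.frame` (see [read_relation_table()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_relation_table <- function(relations, path) {
  utils::write.table(relations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tabular result to TSV
#'
#' Tab-separated with a header row; numeric values are written with full
#' (>= 6 significant digit) precision so that a written table re-reads to
#' the same values.
#'
#' @param records A `data.frame` (possibly zero rows -> header-only file).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
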