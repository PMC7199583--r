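# End-to-end orchestration: relations -> mega-analysis -> confirmation ->
# covariate regression -> enrichment -> shared-pathway network, each stage
# writing a plain TSV artifact plus a reproducibility manifest.

#' Pipeline configuration
#'
#' @param relations Path to the relation TSV (see
#'   [read_relation_table()]).
#' @param studies_manifest Path to a TSV listing the studies, with columns
#'   `study_id`, `matrix_path`, `groups_path`, `country`, `study_age`.
#' @param gmt Path to the gene-set GMT file.
#' @param universe Optional path to a one-gene-per-line background file;
#'   default: union of the GMT sets.
#' @param regulator Regulator gene identifier (default `"PPARG"`).
#' @param alpha Per-gene confirmation significance level (default 0.05).
#' @param p_threshold Enrichment survival threshold (strict, default
#'   `1e-6`).
#' @param fdr_q FDR level for the enrichment pass/fail column (default
#'   0.05).
#' @param top_k Rows kept in the ranked enrichment table (default 10).
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed matters when the inputs were simulated).
#' @param out_dir Output directory for the artifact bundle.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(relations, studies_manifest, gmt,
                            universe = NULL, regulator = "PPARG",
                            alpha = 0.05, p_threshold = 1e-6, fdr_q = 0.05,
                            top_k = 10L, seed = 1L, out_dir = ".") {
  structure(list(relations = relations, studies_manifest = studies_manifest,
                 gmt = gmt, universe = universe, regulator = regulator,
                 alpha = alpha, p_threshold = p_threshold, fdr_q = fdr_q,
                 top_k = as.integer(top_k), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Never throws: returns a character vector of problems (missing paths,
#' out-of-range thresholds); an empty vector means the configuration is
#' runnable.
#'
#' @param cfg A [pipeline_config()].
#' @return Character vector of issues (possibly empty).
#' @export
validate_config <- function(cfg) {
  issues <- character(0)
  for (field in c("relations", "studies_manifest", "gmt")) {
    p <- cfg[[field]]
    if (is.null(p) || !is.character(p) || !file.exists(p))
      issues <- c(issues, paste0("missing or unreadable ", field,
                                 " path: '", p, "'"))
  }
  if (!is.null(cfg$universe) && !file.exists(cfg$universe))
    issues <- c(issues, paste0("missing universe path: '", cfg$universe, "'"))
  for (field in c("alpha", "p_threshold", "fdr_q")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      issues <- c(issues, paste0(field, " must lie in (0, 1); got ", v))
  }
  if (cfg$top_k < 1L) issues <- c(issues, "top_k must be >= 1")
  issues
}

.read_studies_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "matrix_path", "groups_path", "country", "study_age")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("studies manifest missing column(s): ", paste(miss, collapse = ", "))
  # relative paths resolve against the manifest's own directory
  base <- dirname(path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  lapply(seq_len(nrow(man)), function(i)
    read_expression_study(fix(man$matrix_path[i]), fix(man$groups_path[i]),
                          study_id = man$study_id[i],
                          country = man$country[i],
                          study_age = man$study_age[i]))
}

.stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage '", name, "': ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: relation classification, per-gene mega-analysis,
#' expression-based confirmation, covariate regression, Fisher's exact
#' enrichment, and shared-pathway network construction. Each stage writes
#' a TSV artifact into `cfg$out_dir`; a run manifest (package version,
#' seed, thresholds, input digests) makes the run reproducible. Two runs
#' with identical configuration and inputs produce byte-identical outputs.
#'
#' @param cfg A [pipeline_config()]; must pass [validate_config()].
#' @return Invisibly, a named list of the artifact paths.
#' @export
run_pipeline <- function(cfg) {
  issues <- validate_config(cfg)
  if (length(issues))
    stop("invalid pipeline configuration:\n  ",
         paste(issues, collapse = "\n  "))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(cfg$out_dir, "FAILED"))
  out <- function(f) file.path(cfg$out_dir, f)
  paths <- list()

  relations <- .stage("read_relations", cfg$out_dir,
                      read_relation_table(cfg$relations))
  targets <- .stage("classify", cfg$out_dir, suppressMessages(
    classify_contradirectional(relations, cfg$regulator)))
  paths$classified_targets <- out("classified_targets.tsv")
  write_results_table(targets, paths$classified_targets)
  counts <- count_classes(targets)
  message("pipeline: ", counts$classes[["suppressed_disease_promoter"]],
          " suppressed disease promoters, ",
          counts$classes[["activated_disease_inhibitor"]],
          " activated disease inhibitors among ", counts$n_targets,
          " classified targets")

  studies <- .stage("read_studies", cfg$out_dir,
                    .read_studies_manifest(cfg$studies_manifest))
  genes <- sort(unique(c(cfg$regulator, relations$target)))
  mega <- .stage("mega_analysis", cfg$out_dir,
                 mega_analyze_genes(studies, genes))
  paths$mega_analysis <- out("mega_analysis.tsv")
  write_results_table(mega, paths$mega_analysis)
  message("pipeline: mega-analysis pooled ", nrow(mega), " genes across ",
          length(studies), " studies")

  confirmed <- .stage("confirm", cfg$out_dir,
                      confirm_with_expression(targets, mega,
                                              alpha = cfg$alpha))
  paths$confirmation <- out("confirmation.tsv")
  write_results_table(confirmed, paths$confirmation)

  mlr <- .stage("mlr", cfg$out_dir, suppressMessages(
    mlr_table(studies, genes)))
  paths$mlr <- out("mlr.tsv")
  write_results_table(mlr, paths$mlr)

  gsc <- .stage("read_gmt", cfg$out_dir, read_gmt(cfg$gmt))
  universe <- if (!is.null(cfg$universe)) readLines(cfg$universe) else NULL
  query <- genes
  enrich <- .stage("enrichment", cfg$out_dir, suppressWarnings(
    fisher_enrich(query, gsc, universe = universe, fdr_q = cfg$fdr_q)))
  surviving <- filter_and_rank(enrich, p_threshold = cfg$p_threshold)
  ranked <- utils::head(surviving, cfg$top_k)
  paths$enrichment <- out("enrichment.tsv")
  write_results_table(enrich[order(enrich$p_value, enrich$set_name), ],
                      paths$enrichment)
  paths$enrichment_top <- out("enrichment_top.tsv")
  write_results_table(ranked, paths$enrichment_top)
  message("pipeline: ", nrow(surviving), " sets below p < ", cfg$p_threshold,
          "; ", genes_covered(ranked, query), " of ", length(query),
          " query genes covered by the top ", nrow(ranked))

  membership <- .stage("network", cfg$out_dir, {
    mem <- lapply(stats::setNames(query, query), function(g)
      surviving$set_name[vapply(
        strsplit(surviving$overlap_genes, ";", fixed = TRUE),
        function(x) g %in% x, logical(1L))])
    mem[lengths(mem) > 0L]
  })
  net <- build_network(membership)
  paths$network <- out("network_edges.sif")
  write_network_sif(net, paths$network)
  paths$node_stats <- out("node_stats.tsv")
  write_results_table(node_stats_table(net), paths$node_stats)

  manifest <- data.frame(
    key = c("megapath_version", "seed", "regulator", "alpha", "p_threshold",
            "fdr_q", "top_k", "md5_relations", "md5_studies_manifest",
            "md5_gmt"),
    value = c(as.character(utils::packageVersion("megapath")), cfg$seed,
              cfg$regulator, cfg$alpha, cfg$p_threshold, cfg$fdr_q,
              cfg$top_k,
              unname(tools::md5sum(cfg$relations)),
              unname(tools::md5sum(cfg$studies_manifest)),
              unname(tools::md5sum(cfg$gmt))),
    stringsAsFactors = FALSE)
  paths$manifest <- out("run_manifest.tsv")
  write_results_table(manifest, paths$manifest)
  invisible(paths)
}
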