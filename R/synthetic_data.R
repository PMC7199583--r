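# Synthetic-data generator. Emulates the structure of a multi-cohort
# case/control microarray compendium — 13 public GEO lung-adenocarcinoma
# series with arm sizes from 4 to 443 — plus literature relation tables
# and GMT gene-set collections with planted ground truth, so every stage
# of the pipeline is testable without downloading anything.

#' Default 13-cohort study design
#'
#' Per-study control/case arm sizes, country of origin and study age
#' (years) mirroring 13 public GEO lung-adenocarcinoma case/control
#' series. This design (extreme arm imbalance included) is the default
#' condition under which the generator and the package's recovery
#' experiments operate.
#'
#' @return `data.frame` with `study_id`, `n_control`, `n_case`, `country`,
#'   `study_age`.
#' @export
default_study_design <- function() {
  data.frame(
    study_id = c("GSE2088", "GSE7670", "GSE10072", "GSE31547", "GSE32863",
                 "GSE32867", "GSE40791", "GSE43458", "GSE46539", "GSE51852",
                 "GSE63459", "GSE68465", "GSE118370"),
    n_control = c(30L, 28L, 49L, 20L, 58L, 58L, 90L, 30L, 92L, 4L, 32L, 4L, 6L),
    n_case = c(9L, 27L, 58L, 30L, 58L, 58L, 94L, 80L, 92L, 49L, 33L, 443L, 6L),
    country = c("Japan", "Taiwan", "USA", "USA", "USA", "USA", "USA", "USA",
                "Taiwan", "Japan", "USA", "USA", "China"),
    study_age = c(11L, 13L, 12L, 9L, 8L, 8L, 7L, 7L, 4L, 6L, 5L, 5L, 1L),
    stringsAsFactors = FALSE)
}

#' Default planted true effects
#'
#' Log2 fold-changes planted by default: the regulator PPARG at -0.48
#' (down in disease) and a 0.5-magnitude effect, signed by literature
#' direction, for the targets the expression analysis is expected to
#' confirm; all other genes 0.
#'
#' @param relations Optional relation table whose confirmable targets get
#'   planted effects; defaults to the packaged synthetic relation fixture.
#' @return Named numeric vector of true log2 fold-changes.
#' @export
default_true_lfc <- function(relations = NULL) {
  up <- c("COL1A1", "SPP1", "CXCL14", "MMP9", "CCNB1", "CCR7", "TLR2")
  down <- c("CAV1", "PTEN", "FAS", "MIR145")
  lfc <- c(stats::setNames(rep(0.5, length(up)), up),
           stats::setNames(rep(-0.5, length(down)), down),
           PPARG = -0.48)
  if (is.null(relations))
    relations <- read_relation_table(megapath_fixture("synthetic_relations.tsv"))
  others <- setdiff(unique(c(relations$regulator, relations$target)),
                    names(lfc))
  c(lfc, stats::setNames(rep(0, length(others)), others))
}

#' Simulation configuration
#'
#' Bundles the study design and generative parameters. Per study `s` and
#' gene `g`, the true study effect is
#' `delta_gs ~ Normal(true_lfc_g + covariate terms, tau2)`; control
#' samples are `Normal(baseline_mean, noise_sd^2)` and case samples
#' `Normal(baseline_mean + delta_gs, noise_sd^2)`, all on the log2 scale.
#'
#' @param design Study design `data.frame` (see [default_study_design()]).
#' @param true_lfc Named numeric vector gene -> true log2 fold-change
#'   (defines the simulated gene universe).
#' @param tau2 Between-study variance of true effects (>= 0, default 0).
#' @param noise_sd Per-sample log2 noise standard deviation (> 0,
#'   default 1).
#' @param baseline_mean Log2 baseline intensity (default 8).
#' @param covariate_slopes Optional named list/vector with any of
#'   `sample_size`, `study_age` (per-unit additive effects on the true
#'   study effect) and `country` (named vector of per-country offsets).
#' @param seed Integer RNG seed (fixed seed => byte-identical output).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(design = default_study_design(),
                              true_lfc = default_true_lfc(),
                              tau2 = 0, noise_sd = 1, baseline_mean = 8,
                              covariate_slopes = NULL, seed = 1L) {
  stopifnot(tau2 >= 0, noise_sd > 0,
            all(design$n_control >= 1L), all(design$n_case >= 1L))
  if (is.null(names(true_lfc)))
    stop("true_lfc must be a named vector (gene -> effect)")
  structure(list(design = design, true_lfc = true_lfc, tau2 = tau2,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 covariate_slopes = covariate_slopes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.covariate_shift <- function(cfg, study_row) {
  sl <- cfg$covariate_slopes
  if (is.null(sl)) return(0)
  shift <- 0
  if (!is.null(sl$sample_size))
    shift <- shift + sl$sample_size * (study_row$n_control + study_row$n_case)
  if (!is.null(sl$study_age))
    shift <- shift + sl$study_age * study_row$study_age
  if (!is.null(sl$country) && study_row$country %in% names(sl$country))
    shift <- shift + sl$country[[study_row$country]]
  shift
}

#' Simulate a collection of expression studies with known ground truth
#'
#' @param cfg A [simulation_config()].
#' @return List with `studies` (list of [expression_study()] objects) and
#'   `truth` (`data.frame` of the realized per-study true effects
#'   `delta_gs`, one row per gene x study, plus the config's planted
#'   `true_lfc`).
#' @export
simulate_studies <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genes <- names(cfg$true_lfc)
  studies <- vector("list", nrow(cfg$design))
  truth <- vector("list", nrow(cfg$design))
  for (i in seq_len(nrow(cfg$design))) {
    row <- cfg$design[i, ]
    nc <- row$n_control; na <- row$n_case
    delta <- stats::rnorm(length(genes),
                          cfg$true_lfc + .covariate_shift(cfg, row),
                          sqrt(cfg$tau2))
    ctrl <- matrix(stats::rnorm(length(genes) * nc, cfg$baseline_mean,
                                cfg$noise_sd),
                   length(genes), nc)
    case <- matrix(stats::rnorm(length(genes) * na,
                                rep(cfg$baseline_mean + delta, na),
                                cfg$noise_sd),
                   length(genes), na)
    m <- cbind(ctrl, case)
    dimnames(m) <- list(genes,
                        c(sprintf("%s_C%03d", row$study_id, seq_len(nc)),
                          sprintf("%s_T%03d", row$study_id, seq_len(na))))
    studies[[i]] <- expression_study(
      row$study_id, m, rep(c("control", "case"), c(nc, na)),
      country = row$country, study_age = row$study_age)
    truth[[i]] <- data.frame(study_id = row$study_id, gene = genes,
                             delta = delta, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth$true_lfc <- cfg$true_lfc[truth$gene]
  list(studies = studies, truth = truth)
}

#' Simulate a gene-set collection with planted query overlaps
#'
#' Each generated set contains exactly the requested number of query
#' genes (drawn from a restricted coverage pool when `planted_coverage`
#' is given, so that the union of all overlaps covers exactly that many
#' query genes) plus background genes sampled from the universe outside
#' the query.
#'
#' @param sizes Integer vector of set sizes (one set per entry).
#' @param planted_query Character vector: the query gene list.
#' @param planted_overlaps Integer vector, same length as `sizes`: exact
#'   overlap of each set with the query.
#' @param universe_size Total number of genes in the background universe
#'   (query included).
#' @param planted_coverage Optional cap on how many distinct query genes
#'   may appear across all sets (e.g. 24 of a 26-gene query).
#' @param set_names Optional set names (default `SET001`, ...).
#' @param seed Integer RNG seed.
#' @return A [gene_set_collection()] with an explicit universe; planted
#'   truth (`sizes`, `overlaps`, `coverage_pool`) in `attr(, "truth")`.
#' @export
simulate_genesets <- function(sizes, planted_query, planted_overlaps,
                              universe_size, planted_coverage = NULL,
                              set_names = NULL, seed = 1L) {
  stopifnot(length(sizes) == length(planted_overlaps))
  if (any(planted_overlaps > pmin(sizes, length(planted_query))))
    stop("planted overlap exceeds set size or query size")
  if (universe_size < max(sizes) + length(planted_query))
    stop("universe_size too small for the requested sets")
  set.seed(as.integer(seed))
  query <- unique(planted_query)
  background <- sprintf("BG%05d", seq_len(universe_size - length(query)))
  pool <- if (is.null(planted_coverage)) query
          else sample(query, planted_coverage)
  if (any(planted_overlaps > length(pool)))
    stop("planted overlap exceeds the coverage pool")
  if (is.null(set_names)) set_names <- sprintf("SET%03d", seq_along(sizes))
  overlap_members <- lapply(planted_overlaps, function(k) sample(pool, k))
  # repair pass: every coverage-pool gene must appear in >= 1 set (so the
  # realized coverage equals the planted one exactly), provided the total
  # overlap budget allows it
  if (sum(planted_overlaps) >= length(pool)) {
    uncovered <- setdiff(pool, unlist(overlap_members))
    for (g in uncovered) {
      counts <- table(unlist(overlap_members))
      dup <- names(counts)[counts >= 2L]
      for (i in order(-planted_overlaps)) {
        swap <- intersect(overlap_members[[i]], dup)
        if (length(swap)) {
          overlap_members[[i]][match(swap[1L], overlap_members[[i]])] <- g
          break
        }
      }
    }
  }
  sets <- lapply(seq_along(sizes), function(i) {
    bg <- sample(background, sizes[i] - planted_overlaps[i])
    sort(c(overlap_members[[i]], bg))
  })
  names(sets) <- set_names
  out <- gene_set_collection(sets, universe = c(query, background))
  attr(out, "truth") <- list(sizes = sizes, overlaps = planted_overlaps,
                             coverage_pool = sort(pool))
  out
}

#' Simulate a literature relation table with planted class composition
#'
#' Generates regulator -> target relations whose contradirectional class
#' counts are matched exactly: `n_suppressed` negative-polarity targets
#' reported up in disease (suppressed disease promoters), `n_activated`
#' positive-polarity targets reported down in disease (activated disease
#' inhibitors), and the remaining `n_targets - n_suppressed - n_activated`
#' concordant pairs with random orientation.
#'
#' @param n_targets Total number of distinct targets.
#' @param n_suppressed,n_activated Planted contradirectional class counts.
#' @param regulator Regulator gene identifier (default `"REG1"`).
#' @param seed Integer RNG seed.
#' @return Relation `data.frame` (columns as in [read_relation_table()]);
#'   planted per-target classes in `attr(, "truth")`.
#' @export
simulate_relations <- function(n_targets, n_suppressed, n_activated,
                               regulator = "REG1", seed = 1L) {
  stopifnot(n_suppressed + n_activated <= n_targets)
  set.seed(as.integer(seed))
  targets <- sprintf("TGT%03d", seq_len(n_targets))
  cls <- rep("concordant_excluded", n_targets)
  cls[seq_len(n_suppressed)] <- "suppressed_disease_promoter"
  cls[n_suppressed + seq_len(n_activated)] <- "activated_disease_inhibitor"
  cls <- sample(cls)
  pol <- dir <- character(n_targets)
  pol[cls == "suppressed_disease_promoter"] <- "negative"
  dir[cls == "suppressed_disease_promoter"] <- "up_in_disease"
  pol[cls == "activated_disease_inhibitor"] <- "positive"
  dir[cls == "activated_disease_inhibitor"] <- "down_in_disease"
  conc <- cls == "concordant_excluded"
  pol[conc] <- sample(c("positive", "negative"), sum(conc), replace = TRUE)
  dir[conc] <- ifelse(pol[conc] == "positive", "up_in_disease",
                      "down_in_disease")
  out <- data.frame(regulator = regulator, target = targets, polarity = pol,
                    disease_direction = dir,
                    n_refs = sample(1:50, n_targets, replace = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(gene = targets, cls = cls,
                                   stringsAsFactors = FALSE)
  out
}

#' Path to a packaged fixture file
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
megapath_fixture <- function(file) {
  p <- system.file("extdata", file, package = "megapath", mustWork = TRUE)
  p
}

#' Write a complete synthetic input bundle to a directory
#'
#' Materializes everything [run_pipeline()] consumes: the packaged
#' synthetic relation table, simulated expression matrices with a studies
#' manifest, and a simulated GMT collection whose top sets reproduce the
#' planted overlap arithmetic (sizes 544, 334, 803, 662, 553, 215, 424,
#' 603, 461, 630 with overlaps 17, 14, 17, 16, 15, 12, 14, 15, 14, 15
#' against the 26-gene regulator + target query, coverage capped at 24
#' genes) plus weaker background sets.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed driving every stochastic choice.
#' @param n_extra_sets Number of additional weakly-overlapping sets
#'   (default 40).
#' @param universe_size Background universe size (default 8000).
#' @return Invisibly, a named list of the written paths (elements
#'   `relations`, `studies_manifest`, `gmt`).
#' @export
write_synthetic_bundle <- function(dir, seed = 1L, n_extra_sets = 40L,
                                   universe_size = 8000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  relations_path <- file.path(dir, "relations.tsv")
  file.copy(megapath_fixture("synthetic_relations.tsv"), relations_path,
            overwrite = TRUE)
  relations <- read_relation_table(relations_path)
  cfg <- simulation_config(true_lfc = default_true_lfc(relations),
                           seed = seed)
  sim <- simulate_studies(cfg)
  manifest <- studies_metadata(sim$studies)
  manifest$matrix_path <- file.path(dir,
                                    paste0(manifest$study_id, "_expr.tsv"))
  manifest$groups_path <- file.path(dir,
                                    paste0(manifest$study_id, "_groups.tsv"))
  for (i in seq_along(sim$studies))
    write_expression_study(sim$studies[[i]], manifest$matrix_path[i],
                           manifest$groups_path[i])
  manifest_path <- file.path(dir, "studies_manifest.tsv")
  write_results_table(manifest, manifest_path)
  write_results_table(sim$truth, file.path(dir, "ground_truth_effects.tsv"))
  query <- sort(unique(c(relations$regulator, relations$target)))
  top_sizes <- c(544L, 334L, 803L, 662L, 553L, 215L, 424L, 603L, 461L, 630L)
  top_overlaps <- c(17L, 14L, 17L, 16L, 15L, 12L, 14L, 15L, 14L, 15L)
  set.seed(seed + 1L)
  extra_sizes <- sample(100:800, n_extra_sets, replace = TRUE)
  extra_overlaps <- sample(4:10, n_extra_sets, replace = TRUE)
  gsc <- simulate_genesets(
    sizes = c(top_sizes, extra_sizes),
    planted_query = query,
    planted_overlaps = c(top_overlaps, extra_overlaps),
    universe_size = universe_size,
    planted_coverage = 24L,
    set_names = sprintf("PATH%03d", seq_len(10L + n_extra_sets)),
    seed = seed + 2L)
  gmt_path <- file.path(dir, "genesets.gmt")
  write_gmt(gsc, gmt_path)
  writeLines(gsc$universe, file.path(dir, "universe.txt"))
  invisible(list(relations = relations_path,
                 studies_manifest = manifest_path, gmt = gmt_path,
                 universe = file.path(dir, "universe.txt")))
}
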