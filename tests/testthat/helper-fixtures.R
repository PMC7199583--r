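# Shared builders for the test suite. Everything is generated in code;
# only the small relation TSVs ship as packaged fixtures.

# A tiny study with known group means: 3 genes x 4 samples.
toy_study <- function(study_id = "toy") {
  m <- rbind(G1 = c(1, 2, 3, 5),
             G2 = c(5, 5, 5, 5),
             G3 = c(2, 4, 3, 5))
  colnames(m) <- paste0("s", 1:4)
  expression_study(study_id, m, c("control", "control", "case", "case"),
                   country = "USA", study_age = 5L)
}

# A study built from explicit per-group value vectors for one gene.
one_gene_study <- function(ctrl, case, gene = "G", study_id = "s1") {
  m <- matrix(c(ctrl, case), nrow = 1,
              dimnames = list(gene, paste0("x", seq_along(c(ctrl, case)))))
  expression_study(study_id, m,
                   rep(c("control", "case"), c(length(ctrl), length(case))))
}

# Effect-size frame shorthand.
eff_df <- function(lfc, se, gene = "G") {
  data.frame(gene = gene, study_id = paste0("s", seq_along(lfc)),
             lfc = lfc, se = se, stringsAsFactors = FALSE)
}

write_tsv_text <- function(text) {
  f <- tempfile(fileext = ".tsv")
  writeLines(text, f)
  f
}

relations_fixture <- function(which = "common") {
  megapath_fixture(switch(which,
    common = "synthetic_relations_common_targets.tsv",
    role = "synthetic_relations_disease_role.tsv",
    all = "synthetic_relations.tsv"))
}

# Exhaustive hypergeometric upper tail by subset enumeration (oracle).
enum_fisher_p <- function(N, set_size, query_size, observed_overlap) {
  universe <- seq_len(N)
  set <- seq_len(set_size)
  if (query_size == 0)
    return(as.numeric(observed_overlap <= 0))
  subsets <- utils::combn(universe, query_size)
  overlaps <- colSums(matrix(subsets %in% set, nrow = query_size))
  mean(overlaps >= observed_overlap)
}
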