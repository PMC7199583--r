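test_that("expression matrix parsing validates structure and values", {
  f <- write_tsv_text(c("gene\ts1\ts2\ts3\ts4",
                        "TP53\t1.5\t2.0\t3.5\t4.0",
                        "PPARG\t5\t5\t5\t5",
                        "EGFR\t2\t3\t4\t5"))
  g <- write_tsv_text(c("s1\tcontrol", "s2\tcontrol", "s3\tcase", "s4\tcase"))
  st <- read_expression_study(f, g, study_id = "demo")
  expect_s3_class(st, "expression_study")
  expect_equal(st$n_control, 2L)
  expect_equal(st$n_case, 2L)
  expect_equal(dim(st$matrix), c(3L, 4L))
  expect_equal(st$matrix["TP53", "s3"], 3.5)

  dup <- write_tsv_text(c("gene\ts1\ts2\ts3\ts4",
                          "TP53\t1\t2\t3\t4", "TP53\t5\t6\t7\t8"))
  expect_error(read_expression_study(dup, g), "TP53")

  bad <- write_tsv_text(c("gene\ts1\ts2\ts3\ts4",
                          "TP53\t1\toops\t3\t4"))
  expect_error(read_expression_study(bad, g), "non-numeric")

  gmiss <- write_tsv_text(c("s1\tcontrol", "s2\tcontrol", "s3\tcase"))
  expect_error(read_expression_study(f, gmiss), "s4")
})

test_that("expression studies round-trip bit-for-bit", {
  st <- toy_study()
  mf <- tempfile(); gf <- tempfile()
  write_expression_study(st, mf, gf)
  back <- read_expression_study(mf, gf, study_id = st$study_id,
                                country = st$country,
                                study_age = st$study_age)
  expect_identical(back$matrix, st$matrix)
  expect_identical(back$sample_groups, st$sample_groups)
})

test_that("linear-scale input gets the log2(x+1) transform on request", {
  f <- write_tsv_text(c("gene\ts1\ts2", "G\t3\t7"))
  g <- write_tsv_text(c("s1\tcontrol", "s2\tcase"))
  st <- read_expression_study(f, g, assume_log2 = FALSE)
  expect_equal(unname(st$matrix[1, ]), log2(c(3, 7) + 1))
})

test_that("GMT parsing enforces the 3-field minimum and de-duplicates", {
  f <- write_tsv_text("GO:0070482\tresponse to oxygen levels\tA\tB\tC")
  gsc <- read_gmt(f)
  expect_length(gsc$sets, 1L)
  expect_setequal(gsc$sets[["GO:0070482"]], c("A", "B", "C"))

  empty <- tempfile(); file.create(empty)
  expect_length(read_gmt(empty)$sets, 0L)

  dup <- write_tsv_text("S1\tdesc\tA\tB\tA")
  expect_warning(gsc2 <- read_gmt(dup), "duplicate")
  expect_length(gsc2$sets[["S1"]], 2L)

  short <- write_tsv_text(c("S1\tdesc\tA", "S2\tonlydesc"))
  expect_error(read_gmt(short), "line 2")
})

test_that("GMT collections round-trip up to member ordering", {
  gsc <- gene_set_collection(list(S1 = c("B", "A", "C"), S2 = c("X", "Y")),
                             descriptions = c(S1 = "one", S2 = "two"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(gsc, f)
  back <- read_gmt(f)
  expect_identical(names(back$sets), names(gsc$sets))
  for (nm in names(gsc$sets))
    expect_setequal(back$sets[[nm]], gsc$sets[[nm]])
})

test_that("relation tables admit only polarity-bearing rows", {
  f <- write_tsv_text(c(
    "regulator\ttarget\tpolarity\tdisease_direction\tn_refs",
    "PPARG\tCOL1A1\t-|\tup_in_disease\t3",
    "PPARG\tMIR145\t-+>\tdown_in_disease\t2",
    "PPARG\tXYZ\t?\tup_in_disease\t1",
    "PPARG\tABC\tpositive\tweird_direction\t4"))
  rel <- suppressMessages(read_relation_table(f))
  expect_equal(nrow(rel), 3L)
  expect_equal(rel$polarity[rel$target == "COL1A1"], "negative")
  expect_equal(rel$polarity[rel$target == "MIR145"], "positive")
  expect_equal(rel$disease_direction[rel$target == "ABC"], "unknown")
  rejected <- attr(rel, "rejected")
  expect_equal(rejected$target, "XYZ")
  expect_match(rejected$reason, "polarity")
})

test_that("relation tables round-trip through write/read", {
  rel <- read_relation_table(relations_fixture("common"))
  f <- tempfile()
  write_relation_table(rel, f)
  back <- read_relation_table(f)
  expect_equal(back, rel, ignore_attr = TRUE)
})

test_that("results tables write headers for empty input and keep precision", {
  f <- tempfile()
  write_results_table(data.frame(gene = character(0), p = numeric(0)), f)
  expect_identical(readLines(f), "gene\tp")

  df <- data.frame(gene = c("A", "B"), value = c(1.2345678901, -0.000123456789))
  write_results_table(df, f)
  back <- utils::read.delim(f)
  expect_equal(back$value, df$value, tolerance = 1e-9)
})
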