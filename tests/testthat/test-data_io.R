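test_that("a well-formed bundle loads with the expected shapes", {
  paths <- write_toy_bundle()
  b <- load_input_bundle(paths)
  expect_s3_class(b, "sponge_bundle")
  expect_equal(nrow(b$circ_expr), 5L)
  expect_equal(nrow(b$mrna_expr), 8L)
  expect_equal(nrow(b$mirna_expr), 4L)
  expect_equal(sum(b$annotation$condition == "condition_1"), 3L)
  expect_equal(sum(b$annotation$condition == "condition_2"), 3L)
  # validated table kept verbatim; site tables cross-resolved
  expect_equal(nrow(b$validated), 2L)
  expect_true(all(b$circ_sites$target_id %in% rownames(b$circ_expr)))
})

test_that("annotation with fewer than 3 samples per condition is rejected", {
  paths <- write_toy_bundle(annotation_split = c(3L, 2L))
  expect_error(load_input_bundle(paths), class = "sample_count_error")
})

test_that("malformed identifiers are rejected with the offending value", {
  d <- tempfile(); dir.create(d)
  m <- matrix(1:12 + 0, 2, 6,
              dimnames = list(c("circ_12345", "hsa_circ_0000002"), sprintf("S%d", 1:6)))
  write.csv(data.frame(id = rownames(m), m), file.path(d, "bad.csv"), row.names = FALSE)
  err <- expect_error(read_expression_matrix(file.path(d, "bad.csv"), "circRNA"),
                      class = "identifier_error")
  expect_match(conditionMessage(err), "circ_12345")
  expect_error(expression_matrix(m, "miRNA"), class = "identifier_error")
})

test_that("the has_circ_ misspelling is auto-corrected with a warning", {
  m <- matrix(rnorm(6), 1, 6,
              dimnames = list("has_circ_0001234", sprintf("S%d", 1:6)))
  expect_warning(em <- expression_matrix(m, "circRNA"), "has_circ_")
  expect_equal(rownames(em), "hsa_circ_0001234")
})

test_that("shape violations name the problem", {
  m <- matrix(1, 2, 6, dimnames = list(c("G1", "G1"), sprintf("S%d", 1:6)))
  expect_error(expression_matrix(m, "mRNA"), class = "shape_error")
  m2 <- matrix(c(1, NA), 1, 2, dimnames = list("G1", c("S1", "S2")))
  expect_error(expression_matrix(m2, "mRNA"), class = "shape_error")
  d <- tempfile(); dir.create(d)
  writeLines("samples,foo\nS1,x", file.path(d, "ann.csv"))
  expect_error(read_sample_annotation(file.path(d, "ann.csv")),
               class = "missing_column_error")
})

test_that("GMT parsing uppercases, deduplicates and rejects short lines", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tTP53\tKRAS", "SETB\tdesc\tkras\tKRAS"), f)
  gs <- read_gmt(f)
  expect_equal(gs$SETA, c("TP53", "KRAS"))
  expect_equal(gs$SETB, "KRAS")
  writeLines(c("SETC\tdesc"), f)
  expect_error(read_gmt(f), class = "format_error")
})

test_that("the score matrix round-trips losslessly and sorts by rank", {
  fx <- generate_fixture(small_fixture_config(seed = 3))
  res <- run_pipeline(fx$bundle, sponge_config(seed = 3, nperm = 200))
  m <- res$score_matrix
  f <- tempfile(fileext = ".csv")
  write_score_matrix(m[sample.int(nrow(m)), ], f)   # writer restores rank order
  back <- read_score_matrix(f)
  expect_equal(names(back), names(m))
  expect_equal(back$rank_global, m$rank_global)
  expect_equal(back$mirna_id, m$mirna_id)
  expect_equal(back$mrna_target_list, m$mrna_target_list)
  for (col in c("s_affinity", "s_nbmre", "s_enrichmre", "s_fc_circ", "ss",
                "s_enrichsg", "mean_sg_of_targets")) {
    expect_equal(back[[col]], m[[col]], tolerance = 1e-9)
  }
})

test_that("an empty score matrix writes a header-only file with a warning", {
  empty <- assemble_score_matrix(
    data.frame(mirna_id = character(0), circ_id = character(0),
               s_affinity = numeric(0), s_nbmre = numeric(0),
               s_enrichmre = numeric(0), s_fc_circ = numeric(0),
               s_mirexpr = numeric(0), s_targetexpr_circ = numeric(0),
               s_enrichsg = numeric(0), ss = numeric(0),
               condition = character(0), n_mrna_targets = integer(0),
               mean_sg_of_targets = numeric(0), mrna_target_list = character(0),
               stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".csv")
  expect_warning(write_score_matrix(empty, f), "empty")
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_score_matrix(f)), 0L)
})

test_that("loading is insensitive to input row order", {
  paths <- write_toy_bundle()
  b1 <- load_input_bundle(paths)
  # permute the circRNA site rows on disk; canonical sorting restores them
  sites <- read.csv(paths$circ_sites)
  write.csv(sites[rev(seq_len(nrow(sites))), ], paths$circ_sites,
            row.names = FALSE, quote = FALSE)
  b2 <- load_input_bundle(paths)
  expect_equal(b2$circ_sites, b1$circ_sites)
})
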