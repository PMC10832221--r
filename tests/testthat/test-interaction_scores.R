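mk_sites <- function(mirna, target, score, type = "circRNA") {
  site_table(mirna, target, score, target_type = type)
}

test_that("collapse keeps the strongest site and counts MREs", {
  s <- mk_sites(rep("hsa-miR-1", 3), rep("hsa_circ_0000001", 3), c(-0.4, -0.1, -0.2))
  p <- collapse_sites(s)
  expect_equal(p$n_sites, 3L)
  expect_equal(p$raw_score_best, -0.4)

  s2 <- mk_sites(c("hsa-miR-1", "hsa-miR-1"), c("hsa_circ_0000001", "hsa_circ_0000002"),
                 c(-0.3, -0.2))
  p2 <- collapse_sites(s2)
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$n_sites, c(1L, 1L))
})

test_that("collapse conserves the total number of site rows", {
  set.seed(41)
  s <- mk_sites(sprintf("hsa-miR-%d", sample(1:5, 40, TRUE)),
                sprintf("hsa_circ_%07d", sample(1:6, 40, TRUE)),
                round(runif(40, -0.6, -0.05), 3))
  expect_equal(sum(collapse_sites(s)$n_sites), nrow(s))
})

test_that("affinity cutoff calibration restricts by evidence and interpolates", {
  pred <- data.frame(mirna_id = sprintf("hsa-miR-%d", 1:5),
                     target_id = sprintf("hsa_circ_%07d", 1:5),
                     target_type = "circRNA",
                     raw_score_best = c(-0.5, -0.4, -0.3, -0.2, -0.1),
                     n_sites = 1L, stringsAsFactors = FALSE)
  val <- validated_table(pred$mirna_id, pred$target_id,
                         n_clipseq = c(2L, 2L, 3L, 2L, 2L),
                         n_degradome = c(2L, 2L, 2L, 1L, 2L))
  # the (n_clip=2, n_deg=1) pair is excluded from the calibration set
  cal <- calibrate_affinity_cutoff(pred, val)
  expect_equal(cal$n_validated_used, 4L)
  expect_equal(cal$cutoff,
               quantile_type7_oracle(c(-0.5, -0.4, -0.3, -0.1), 0.95),
               tolerance = 1e-12)

  # constant distribution: cutoff = the constant; keep raw <= cutoff
  pred2 <- pred; pred2$raw_score_best <- rep(-0.2, 5)
  val2 <- validated_table(pred$mirna_id, pred$target_id, rep(2L, 5), rep(2L, 5))
  cal2 <- calibrate_affinity_cutoff(pred2, val2)
  expect_equal(cal2$cutoff, -0.2)
  keep <- apply_affinity_cutoff(data.frame(pred, check.names = FALSE), cal2)
  expect_equal(keep$raw_score_best, c(-0.5, -0.4, -0.3, -0.2))

  expect_error(calibrate_affinity_cutoff(pred, validated_table(
    "hsa-miR-9", "hsa_circ_0000009", 3L, 3L)), class = "calibration_error")
})

test_that("affinity rescaling maps strongest to 1, weakest to 0", {
  p <- data.frame(raw_score_best = c(-0.5, -0.3, -0.1))
  r <- rescale_affinity(p)
  expect_equal(r$s_affinity, c(1, 0.5, 0))
  pc <- data.frame(raw_score_best = rep(-0.2, 4))
  expect_equal(rescale_affinity(pc)$s_affinity, rep(0.5, 4))
  # strictly decreasing in the raw score wherever scores differ
  set.seed(5)
  pr <- data.frame(raw_score_best = sort(runif(20, -1, 0)))
  expect_true(all(diff(rescale_affinity(pr)$s_affinity) <= 0))
})

test_that("MRE counts are length-normalised for circRNAs only", {
  circ <- data.frame(mirna_id = "hsa-miR-1", target_id = "hsa_circ_0000001",
                     target_type = "circRNA", raw_score_best = -0.3, n_sites = 10L,
                     stringsAsFactors = FALSE)
  lengths <- circ_length_table("hsa_circ_0000001", 500L)
  expect_equal(normalize_mre_counts(circ, lengths)$s_nbmre, 0.02)
  mrna <- data.frame(mirna_id = "hsa-miR-1", target_id = "G1",
                     target_type = "mRNA", raw_score_best = -0.3, n_sites = 4L,
                     stringsAsFactors = FALSE)
  expect_equal(normalize_mre_counts(mrna)$s_nbmre, 4)
  expect_error(normalize_mre_counts(circ, circ_length_table("hsa_circ_0000002", 100L)),
               class = "missing_length_error")
})

test_that("binomial upper tail matches the exact pmf-summation oracle", {
  expect_equal(binomial_upper_tail(0L, 5L, 0.3), 1)
  expect_equal(binomial_upper_tail(2L, 2L, 0.5), 0.25)
  for (N in c(3L, 7L, 12L)) {
    for (k in 0:N) {
      for (p0 in c(0.05, 0.2, 0.5)) {
        expect_equal(binomial_upper_tail(k, N, p0), binom_tail_oracle(k, N, p0),
                     tolerance = 1e-12)
      }
    }
  }
  # monotonically non-increasing in k at fixed (N, p0)
  expect_true(all(diff(binomial_upper_tail(0:10, 10L, 0.2)) <= 0))
})

test_that("MRE enrichment computes pair-level binomial tests with BH", {
  pairs <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m2"),
    target_id = c("c1", "c2", "c1", "c2"),
    target_type = "circRNA",
    raw_score_best = -0.3,
    n_sites = c(6L, 1L, 1L, 4L), stringsAsFactors = FALSE)
  res <- test_mre_enrichment(pairs)
  grand <- 12L
  N <- c(7L, 5L, 7L, 5L)          # per-circRNA totals
  m_tot <- c(7L, 7L, 5L, 5L)      # per-miRNA totals
  p_exp <- mapply(function(k, N, p0) binom_tail_oracle(k, N, p0),
                  pairs$n_sites, N, m_tot / grand)
  expect_equal(res$pairs$s_enrichmre, bh_oracle(p_exp), tolerance = 1e-12)
  # filter idempotence
  again <- test_mre_enrichment(pairs)$filtered
  expect_equal(again[again$s_enrichmre < 0.05, ], again)
})

test_that("BH adjustment equals the step-up oracle exactly", {
  set.seed(61)
  for (n in c(1L, 17L, 400L)) {
    p <- runif(n)
    expect_identical(bh_adjust(p), bh_oracle(p))
  }
  # and stays numerically indistinguishable from stats::p.adjust
  p <- runif(100)
  expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"), tolerance = 1e-14)
})
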