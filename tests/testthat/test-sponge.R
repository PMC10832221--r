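mk_eligible <- function(mirna, circ, mrnas) {
  out <- data.frame(mirna_id = mirna, circ_id = circ, stringsAsFactors = FALSE)
  out$mrna_ids <- I(mrnas)
  out
}

mk_scored_pairs <- function(mirna, target, type, s_affinity, s_nbmre,
                            s_enrichmre = NULL) {
  df <- data.frame(mirna_id = mirna, target_id = target, target_type = type,
                   raw_score_best = -s_affinity, n_sites = 1L,
                   s_affinity = s_affinity, s_nbmre = s_nbmre,
                   stringsAsFactors = FALSE)
  if (!is.null(s_enrichmre)) df$s_enrichmre <- s_enrichmre
  df
}

test_that("SG is one joint TOPSIS over all eligible miRNA-mRNA pairs", {
  eligible <- mk_eligible("m1", "c1", list("g1"))
  mp <- mk_scored_pairs("m1", "g1", "mRNA", 0.8, 2)
  fc <- c(g1 = 1.5); mir <- c(m1 = 6); te <- c(g1 = 7)
  sg1 <- compute_sg(mp, fc, mir, te, eligible)
  expect_equal(sg1$sg, 0.5)     # degenerate single-alternative convention

  # dominance on all five criteria
  eligible2 <- mk_eligible(c("m1", "m2"), c("c1", "c1"), list("g1", "g2"))
  mp2 <- mk_scored_pairs(c("m1", "m2"), c("g1", "g2"), "mRNA",
                         c(0.9, 0.1), c(5, 1))
  fc2 <- c(g1 = 3, g2 = 0.5); mir2 <- c(m1 = 8, m2 = 2); te2 <- c(g1 = 9, g2 = 3)
  sg2 <- compute_sg(mp2, fc2, mir2, te2, eligible2)
  expect_equal(sg2$sg, c(1, 0))

  # random pools equal the brute-force TOPSIS oracle on the same matrix
  set.seed(131)
  n <- 10L
  genes <- sprintf("g%d", 1:n)
  eligible3 <- mk_eligible(rep("m1", n), rep("c1", n), as.list(genes))
  mp3 <- mk_scored_pairs(rep("m1", n), genes, "mRNA", runif(n), runif(n, 1, 5))
  fc3 <- setNames(rnorm(n), genes)
  te3 <- setNames(runif(n, 3, 9), genes)
  sg3 <- compute_sg(mp3, fc3, c(m1 = 5), te3, eligible3)
  i <- match(sg3$mrna_id, mp3$target_id)   # compute_sg sorts pairs canonically
  X <- cbind(mp3$s_affinity[i], mp3$s_nbmre[i], abs(fc3[sg3$mrna_id]),
             rep(5, n), te3[sg3$mrna_id])
  expect_equal(sg3$sg, topsis_oracle(X, rep("benefit", 5)), tolerance = 1e-12)
})

test_that("sponge scores run a 7-criterion TOPSIS with cost p-values", {
  eligible <- mk_eligible(c("m1", "m2"), c("c1", "c2"), list("g1", "g2"))
  cp <- mk_scored_pairs(c("m1", "m2"), c("c1", "c2"), "circRNA",
                        c(0.9, 0.2), c(0.01, 0.002), s_enrichmre = c(0.001, 0.04))
  fc <- c(c1 = 3, c2 = -1)
  mir <- c(m1 = 8, m2 = 3); te <- c(c1 = 9, c2 = 4)
  enrich <- data.frame(mirna_id = c("m1", "m2"), es = c(0.9, 0.4),
                       pvalue = c(0.001, 0.2), s_enrichsg = c(0.002, 0.2),
                       stringsAsFactors = FALSE)
  sg <- data.frame(mirna_id = c("m1", "m2"), mrna_id = c("g1", "g2"),
                   sg = c(0.9, 0.1), stringsAsFactors = FALSE)
  rows <- compute_sponge_scores(cp, fc, mir, te, enrich, eligible, sg)
  expect_equal(rows$ss, c(1, 0))  # m1-c1 dominates every criterion
  expect_equal(rows$condition, c("condition_2", "condition_1"))
  expect_equal(rows$n_mrna_targets, c(1L, 1L))
  expect_equal(rows$mean_sg_of_targets, c(0.9, 0.1))

  X <- cbind(cp$s_affinity, cp$s_nbmre, unname(mir[c("m1", "m2")]),
             unname(te[c("c1", "c2")]), abs(unname(fc[c("c1", "c2")])),
             enrich$s_enrichsg, cp$s_enrichmre)
  expect_equal(rows$ss,
               topsis_oracle(X, c(rep("benefit", 5), "cost", "cost")),
               tolerance = 1e-12)
})

test_that("ranks are dense, tie-broken lexicographically and stratified", {
  rows <- data.frame(
    mirna_id = c("m2", "m1", "m1"), circ_id = c("c1", "c2", "c1"),
    s_affinity = 0.5, s_nbmre = 0.01, s_enrichmre = 0.01,
    s_fc_circ = c(2, -1, 3), s_mirexpr = 5, s_targetexpr_circ = 6,
    s_enrichsg = 0.05, ss = c(0.5, 0.5, 0.9),
    condition = c("condition_2", "condition_1", "condition_2"),
    n_mrna_targets = 1L, mean_sg_of_targets = 0.4, mrna_target_list = "g1",
    stringsAsFactors = FALSE)
  m <- assemble_score_matrix(rows)
  expect_equal(names(m), spongescan:::score_matrix_columns)
  expect_equal(m$rank_global, 1:3)
  # tie at 0.5 broken by (mirna_id, circ_id): m1-c2 before m2-c1
  expect_equal(paste(m$mirna_id, m$circ_id),
               c("m1 c1", "m1 c2", "m2 c1"))
  # strata partition the rows; within-stratum ranks are 1..k
  expect_equal(sum(m$condition == "condition_1") + sum(m$condition == "condition_2"),
               nrow(m))
  for (cond in unique(m$condition)) {
    expect_equal(sort(m$rank_in_condition[m$condition == cond]),
                 seq_len(sum(m$condition == cond)))
  }
})

test_that("the assembled pipeline is deterministic given inputs and seed", {
  fx <- generate_fixture(small_fixture_config(seed = 8))
  r1 <- run_pipeline(fx$bundle, sponge_config(seed = 5, nperm = 300))
  r2 <- run_pipeline(fx$bundle, sponge_config(seed = 5, nperm = 300))
  expect_identical(r1$score_matrix, r2$score_matrix)
})
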