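mk_mirna <- function(values, ids = sprintf("hsa-miR-%d", seq_len(nrow(values)))) {
  dimnames(values) <- list(ids, sprintf("S%d", seq_len(ncol(values))))
  expression_matrix(values, "miRNA")
}

test_that("pooled Q1 cutoff and strict thresholds follow the stated rule", {
  # 2 miRNAs x 4 samples: pooled Q1 of {1..8} = 2.75; miRNA-2 above in 4/4
  m <- mk_mirna(rbind(1:4, 5:8))
  res <- filter_mirnas(m)
  expect_equal(res$cutoff, 2.75)
  expect_equal(res$kept_mirnas, "hsa-miR-2")

  # exactly 90% above the cutoff is NOT enough (strict inequality)
  vals <- rbind(c(rep(10, 9), 0.1), rep(0.2, 10))  # pooled Q1 = 0.2 area
  m2 <- mk_mirna(vals)
  res2 <- filter_mirnas(m2)
  cutoff <- res2$cutoff
  expect_equal(sum(vals[1, ] > cutoff), 9L)  # 9/10 = 0.90 exactly
  expect_false("hsa-miR-1" %in% res2$kept_mirnas)

  # all-zero miRNA excluded regardless of the cutoff
  m3 <- mk_mirna(rbind(rep(0, 4), c(5, 6, 7, 8)))
  expect_false("hsa-miR-1" %in% filter_mirnas(m3)$kept_mirnas)
})

test_that("pooled Q1 matches a brute-force type-7 quantile oracle", {
  set.seed(11)
  for (i in 1:20) {
    m <- mk_mirna(matrix(round(rexp(40, 0.3), 3), 5, 8))
    expect_equal(filter_mirnas(m)$cutoff,
                 quantile_type7_oracle(as.numeric(m), 0.25), tolerance = 1e-12)
  }
})

test_that("signature input skips the sufficiency filter", {
  sig <- mirna_signature(c("hsa-miR-1" = 5.1, "hsa-miR-2" = 0.01))
  res <- filter_mirnas(sig)
  expect_true(res$skipped)
  expect_equal(res$kept_mirnas, names(sig))
})

test_that("direction signs come from the fold-change sign", {
  d <- split_by_direction(c(a = 1.3, b = -0.2, c = 0))
  expect_equal(d, c(a = 1L, b = -1L, c = 0L))
})

mk_pairs <- function(mirna, target, type) {
  data.frame(mirna_id = mirna, target_id = target, target_type = type,
             stringsAsFactors = FALSE)
}

test_that("sponge prerequisites keep only complete, co-directional pairs", {
  kept <- list(kept_mirnas = c("m1", "m2"))
  directions <- c(c1 = 1L, c2 = 0L, g1 = 1L, g2 = -1L, g3 = 1L)
  circ <- mk_pairs(c("m1", "m1", "m2", "m3"), c("c1", "c2", "c1", "c1"), "circRNA")
  mrna <- mk_pairs(c("m1", "m1", "m3"), c("g1", "g2", "g3"), "mRNA")
  res <- apply_sponge_prerequisites(circ, mrna, kept, directions)
  # m1-c1 kept with the co-directional (+1) mRNA only; m1-c2 dropped (dir 0);
  # m2-c1 dropped (no mRNA targets); m3 dropped (not kept)
  expect_equal(nrow(res), 1L)
  expect_equal(res$mirna_id, "m1")
  expect_equal(res$circ_id, "c1")
  expect_equal(res$mrna_ids[[1L]], "g1")
})

test_that("prerequisites equal a brute-force triple loop on random instances", {
  set.seed(21)
  for (rep in 1:10) {
    mirnas <- sprintf("m%d", 1:6); circs <- sprintf("c%d", 1:6); genes <- sprintf("g%d", 1:8)
    circ <- unique(mk_pairs(sample(mirnas, 12, TRUE), sample(circs, 12, TRUE), "circRNA"))
    mrna <- unique(mk_pairs(sample(mirnas, 12, TRUE), sample(genes, 12, TRUE), "mRNA"))
    kept <- list(kept_mirnas = sample(mirnas, 4))
    directions <- setNames(sample(c(-1L, 0L, 1L), 14, TRUE), c(circs, genes))
    res <- apply_sponge_prerequisites(circ, mrna, kept, directions)

    expected <- list()
    for (i in seq_len(nrow(circ))) {
      m <- circ$mirna_id[i]; c_ <- circ$target_id[i]
      if (!m %in% kept$kept_mirnas || directions[c_] == 0L) next
      hits <- character(0)
      for (j in seq_len(nrow(mrna))) {
        if (mrna$mirna_id[j] == m && directions[mrna$target_id[j]] == directions[c_] &&
              directions[mrna$target_id[j]] != 0L) {
          hits <- c(hits, mrna$target_id[j])
        }
      }
      if (length(hits)) expected[[paste(m, c_)]] <- sort(unique(hits))
    }
    expect_equal(nrow(res), length(expected))
    if (nrow(res)) {
      got <- setNames(res$mrna_ids, paste(res$mirna_id, res$circ_id))
      expect_equal(lapply(got[sort(names(got))], identity),
                   expected[sort(names(expected))], ignore_attr = TRUE)
    }
  }
})

test_that("enlarging the kept-miRNA set can only enlarge the eligible set", {
  set.seed(31)
  mirnas <- sprintf("m%d", 1:5)
  circ <- unique(mk_pairs(sample(mirnas, 10, TRUE), sample(sprintf("c%d", 1:5), 10, TRUE), "circRNA"))
  mrna <- unique(mk_pairs(sample(mirnas, 10, TRUE), sample(sprintf("g%d", 1:5), 10, TRUE), "mRNA"))
  directions <- setNames(sample(c(-1L, 1L), 10, TRUE),
                         c(sprintf("c%d", 1:5), sprintf("g%d", 1:5)))
  small <- apply_sponge_prerequisites(circ, mrna, list(kept_mirnas = mirnas[1:2]), directions)
  large <- apply_sponge_prerequisites(circ, mrna, list(kept_mirnas = mirnas), directions)
  expect_true(all(paste(small$mirna_id, small$circ_id) %in%
                    paste(large$mirna_id, large$circ_id)))
})
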