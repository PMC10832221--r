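# Seeded synthetic input bundles with planted sponge mechanisms. The
# generator emulates the shapes of real inputs: log2-scale expression with
# Gaussian noise, per-MRE site tables with TargetScan-like negative context
# scores, spliced lengths, a validated-interaction table and (optionally)
# written CSV files. It does NOT emulate count-level noise, normalisation
# artefacts or correlated co-expression structure.

#' Synthetic fixture configuration
#'
#' Defaults state the reference simulation: 200 circRNAs, 500 mRNAs,
#' 50 miRNAs, 6 + 6 samples, one planted mechanism at full strength.
#'
#' @param n_circ,n_mrna,n_mirna feature counts (all >= 1).
#' @param n_samples_per_condition samples per condition (>= 3).
#' @param n_planted number of planted sponge mechanisms.
#' @param planted_strength in (0, 1]: scales the planted affinity advantage,
#'   MRE count and fold change; 1 = constructed dominance, 0 = background.
#' @param background_site_rate probability that a random (miRNA, target)
#'   pair carries predicted sites (default 0.02).
#' @param noise_sd Gaussian noise SD on the log2 scale (default 0.5).
#' @param n_mrna_per_planted co-regulated mRNA targets per planted mechanism.
#' @param seed integer RNG seed.
#' @return validated config list of class `sponge_fixture_config`.
#' @export
fixture_config <- function(n_circ = 200L, n_mrna = 500L, n_mirna = 50L,
                           n_samples_per_condition = 6L, n_planted = 1L,
                           planted_strength = 1, background_site_rate = 0.02,
                           noise_sd = 0.5, n_mrna_per_planted = 5L, seed = 1L) {
  cfg <- list(n_circ = as.integer(n_circ), n_mrna = as.integer(n_mrna),
              n_mirna = as.integer(n_mirna),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              n_planted = as.integer(n_planted),
              planted_strength = as.numeric(planted_strength),
              background_site_rate = as.numeric(background_site_rate),
              noise_sd = as.numeric(noise_sd),
              n_mrna_per_planted = as.integer(n_mrna_per_planted),
              seed = as.integer(seed))
  if (any(vapply(cfg[c("n_circ", "n_mrna", "n_mirna", "n_planted")],
                 function(x) x < 1L, logical(1L)))) {
    sponge_abort("feature and planted counts must be >= 1", "config_error")
  }
  if (cfg$n_samples_per_condition < 3L) {
    sponge_abort("n_samples_per_condition must be >= 3 (minimum 3 samples per condition)",
                 "config_error")
  }
  if (cfg$planted_strength < 0 || cfg$planted_strength > 1) {
    sponge_abort("planted_strength must lie in [0, 1]", "config_error")
  }
  if (cfg$n_planted > min(cfg$n_mirna, cfg$n_circ)) {
    sponge_abort("n_planted exceeds the number of available miRNAs/circRNAs",
                 "config_error")
  }
  structure(cfg, class = "sponge_fixture_config")
}

#' Generate a synthetic input bundle with planted sponge mechanisms
#'
#' Planted mechanisms place a strongly up-regulated circRNA (condition_2), a
#' well-expressed miRNA, many strong (most-negative-score) MREs on the
#' circRNA, and co-up-regulated mRNA targets; decoys get sparse weak sites.
#' The validated table contains the planted pairs (3 CLIP-seq, 3
#' degradome-seq experiments each) plus random background pairs with mixed
#' evidence. Deterministic given the seed.
#'
#' @param cfg a [fixture_config()].
#' @return list with `bundle` (class `sponge_bundle`) and `truth`
#'   (data.frame of planted `mirna_id`, `circ_id`, `mrna_ids`, `direction`).
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  if (!inherits(cfg, "sponge_fixture_config")) cfg <- do.call(fixture_config, cfg)
  set.seed(cfg$seed)
  st <- cfg$planted_strength

  circ_ids <- sprintf("hsa_circ_%07d", seq_len(cfg$n_circ))
  mrna_ids <- sprintf("GENE%04d", seq_len(cfg$n_mrna))
  mirna_ids <- sprintf("hsa-miR-%d-5p", 100L + seq_len(cfg$n_mirna))
  nsc <- cfg$n_samples_per_condition
  samples <- c(sprintf("ctrl_%02d", seq_len(nsc)), sprintf("case_%02d", seq_len(nsc)))
  conditions <- rep(c("condition_1", "condition_2"), each = nsc)

  planted_mirna <- mirna_ids[seq_len(cfg$n_planted)]
  planted_circ <- circ_ids[seq_len(cfg$n_planted)]
  planted_mrnas <- lapply(seq_len(cfg$n_planted), function(j) {
    mrna_ids[(j - 1L) * cfg$n_mrna_per_planted + seq_len(cfg$n_mrna_per_planted)]
  })

  make_expr <- function(ids, baseline, effect, type) {
    n <- length(ids)
    m <- matrix(stats::rnorm(n * 2L * nsc, sd = cfg$noise_sd), nrow = n) +
      baseline + cbind(matrix(0, n, nsc), matrix(effect, n, nsc))
    dimnames(m) <- list(ids, samples)
    expression_matrix(m, type)
  }

  # every decoy circRNA/mRNA is "differentially expressed" with a random
  # direction, as real inputs are pre-restricted to DE features
  circ_base <- stats::runif(cfg$n_circ, 2, 8)
  circ_eff <- sample(c(-1, 1), cfg$n_circ, replace = TRUE) * stats::runif(cfg$n_circ, 0.8, 2)
  mrna_base <- stats::runif(cfg$n_mrna, 4, 10)
  mrna_eff <- sample(c(-1, 1), cfg$n_mrna, replace = TRUE) * stats::runif(cfg$n_mrna, 0.8, 2)
  mirna_base <- stats::runif(cfg$n_mirna, 2, 9)

  for (j in seq_len(cfg$n_planted)) {
    circ_base[j] <- 6.5
    circ_eff[j] <- 4 * st + (1 - st) * circ_eff[j]
    mi <- (j - 1L) * cfg$n_mrna_per_planted + seq_len(cfg$n_mrna_per_planted)
    mrna_eff[mi] <- 2 * st + (1 - st) * mrna_eff[mi]
    mirna_base[j] <- 9.5 * st + (1 - st) * mirna_base[j]
  }

  circ_expr <- make_expr(circ_ids, circ_base, circ_eff, "circRNA")
  mrna_expr <- make_expr(mrna_ids, mrna_base, mrna_eff, "mRNA")
  mirna_expr <- make_expr(mirna_ids, mirna_base, 0, "miRNA")
  annotation <- sample_annotation(samples, conditions)

  lengths <- circ_length_table(circ_ids,
                               round(stats::runif(cfg$n_circ, 300, 2000)))

  # background sites: sparse, weak (scores near 0); 1-2 sites per pair
  background_sites <- function(mirnas, targets) {
    hit <- which(matrix(stats::runif(length(mirnas) * length(targets)),
                        length(mirnas)) < cfg$background_site_rate,
                 arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    n_sites <- 1L + stats::rbinom(nrow(hit), 1L, 0.3)
    data.frame(mirna_id = rep(mirnas[hit[, 1L]], n_sites),
               target_id = rep(targets[hit[, 2L]], n_sites),
               score = round(stats::runif(sum(n_sites), -0.35, -0.05), 4),
               stringsAsFactors = FALSE)
  }
  circ_bg <- background_sites(mirna_ids, circ_ids)
  mrna_bg <- background_sites(mirna_ids, mrna_ids)

  planted_circ_sites <- NULL
  planted_mrna_sites <- NULL
  for (j in seq_len(cfg$n_planted)) {
    len <- lengths[planted_circ[j]]
    k <- max(1L, as.integer(round(st * len / 80)))
    planted_circ_sites <- rbind(planted_circ_sites, data.frame(
      mirna_id = planted_mirna[j], target_id = planted_circ[j],
      score = round(-0.25 - 0.45 * st + stats::runif(k, -0.03, 0.03), 4),
      stringsAsFactors = FALSE))
    for (g in planted_mrnas[[j]]) {
      km <- max(1L, as.integer(round(1 + 3 * st)))
      planted_mrna_sites <- rbind(planted_mrna_sites, data.frame(
        mirna_id = planted_mirna[j], target_id = g,
        score = round(-0.2 - 0.35 * st + stats::runif(km, -0.03, 0.03), 4),
        stringsAsFactors = FALSE))
    }
  }

  dedup_sites <- function(bg, planted, type) {
    if (!is.null(planted) && !is.null(bg)) {
      # planted pairs replace any colliding background pair
      pkey <- unique(paste(planted$mirna_id, planted$target_id, sep = "\r"))
      bgk <- paste(bg$mirna_id, bg$target_id, sep = "\r")
      bg <- bg[!bgk %in% pkey, , drop = FALSE]
    }
    df <- rbind(planted, bg)
    if (is.null(df) || nrow(df) == 0L) {
      sponge_abort("background_site_rate too low: no sites generated", "config_error")
    }
    site_table(df$mirna_id, df$target_id, df$score, target_type = type)
  }
  circ_sites <- dedup_sites(circ_bg, planted_circ_sites, "circRNA")
  mrna_sites <- dedup_sites(mrna_bg, planted_mrna_sites, "mRNA")

  # validated interactions: planted pairs with solid evidence plus random
  # predicted background pairs with mixed evidence for a realistic cutoff
  circ_pairs <- unique(circ_sites[, c("mirna_id", "target_id")])
  pkey <- paste(planted_mirna, planted_circ, sep = "\r")
  bg_pairs <- circ_pairs[!paste(circ_pairs$mirna_id, circ_pairs$target_id, sep = "\r") %in% pkey, ,
                         drop = FALSE]
  n_val <- min(30L, nrow(bg_pairs))
  picked <- if (n_val > 0L) bg_pairs[sample.int(nrow(bg_pairs), n_val), , drop = FALSE] else NULL
  validated <- validated_table(
    c(planted_mirna, picked$mirna_id),
    c(planted_circ, picked$target_id),
    c(rep(3L, cfg$n_planted), sample(0:4, n_val, replace = TRUE)),
    c(rep(3L, cfg$n_planted), sample(0:4, n_val, replace = TRUE)))

  bundle <- structure(list(circ_expr = circ_expr, mrna_expr = mrna_expr,
                           mirna_expr = mirna_expr, signature = NULL,
                           annotation = annotation, mirna_annotation = annotation,
                           circ_sites = circ_sites, mrna_sites = mrna_sites,
                           circ_lengths = lengths, validated = validated),
                      class = "sponge_bundle")
  truth <- data.frame(mirna_id = planted_mirna, circ_id = planted_circ,
                      direction = rep(1L, cfg$n_planted),
                      stringsAsFactors = FALSE)
  truth$mrna_ids <- I(planted_mrnas)
  list(bundle = bundle, truth = truth)
}

#' Write a synthetic bundle as a CSV file set
#'
#' Produces the exact on-disk layout [load_input_bundle()] expects, plus a
#' `truth.csv` listing the planted mechanisms.
#'
#' @param fixture result of [generate_fixture()].
#' @param dir output directory (created if absent).
#' @return named list of written paths (suitable for [load_input_bundle()]).
#' @export
write_fixture_csv <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- fixture$bundle
  p <- list()
  wexpr <- function(m, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    df <- data.frame(feature = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE]),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  p$circ_expr <- wexpr(b$circ_expr, "circ_expr")
  p$mrna_expr <- wexpr(b$mrna_expr, "mrna_expr")
  p$mirna_expr <- wexpr(b$mirna_expr, "mirna_expr")
  p$annotation <- file.path(dir, "annotation.csv")
  utils::write.csv(data.frame(samples = b$annotation$sample_id,
                              conditions = b$annotation$condition),
                   p$annotation, row.names = FALSE, quote = FALSE)
  wsites <- function(s, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(data.frame(mirna = s$mirna_id, target = s$target_id,
                                target_type = s$target_type, score = s$score,
                                site = s$site),
                     path, row.names = FALSE, quote = FALSE)
    path
  }
  p$circ_sites <- wsites(b$circ_sites, "circ_sites")
  p$mrna_sites <- wsites(b$mrna_sites, "mrna_sites")
  p$circ_lengths <- file.path(dir, "circ_lengths.csv")
  utils::write.csv(data.frame(circ = names(b$circ_lengths),
                              length = as.integer(b$circ_lengths)),
                   p$circ_lengths, row.names = FALSE, quote = FALSE)
  p$validated <- file.path(dir, "validated.csv")
  utils::write.csv(data.frame(mirna = b$validated$mirna_id,
                              circ = b$validated$circ_id,
                              n_clipseq = b$validated$n_clipseq,
                              n_degradome = b$validated$n_degradome),
                   p$validated, row.names = FALSE, quote = FALSE)
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(data.frame(mirna = fixture$truth$mirna_id,
                              circ = fixture$truth$circ_id,
                              direction = fixture$truth$direction,
                              mrnas = vapply(fixture$truth$mrna_ids,
                                             paste, character(1L), collapse = ";")),
                   truth_path, row.names = FALSE, quote = FALSE)
  p
}
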