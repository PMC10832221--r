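# Independent reference implementations ("oracles"), deliberately coded
# step-by-step with plain loops, sharing no code path with the package.

options(spongescan.quiet = TRUE)

topsis_oracle <- function(X, dirs, w = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, p)
  w <- w / sum(w)
  V <- matrix(0, n, p)
  for (j in seq_len(p)) {
    nrm <- sqrt(sum(X[, j]^2))
    for (i in seq_len(n)) V[i, j] <- if (nrm == 0) 0 else X[i, j] / nrm * w[j]
  }
  ideal <- numeric(p); anti <- numeric(p)
  for (j in seq_len(p)) {
    if (dirs[j] == "benefit") { ideal[j] <- max(V[, j]); anti[j] <- min(V[, j]) }
    else { ideal[j] <- min(V[, j]); anti[j] <- max(V[, j]) }
  }
  C <- numeric(n)
  for (i in seq_len(n)) {
    dp <- sqrt(sum((V[i, ] - ideal)^2))
    dn <- sqrt(sum((V[i, ] - anti)^2))
    C[i] <- if (dp + dn == 0) 0.5 else dn / (dp + dn)
  }
  C
}

bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  cur <- 1
  for (i in n:1) {
    cur <- min(cur, ranked[i] * n / i)
    adj[i] <- cur
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

binom_tail_oracle <- function(k, N, p) {
  if (k <= 0) return(1)
  if (k > N) return(0)
  s <- 0
  for (i in k:N) s <- s + choose(N, i) * p^i * (1 - p)^(N - i)
  s
}

quantile_type7_oracle <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  if (lo >= n) return(xs[n])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

# full running-sum walk over every list position (the package computes the
# maximum from hit positions only)
gsea_es_oracle <- function(positions, weights) {
  n <- length(weights)
  k <- length(positions)
  W <- sum(abs(weights[positions]))
  running <- 0
  best <- -Inf
  for (i in seq_len(n)) {
    if (i %in% positions) {
      running <- running + if (W == 0) 1 / k else abs(weights[i]) / W
    } else {
      running <- running - 1 / (n - k)
    }
    best <- max(best, running)
  }
  best
}

hyper_tail_oracle <- function(k, set_size, background_size, query_size) {
  s <- 0
  for (j in seq(k, min(set_size, query_size))) {
    s <- s + choose(set_size, j) * choose(background_size - set_size, query_size - j)
  }
  s / choose(background_size, query_size)
}

# --- toy CSV bundle ---------------------------------------------------------

write_toy_bundle <- function(dir = tempfile("bundle"), annotation_split = c(3L, 3L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(99)
  samples <- sprintf("S%d", 1:6)
  circ <- sprintf("hsa_circ_%07d", 1:5)
  mrna <- sprintf("G%d", 1:8)
  mirna <- c("hsa-miR-1-5p", "hsa-miR-2-3p", "hsa-miR-3-5p", "hsa-let-7a")
  wexpr <- function(ids, file) {
    m <- matrix(round(runif(length(ids) * 6, 1, 10), 3), nrow = length(ids),
                dimnames = list(ids, samples))
    df <- data.frame(id = ids, m, check.names = FALSE)
    write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
  }
  wexpr(circ, "circ.csv"); wexpr(mrna, "mrna.csv"); wexpr(mirna, "mirna.csv")
  conds <- c(rep("condition_1", annotation_split[1L]),
             rep("condition_2", annotation_split[2L]))
  write.csv(data.frame(samples = samples[seq_along(conds)], conditions = conds),
            file.path(dir, "annotation.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(mirna = c(mirna[1], mirna[1], mirna[2], mirna[3]),
                       target = c(circ[1], circ[1], circ[2], circ[1]),
                       score = c(-0.4, -0.1, -0.3, -0.2),
                       site = c(1L, 2L, 1L, 1L)),
            file.path(dir, "circ_sites.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(mirna = c(mirna[1], mirna[2], mirna[3], mirna[4]),
                       target = c(mrna[1], mrna[2], mrna[3], mrna[4]),
                       score = c(-0.5, -0.2, -0.3, -0.25)),
            file.path(dir, "mrna_sites.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(circ = circ, length = c(500L, 800L, 1200L, 400L, 1500L)),
            file.path(dir, "circ_lengths.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(mirna = mirna[1:2], circ = circ[1:2],
                       n_clipseq = c(3L, 2L), n_degradome = c(2L, 1L)),
            file.path(dir, "validated.csv"), row.names = FALSE, quote = FALSE)
  list(circ_expr = file.path(dir, "circ.csv"),
       mrna_expr = file.path(dir, "mrna.csv"),
       mirna_expr = file.path(dir, "mirna.csv"),
       annotation = file.path(dir, "annotation.csv"),
       circ_sites = file.path(dir, "circ_sites.csv"),
       mrna_sites = file.path(dir, "mrna_sites.csv"),
       circ_lengths = file.path(dir, "circ_lengths.csv"),
       validated = file.path(dir, "validated.csv"))
}

# small config used where full scale is unnecessary
small_fixture_config <- function(seed = 1L, ...) {
  fixture_config(n_circ = 30L, n_mrna = 60L, n_mirna = 10L,
                 n_samples_per_condition = 4L, background_site_rate = 0.08,
                 seed = seed, ...)
}
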