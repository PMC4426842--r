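# Unit checks of the per-replica Gibbs updates and the interacting loop.

test_that("site conditional: uninformative PPM gives P(z=1) = gamma^K with uniform starts", {
  seqs <- motif_seqs("ACGTTGCCA")   # L = 9
  K <- 3L; gam <- 0.7
  lr <- matrix(0, 4, K)             # Theta identical to theta0
  cond <- rpmotif:::site_conditional(seqs$codes[[1]], 9L, K, lr, gam)
  expect_equal(cond$p0, 1 - gam^K, tolerance = 1e-12)
  expect_equal(cond$pu, rep(gam^K / (2 * 7), 2 * 7), tolerance = 1e-12)
  expect_equal(cond$p0 + sum(cond$pu), 1, tolerance = 1e-12)
})

test_that("site draws match the exhaustively enumerated conditional", {
  seqs <- motif_seqs("GGTACG")      # L = 6, K = 3: 8 starts + absence
  K <- 3L; gam <- 0.5
  pp <- example_ppm("GTA", strength = 0.7)
  th0 <- rep(0.25, 4)
  lr <- log(unclass(pp)) - log(th0)
  cond <- rpmotif:::site_conditional(seqs$codes[[1]], 6L, K, lr, gam)
  probs <- c(cond$p0, cond$pu)
  set.seed(42)
  draws <- replicate(2e4, {
    s <- rpmotif:::sample_site(seqs$codes[[1]], 6L, K, lr, gam)
    if (s$z == 0L) 1L else 1L + match(s$u, cond$starts)
  })
  obs <- tabulate(draws, nbins = length(probs))
  expect_gt(pooled_chisq_p(obs, probs), 0.01)
})

test_that("gamma = 0 forbids occupancy and K > L forces absence", {
  seqs <- motif_seqs("ACGTAC")
  lr <- matrix(0, 4, 3)
  set.seed(1)
  for (r in 1:20)
    expect_identical(rpmotif:::sample_site(seqs$codes[[1]], 6L, 3L, lr, 0)$z, 0L)
  s <- rpmotif:::sample_site(seqs$codes[[1]], 6L, 7L, matrix(0, 4, 7), 0.9)
  expect_identical(s$z, 0L)
})

test_that("background draw is the conjugate Dirichlet posterior", {
  set.seed(8)
  d <- rpmotif:::sample_background(c(1e6, 0, 0, 0), rep(1, 4))
  expect_gt(d[1], 0.99)
  expect_equal(sum(d), 1, tolerance = 1e-12)
  # prior sampling: empirical mean of theta_A over draws ~ Dirichlet(1,1,1,1)
  m <- rowMeans(replicate(4e3, rpmotif:::sample_background(rep(0, 4), rep(1, 4))))
  se <- sqrt(0.25 * 0.75 / 5) / sqrt(4e3)     # sd of Dirichlet(1,..) coordinate
  expect_true(all(abs(m - 0.25) < 3 * se))
})

test_that("PPM update at beta = 0 is conjugate; at beta > 0 columns still sum to 1", {
  counts <- cbind(c(7, 1, 1, 1), c(2, 2, 3, 3))
  set.seed(10)
  draws <- replicate(4e3, rpmotif:::sample_ppm_repulsive(counts, 1, list(), 0, 0.3))
  m <- apply(draws, c(1, 2), mean)
  expected <- sweep(counts + 1, 2, colSums(counts + 1), "/")
  sds <- sqrt(expected * (1 - expected) / (colSums(counts)[col(expected)] + 5))
  expect_true(all(abs(m - expected) < 3 * sds / sqrt(4e3) + 3e-3))
  # repelled draw stays on the simplex
  other <- list(random_ppm(2))
  cur <- random_ppm(2)
  rep_draw <- rpmotif:::sample_ppm_repulsive(counts, 1, other, 50, 0.3,
                                             current_ppm = cur)
  expect_equal(unname(colSums(rep_draw)), c(1, 1), tolerance = 1e-9)
  expect_true(all(rep_draw >= 0))
})

test_that("repelled PPM draws concentrate away from the other replica", {
  # strong repulsion versus no repulsion, same flat counts: the repelled
  # draw should sit farther from the occupied mode on average
  counts <- matrix(2, 4, 3)
  anchor <- list(ppm(matrix(c(0.85, 0.05, 0.05, 0.05), 4, 3)))
  set.seed(12)
  cur <- random_ppm(3)
  d_rep <- replicate(200, {
    cur <<- rpmotif:::sample_ppm_repulsive(counts, 1, anchor, 80, 0.3,
                                           current_ppm = cur)
    ppm_dissimilarity(cur, anchor[[1]], 0.3)
  })
  d_free <- replicate(200, {
    p <- rpmotif:::sample_ppm_repulsive(counts, 1, list(), 0, 0.3)
    ppm_dissimilarity(p, anchor[[1]], 0.3)
  })
  expect_gt(mean(d_rep[101:200]), mean(d_free))
})

test_that("width move respects the prior support and leaves invalid moves rejected", {
  seqs <- motif_seqs(c("ACGTTGACCAGT", "TTGCCAGTAGGA"))
  ctl <- rpmcmc_control(kmin = 2L, kmax = 3L, gamma = 0.5)
  st <- replica_state(c(1L, 1L), c(4L, 2L), 3L, random_ppm(3), rep(0.25, 4))
  set.seed(3)
  for (r in 1:50) {
    mv <- rpmotif:::propose_length_move(seqs, st, ctl)
    expect_true(mv$state$K >= 2L && mv$state$K <= 3L)
    rpmotif:::check_state(seqs, mv$state)
    st <- mv$state
  }
})

test_that("width posterior on a tiny instance matches exhaustive enumeration", {
  # one 8-bp sequence, widths 2..3: enumerate p(K) by integrating the
  # conjugate Dirichlet terms over every (z, u, K) configuration
  seqs <- motif_seqs("ACGGTCAG")
  gam <- 0.6
  lp_K <- vapply(2:3, function(K) {
    vs <- valid_starts(8L, K)
    lw <- vapply(0:length(vs), function(oi) {
      if (oi == 0) {
        log(1 - gam^K) + lmvbeta(1 + seqs$total_counts) + K * lmvbeta(rep(1, 4))
      } else {
        u <- vs[oi]
        kmer <- seqs$codes[[1]][u + 0:(K - 1)]
        m <- matrix(0, 4, K)
        for (k in seq_len(K)) m[kmer[k], k] <- m[kmer[k], k] + 1
        K * log(gam) - log(2 * (8 - K + 1)) +
          lmvbeta(1 + seqs$total_counts - tabulate(kmer, 4)) +
          sum(vapply(seq_len(K), function(k) lmvbeta(1 + m[, k]), numeric(1)))
      }
    }, numeric(1))
    # flat width prior cancels across K; the Dirichlet prior normalisers
    # contribute 1/B(1,1,1,1) per motif column
    log(sum(exp(lw))) - K * lmvbeta(rep(1, 4))
  }, numeric(1))
  pK <- exp(lp_K - max(lp_K)); pK <- pK / sum(pK)

  ctl <- rpmcmc_control(gamma = gam, kmin = 2L, kmax = 3L, replicas = 1L,
                        iterations = 30100L, burnin = 100L, beta_policy = "zero")
  fit <- rpmcmc(seqs, ctl, seed = 31)
  ks <- vapply(fit$samples, function(s) s$replicas[[1]]$K, integer(1))
  est <- mean(ks == 2L)
  # batch-means standard error over 30 batches of 1000
  bm <- vapply(1:30, function(b) mean(ks[((b - 1) * 1000 + 1):(b * 1000)] == 2L),
               numeric(1))
  se <- sd(bm) / sqrt(30)
  expect_lt(abs(est - pK[1]), 4 * se)
})

test_that("the run is reproducible and keeps the configured number of ensembles", {
  seqs <- motif_seqs(c("ACGTTGACCAGTACCGT", "TTGCCAGTAGGATTTGC", "CCATGGTACCATGAGTC"))
  ctl <- rpmcmc_control(kmin = 4L, kmax = 6L, replicas = 3L, iterations = 30L,
                        burnin = 5L)
  f1 <- rpmcmc(seqs, ctl, seed = 99)
  f2 <- rpmcmc(seqs, ctl, seed = 99)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$samples, f2$samples)
  expect_length(f1$samples, 25L)
  # every kept sample satisfies the state invariants
  for (s in f1$samples) for (r in s$replicas) {
    rpmotif:::check_state(seqs, r)
    expect_true(r$K >= 4L && r$K <= 6L)
    expect_equal(unname(colSums(r$ppm)), rep(1, r$K), tolerance = 1e-9)
    expect_equal(sum(r$theta0), 1, tolerance = 1e-9)
  }
  expect_error(rpmcmc(character(0), ctl), "empty|non-empty|length")
})

test_that("sequences shorter than the motif width stay unoccupied", {
  seqs <- motif_seqs(c("ACGTACGTACGT", "ACG"))
  ctl <- rpmcmc_control(kmin = 6L, kmax = 6L, replicas = 1L, iterations = 20L,
                        burnin = 0L, beta_policy = "zero")
  fit <- rpmcmc(seqs, ctl, seed = 5)
  for (s in fit$samples) expect_identical(s$replicas[[1]]$z[2], 0L)
})
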