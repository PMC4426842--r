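test_that("ZOOPS log-likelihood matches the hand-evaluated two-base example", {
  seqs <- motif_seqs("AC")        # concatenated: ACGT
  st <- replica_state(z = 1L, u = 1L, K = 2L,
                      ppm = ppm(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))),
                      theta0 = rep(0.25, 4))
  expect_equal(motif_loglik(seqs, st), 4 * log(0.25) + 2 * log(4), tolerance = 1e-12)
})

test_that("likelihood reduces to all-background when no motif or PPM equals background", {
  set.seed(3)
  seqs <- motif_seqs(c("ACGTTGAC", "TTGCCAGT", "AAACGTGG"))
  th0 <- c(0.3, 0.25, 0.2, 0.25)
  bg_only <- sum(seqs$total_counts * log(th0))
  st0 <- replica_state(z = rep(0L, 3), u = rep(NA_integer_, 3), K = 3L,
                       ppm = random_ppm(3), theta0 = th0)
  expect_equal(motif_loglik(seqs, st0), bg_only, tolerance = 1e-12)
  # PPM identical to background: ratio factor is 1 for any occupancy
  st1 <- replica_state(z = c(1L, 1L, 0L), u = c(2L, 11L, NA), K = 3L,
                       ppm = ppm(matrix(th0, 4, 3)), theta0 = th0)
  expect_equal(motif_loglik(seqs, st1), bg_only, tolerance = 1e-9 * abs(bg_only))
})

test_that("count-based likelihood equals the naive per-position oracle", {
  set.seed(11)
  for (case in 1:20) {
    n <- sample(2:5, 1)
    L <- sample(6:20, 1)
    K <- sample(2:4, 1)
    bases <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    seqs <- motif_seqs(bases)
    z <- rbinom(n, 1, 0.6)
    u <- rep(NA_integer_, n)
    for (i in which(z == 1)) {
      vs <- valid_starts(L, K)
      u[i] <- vs[sample.int(length(vs), 1)]
    }
    g <- rgamma(4, 2); th0 <- g / sum(g)
    pp <- random_ppm(K)
    st <- replica_state(z, u, K, pp, th0)
    expect_equal(motif_loglik(seqs, st),
                 naive_loglik(bases, z, u, unclass(pp), th0),
                 tolerance = 1e-9)
  }
})

test_that("log-likelihood is invariant under permutation of sequence order", {
  set.seed(5)
  bases <- c("ACGTTGACCA", "TTGCCAGTAG", "AAACGTGGTT", "CATCATCATG")
  z <- c(1L, 0L, 1L, 1L); u <- c(3L, NA, 12L, 1L)
  pp <- random_ppm(3); th0 <- rep(0.25, 4)
  ll1 <- motif_loglik(motif_seqs(bases), replica_state(z, u, 3L, pp, th0))
  perm <- c(3, 1, 4, 2)
  ll2 <- motif_loglik(motif_seqs(bases[perm]),
                      replica_state(z[perm], u[perm], 3L, pp, th0))
  expect_equal(ll1, ll2, tolerance = 1e-12)
})

test_that("sufficient statistics tally occupied motif columns and net background", {
  seqs <- motif_seqs(c("ACAA", "ACGG"))    # both carry AC at the start
  st <- replica_state(c(1L, 1L), c(1L, 1L), 2L,
                      ppm(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))), rep(0.25, 4))
  cnt <- motif_counts(seqs, st)
  expect_identical(unname(cnt$motif),
                   matrix(c(2L, 0L, 0L, 0L, 0L, 2L, 0L, 0L), 4, 2))
  expect_equal(unname(colSums(cnt$motif)), c(2, 2))
  expect_equal(cnt$background, as.numeric(seqs$total_counts) - c(2, 2, 0, 0))
  # empty occupancy: zero motif matrix, background = all letters
  st0 <- replica_state(c(0L, 0L), c(NA_integer_, NA_integer_), 2L,
                       ppm(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))), rep(0.25, 4))
  cnt0 <- motif_counts(seqs, st0)
  expect_true(all(cnt0$motif == 0))
  expect_equal(cnt0$background, as.numeric(seqs$total_counts))
})

test_that("log-prior assembles width, occupancy, start-site and Dirichlet terms", {
  seqs <- motif_seqs(c("ACGTTGACCA", "TTGCCAGTAG"))
  ctl <- rpmcmc_control(gamma = 0.6, kmin = 8L, kmax = 15L)
  st <- replica_state(c(1L, 0L), c(2L, NA), 8L, random_ppm(8), rep(0.25, 4))
  # flat Dirichlet priors contribute log Gamma(4) per column and for theta0
  expected <- -log(8) + 8 * log(0.6) + log1p(-0.6^8) - log(2 * (10 - 8 + 1)) +
    9 * lgamma(4)
  expect_equal(motif_log_prior(seqs, st, ctl), expected, tolerance = 1e-12)
  # impossible configurations
  ctl0 <- rpmcmc_control(gamma = 0, kmin = 8L, kmax = 15L)
  expect_identical(motif_log_prior(seqs, st, ctl0), -Inf)
  ctl2 <- rpmcmc_control(kmin = 9L, kmax = 15L)
  expect_identical(motif_log_prior(seqs, st, ctl2), -Inf)
})

test_that("zero probability at a referenced cell gives -Inf, not an error", {
  seqs <- motif_seqs("AC")
  st <- replica_state(1L, 1L, 2L,
                      ppm(cbind(c(0, 1, 0, 0), c(0, 1, 0, 0))),  # P(A at col 1) = 0
                      rep(0.25, 4))
  expect_identical(motif_loglik(seqs, st), -Inf)
})
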