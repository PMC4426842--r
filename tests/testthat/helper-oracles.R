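# Independent oracles used across the test suite.  Each is written directly
# from the model definitions, not from the package internals it checks.

DNA <- c("A", "C", "G", "T")

# Brute-force PPM dissimilarity: enumerate every alignment offset of the
# shorter matrix along the longer one.
brute_dissimilarity <- function(p, q, gap_c) {
  p <- unclass(p); q <- unclass(q)
  if (ncol(p) < ncol(q)) { tmp <- p; p <- q; q <- tmp }
  ks <- ncol(q)
  dk <- ncol(p) - ncol(q)
  fr <- vapply(0:dk, function(o) {
    d <- p[, (o + 1):(o + ks), drop = FALSE] - q
    sqrt(sum(d^2))
  }, numeric(1))
  (min(fr) + gap_c * dk) / ks
}

# Naive per-position evaluation of the ZOOPS likelihood: background
# probability of every letter of every concatenated sequence times the
# motif/background ratio over occupied positions.
naive_loglik <- function(bases, z, u, ppm, theta0) {
  conc <- paste0(bases, reverse_complement(bases))
  ll <- 0
  for (i in seq_along(conc)) {
    code <- match(strsplit(conc[i], "")[[1]], DNA)
    ll <- ll + sum(log(theta0[code]))
    if (z[i] == 1) {
      K <- ncol(ppm)
      for (k in seq_len(K)) {
        s <- code[u[i] + k - 1]
        ll <- ll + log(ppm[s, k]) - log(theta0[s])
      }
    }
  }
  as.numeric(ll)
}

# Random PPM of width K (uniform Dirichlet columns).
random_ppm <- function(K) {
  m <- matrix(rgamma(4 * K, 1), 4, K)
  ppm(sweep(m, 2, colSums(m), "/"))
}

lmvbeta <- function(v) sum(lgamma(v)) - lgamma(sum(v))

# Exhaustive collapsed posterior over (z_i, u_i) at fixed width K with flat
# Dirichlet priors integrated out analytically.  Returns the per-configuration
# probabilities together with the option grid (0 = absent, otherwise the
# index into valid_starts of that sequence).
enumerate_zu_posterior <- function(seqs, K, gamma, alpha = rep(1, 4),
                                   beta_dir = rep(1, 4)) {
  n <- length(seqs)
  vs <- lapply(seq_len(n), function(i) valid_starts(seqs$lengths[i], K))
  grid <- as.matrix(expand.grid(lapply(vs, function(v) 0:length(v))))
  total <- seqs$total_counts
  lw <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    m <- matrix(0, 4, K); occ <- numeric(4); lp <- 0
    for (i in seq_len(n)) {
      oi <- grid[r, i]
      if (oi == 0) {
        lp <- lp + log(1 - gamma^K)
      } else {
        u <- vs[[i]][oi]
        lp <- lp + K * log(gamma) - log(2 * (seqs$lengths[i] - K + 1))
        kmer <- seqs$codes[[i]][u + 0:(K - 1)]
        for (k in seq_len(K)) m[kmer[k], k] <- m[kmer[k], k] + 1
        occ <- occ + tabulate(kmer, 4)
      }
    }
    lw[r] <- lp + lmvbeta(alpha + total - occ) +
      sum(vapply(seq_len(K), function(k) lmvbeta(beta_dir + m[, k]), numeric(1)))
  }
  pr <- exp(lw - max(lw))
  list(prob = pr / sum(pr), grid = grid, starts = vs)
}

# Configuration code (1-based) of a replica state under the enumeration grid.
config_code <- function(state, starts) {
  n <- length(state$z)
  sizes <- vapply(starts, length, integer(1)) + 1L
  code <- 0
  mult <- 1
  for (i in seq_len(n)) {
    oi <- if (state$z[i] == 0L) 0L else match(state$u[i], starts[[i]])
    code <- code + oi * mult
    mult <- mult * sizes[i]
  }
  as.integer(code + 1)
}

config_code_grid <- function(grid) {
  sizes <- apply(grid, 2, max) + 1L
  code <- rep(0, nrow(grid)); mult <- 1
  for (i in seq_len(ncol(grid))) {
    code <- code + grid[, i] * mult
    mult <- mult * sizes[i]
  }
  as.integer(code + 1)
}

# Pooled chi-square goodness-of-fit: cells with expected count below 5 are
# merged into one bucket.
pooled_chisq_p <- function(obs_counts, probs) {
  N <- sum(obs_counts)
  keep <- probs * N >= 5
  o <- c(obs_counts[keep], sum(obs_counts[!keep]))
  p <- c(probs[keep], sum(probs[!keep]))
  nz <- p > 0
  chi <- sum((o[nz] - N * p[nz])^2 / (N * p[nz]))
  stats::pchisq(chi, df = sum(nz) - 1, lower.tail = FALSE)
}

# ---------------------------------------------------------------------------
# Standalone plain Gibbs motif sampler (fixed width, no repulsion): the
# independent-chains baseline, reimplemented directly from the model to check
# that the interacting sampler at zero force severity reduces to it
# draw-for-draw under a shared RNG substream.
plain_gibbs_chain <- function(seqs, K, control, chain_seed, iterations) {
  n <- length(seqs)
  gam <- control$gamma
  alpha <- control$alpha
  bd <- if (length(control$beta_dirichlet) == 1L) rep(control$beta_dirichlet, 4L)
        else control$beta_dirichlet
  rdir <- function(shape) { g <- rgamma(length(shape), shape); g / sum(g) }
  set.seed(chain_seed)

  # -- enriched-word seeding (same scheme as the package, coded afresh)
  text <- paste(c(seqs$bases, reverse_complement(seqs$bases)), collapse = "\1")
  C <- control$seed_candidates
  eligible <- which(seqs$lengths >= K)
  cand <- character(C)
  for (c0 in seq_len(C)) {
    i <- eligible[sample.int(length(eligible), 1L)]
    u <- sample.int(seqs$lengths[i] - K + 1L, 1L)
    cand[c0] <- substr(seqs$bases[i], u, u + K - 1L)
  }
  cnt <- vapply(unique(cand), function(wd) {
    h <- gregexpr(wd, text, fixed = TRUE)[[1L]]
    if (h[1L] == -1L) 0L else length(h)
  }, integer(1))
  cnt <- cnt[match(cand, names(cnt))]
  pick <- sample.int(C, 1L, prob = cnt)
  kmer <- match(strsplit(cand[pick], "")[[1L]], DNA)
  pc <- control$init_pseudocount
  th <- matrix(pc, 4, K)
  th[cbind(kmer, seq_len(K))] <- th[cbind(kmer, seq_len(K))] + 1
  th <- sweep(th, 2, colSums(th), "/")
  theta0 <- as.numeric(seqs$total_counts / sum(seqs$total_counts))
  theta0 <- pmax(theta0, 1e-9); theta0 <- theta0 / sum(theta0)
  z <- rbinom(n, 1L, gam^K)
  z[seqs$lengths < K] <- 0L
  u <- rep(NA_integer_, n)
  for (j in which(z == 1L)) {
    vsj <- valid_starts(seqs$lengths[j], K)
    u[j] <- vsj[sample.int(length(vsj), 1L)]
  }

  out <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    lr <- log(th) - log(theta0)
    for (i in seq_len(n)) {
      L <- seqs$lengths[i]
      code <- seqs$codes[[i]]
      W <- 2L * L - K + 1L
      sc <- lr[code[seq_len(W)], 1L]
      if (K > 1L) for (k in 2:K) sc <- sc + lr[code[k:(W + k - 1L)], k]
      vsi <- c(seq_len(L - K + 1L), L + seq_len(L - K + 1L))
      lw <- c(log1p(-gam^K), K * log(gam) - log(2 * (L - K + 1L)) + sc[vsi])
      mx <- max(lw)
      w <- exp(lw - mx); w <- w / sum(w)
      idx <- sample.int(length(w), 1L, prob = w)
      if (idx == 1L) { z[i] <- 0L; u[i] <- NA_integer_ }
      else { z[i] <- 1L; u[i] <- vsi[idx - 1L] }
    }
    m <- matrix(0L, 4, K); occ <- numeric(4)
    for (i in which(z == 1L)) {
      km <- seqs$codes[[i]][u[i] + 0:(K - 1)]
      for (k in seq_len(K)) m[km[k], k] <- m[km[k], k] + 1L
      occ <- occ + tabulate(km, 4)
    }
    theta0 <- rdir(alpha + seqs$total_counts - occ)
    th <- vapply(seq_len(K), function(k) rdir(bd + m[, k]), numeric(4))
    out[[it]] <- list(z = z, u = u, theta0 = theta0, ppm = th)
  }
  out
}

# Aligned mean per-column total-variation distance between two PPMs (best
# offset of the shorter along the longer; unmatched columns ignored).
aligned_tv <- function(p, q) {
  p <- unclass(p); q <- unclass(q)
  if (ncol(p) < ncol(q)) { tmp <- p; p <- q; q <- tmp }
  ks <- ncol(q)
  best <- Inf
  for (o in 0:(ncol(p) - ks)) {
    v <- mean(colSums(abs(p[, (o + 1):(o + ks), drop = FALSE] - q)) / 2)
    if (v < best) best <- v
  }
  best
}

# Reverse complement of a PPM (motif read on the other strand).
rc_ppm <- function(p) ppm(unclass(p)[4:1, ncol(p):1])

# Shift-tolerant variants of a truth PPM (same motif in a shifted register,
# padded with uniform columns), both strands.
ppm_variants <- function(p, max_shift = 2) {
  one <- function(q) {
    q <- unclass(q)
    out <- list(ppm(q))
    for (k in seq_len(max_shift)) {
      pad <- matrix(0.25, 4, k)
      out <- c(out, list(ppm(cbind(q[, -(1:k), drop = FALSE], pad))),
                    list(ppm(cbind(pad, q[, 1:(ncol(q) - k), drop = FALSE]))))
    }
    out
  }
  c(one(p), one(rc_ppm(p)))
}

# Classify a sampled PPM as one of the planted truths (index into `truths`)
# or 0 when it is not within `lambda` of any variant.
classify_ppm <- function(p, truths, lambda = 0.3) {
  d <- vapply(truths, function(v)
    min(vapply(v, ppm_dissimilarity, numeric(1), p = p)), numeric(1))
  if (min(d) >= lambda) 0L else which.min(d)
}
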