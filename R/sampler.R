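# Gibbs/reversible-jump updates of one replica and the interacting RPMCMC
# loop.  All updates work in log space; categorical draws normalise by the
# running maximum before exponentiating.

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape)
  s <- sum(g)
  if (s == 0) {                      # all-zero gammas: numerically degenerate
    g <- rep(1, length(shape))
    s <- length(shape)
  }
  g / s
}

# Log odds sum_k log(theta_k / theta0) of every K-mer window of the
# concatenated sequence, over all starts 1..2L-K+1 (straddling windows are
# subset away by the caller).
window_log_odds <- function(code, L, K, log_ratio) {
  W <- 2L * L - K + 1L
  sc <- log_ratio[code[seq_len(W)], 1L]
  if (K > 1L) {
    for (k in 2:K) sc <- sc + log_ratio[code[k:(W + k - 1L)], k]
  }
  sc
}

# Full conditional of (z_i, u_i) for one sequence: element `p0` is
# P(z = 0 | ...), `pu` the probabilities of each admissible start.
site_conditional <- function(code, L, K, log_ratio, gamma) {
  nstart <- L - K + 1L
  lw0 <- log1p(-gamma^K)
  sc <- window_log_odds(code, L, K, log_ratio)
  keep <- c(seq_len(nstart), L + seq_len(nstart))
  lwu <- K * log(gamma) - log(2 * nstart) + sc[keep]
  m <- max(lw0, lwu)
  w <- exp(c(lw0, lwu) - m)
  w <- w / sum(w)
  list(p0 = w[1L], pu = w[-1L], starts = keep)
}

# Draw (z_i, u_i) from the exact full conditional.  K > L forces z = 0.
sample_site <- function(code, L, K, log_ratio, gamma) {
  if (K > L) return(list(z = 0L, u = NA_integer_))
  cond <- site_conditional(code, L, K, log_ratio, gamma)
  idx <- sample.int(length(cond$pu) + 1L, 1L, prob = c(cond$p0, cond$pu))
  if (idx == 1L) list(z = 0L, u = NA_integer_)
  else list(z = 1L, u = cond$starts[idx - 1L])
}

# Conjugate Dirichlet draw of the background probabilities.
sample_background <- function(bg_counts, alpha) {
  rdirichlet1(alpha + bg_counts)
}

# Conjugate Dirichlet draw of each PPM column.
sample_ppm_conjugate <- function(counts, beta_dirichlet) {
  K <- ncol(counts)
  bd <- if (length(beta_dirichlet) == 1L) rep(beta_dirichlet, 4L) else beta_dirichlet
  mat <- vapply(seq_len(K), function(k) rdirichlet1(bd + counts[, k]), numeric(4))
  ppm(matrix(mat, nrow = 4L))
}

# One-dimensional slice update (Neal stepping-out then shrinkage) of a
# coordinate with log-density g on (0, 1).
slice_coord <- function(g, x0, w = 0.1, max_expand = 50L) {
  eps <- 1e-9
  x0 <- min(max(x0, eps), 1 - eps)
  g0 <- g(x0)
  if (!is.finite(g0)) return(x0)
  logy <- g0 + log(stats::runif(1))
  L <- x0 - w * stats::runif(1)
  R <- L + w
  for (e in seq_len(max_expand)) {
    if (L <= eps) { L <- eps; break }
    if (g(L) <= logy) break
    L <- L - w
  }
  for (e in seq_len(max_expand)) {
    if (R >= 1 - eps) { R <- 1 - eps; break }
    if (g(R) <= logy) break
    R <- R + w
  }
  L <- max(L, eps); R <- min(R, 1 - eps)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (g(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Update of the PPM under the full conditional
#   prod_k Dirichlet(theta_k; beta_dirichlet + counts_k) * exp(beta * min_j D),
# by coordinate-wise slice sampling: each simplex coordinate theta[s, k] is
# moved along the path that rescales the other three entries of its column
# proportionally, whose induced 1-D density is Beta(a_s, sum a_-s) times the
# repulsion factor; Neal stepping-out with initial width 0.1 per coordinate.
# The repulsion factor can dominate the data term (large beta), in which case
# the conditional's mass sits away from the count mode -- a random-walk slice
# handles both regimes.  At beta = 0 (or with no other replicas) the exact
# conjugate Dirichlet draw is used instead.
sample_ppm_repulsive <- function(counts, beta_dirichlet, other_ppms, beta,
                                 gap_c, current_ppm = NULL, max_tries = 50L) {
  if (beta == 0 || length(other_ppms) == 0L)
    return(sample_ppm_conjugate(counts, beta_dirichlet))
  stopifnot(!is.null(current_ppm))
  K <- ncol(counts)
  bd <- if (length(beta_dirichlet) == 1L) rep(beta_dirichlet, 4L) else beta_dirichlet
  th <- unclass(current_ppm)
  others <- lapply(other_ppms, unclass)
  for (k in seq_len(K)) {
    for (s in 1:4) {
      a <- counts[s, k] + bd[s]
      b <- sum(counts[-s, k] + bd[-s])
      rest <- th[-s, k]
      restp <- if (sum(rest) > 0) rest / sum(rest) else rep(1 / 3, 3L)
      g <- function(x) {
        col <- numeric(4L)
        col[s] <- x
        col[-s] <- restp * (1 - x)
        thx <- th
        thx[, k] <- col
        val <- beta * min_dissimilarity(thx, others, gap_c)
        if (a != 1) val <- val + (a - 1) * log(x)
        if (b != 1) val <- val + (b - 1) * log1p(-x)
        val
      }
      x1 <- slice_coord(g, th[s, k], w = 0.1, max_expand = max_tries)
      th[s, k] <- x1
      th[-s, k] <- restp * (1 - x1)
    }
  }
  ppm(th)
}

# Reversible-jump width move: grow or shrink one boundary column by one.
# The new column is drawn from its Dirichlet prior, which cancels against the
# PPM prior in the acceptance ratio; start sites shift so retained columns
# stay aligned.  Occupied sites that cannot accommodate the new width force a
# rejection.  Returns the (possibly unchanged) state plus an `accepted` flag.
propose_length_move <- function(seqs, state, control) {
  K <- state$K
  grow <- stats::runif(1) < 0.5
  left <- stats::runif(1) < 0.5
  K2 <- if (grow) K + 1L else K - 1L
  bd <- control$beta_dirichlet
  if (length(bd) == 1L) bd <- rep(bd, 4L)
  new_col <- if (grow) rdirichlet1(bd) else NULL  # drawn before any rejection
  if (K2 < control$kmin || K2 > control$kmax)
    return(list(state = state, accepted = FALSE))

  u2 <- state$u
  occ <- which(state$z == 1L)
  if (grow && left) u2[occ] <- u2[occ] - 1L
  if (!grow && left) u2[occ] <- u2[occ] + 1L
  if (grow) {
    for (i in occ) {
      L <- seqs$lengths[i]
      ok <- if (u2[i] <= L - K2 + 1L) u2[i] >= 1L
            else u2[i] >= L + 1L && u2[i] + K2 - 1L <= 2L * L
      if (!ok) return(list(state = state, accepted = FALSE))
    }
  }

  ppm2 <- if (grow) {
    if (left) ppm(cbind(new_col, unclass(state$ppm)))
    else      ppm(cbind(unclass(state$ppm), new_col))
  } else {
    if (left) ppm(unclass(state$ppm)[, -1L, drop = FALSE])
    else      ppm(unclass(state$ppm)[, -K, drop = FALSE])
  }
  cand <- replica_state(state$z, u2, K2, ppm2, state$theta0)

  m1 <- motif_counts(seqs, state)$motif
  m2 <- motif_counts(seqs, cand)$motif
  n1 <- length(occ); n0 <- length(state$z) - n1
  gam <- control$gamma
  log_a <- motif_ratio_loglik(m2, cand$ppm, state$theta0) -
    motif_ratio_loglik(m1, state$ppm, state$theta0) +
    n0 * (log1p(-gam^K2) - log1p(-gam^K))
  if (n1 > 0L)
    log_a <- log_a + n1 * (K2 - K) * log(gam) +
      sum(log(seqs$lengths[occ] - K + 1) -
          log(seqs$lengths[occ] - K2 + 1))
  if (is.nan(log_a)) log_a <- -Inf
  if (log(stats::runif(1)) < log_a) list(state = cand, accepted = TRUE)
  else list(state = state, accepted = FALSE)
}

# Both-strand search text for enriched-word seeding (built once per run; the
# \1 separator prevents matches spanning sequence boundaries).
seed_text <- function(seqs) {
  paste(c(seqs$bases, reverse_complement(seqs$bases)), collapse = "\1")
}

count_word <- function(word, text) {
  hits <- gregexpr(word, text, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

# Seed one replica at width kmin with an enriched data word: a batch of
# candidate K-mers is drawn uniformly from the forward strands and one is
# picked with probability proportional to its exact both-strand occurrence
# count, so overrepresented words (motif instances) are strongly favoured.
# The seed PPM is the chosen word smoothed by `init_pseudocount` per cell
# (sharp by default: the blocked Gibbs chain only locks onto a motif whose
# seed already scores its instances well above the ZOOPS occupancy prior).
# theta0 starts at the empirical base composition; (z, u) are one prior draw.
init_replica <- function(seqs, control, text = seed_text(seqs)) {
  K <- control$kmin                     # reversible jump explores widths
  n <- length(seqs)
  eligible <- which(seqs$lengths >= K)
  if (length(eligible) == 0L) stop("no sequence is long enough for width ", K)
  C <- control$seed_candidates
  cand <- character(C)
  for (c0 in seq_len(C)) {
    i <- eligible[sample.int(length(eligible), 1L)]
    u <- sample.int(seqs$lengths[i] - K + 1L, 1L)
    cand[c0] <- substr(seqs$bases[i], u, u + K - 1L)
  }
  counts <- vapply(unique(cand), count_word, integer(1), text = text)
  counts <- counts[match(cand, names(counts))]
  pick <- sample.int(C, 1L, prob = counts)
  kmer <- encode_bases(cand[pick])
  pc <- control$init_pseudocount
  mat <- matrix(pc, 4L, K)
  mat[cbind(kmer, seq_len(K))] <- mat[cbind(kmer, seq_len(K))] + 1
  mat <- sweep(mat, 2L, colSums(mat), "/")
  theta0 <- as.numeric(seqs$total_counts / sum(seqs$total_counts))
  theta0 <- pmax(theta0, 1e-9); theta0 <- theta0 / sum(theta0)
  z <- stats::rbinom(n, 1L, control$gamma^K)
  z[seqs$lengths < K] <- 0L
  uu <- rep(NA_integer_, n)
  for (j in which(z == 1L)) {
    vs <- valid_starts(seqs$lengths[j], K)
    uu[j] <- vs[sample.int(length(vs), 1L)]
  }
  replica_state(z, uu, K, ppm(mat), theta0)
}

# One full Gibbs sweep of replica `state`: sites, theta0, PPM (repelled
# against `other_ppms`), then the width move when widths are free.
update_replica <- function(seqs, state, other_ppms, beta, control) {
  K <- state$K
  log_ratio <- log(unclass(state$ppm)) - log(state$theta0)
  n <- length(seqs)
  z <- state$z; u <- state$u
  for (i in seq_len(n)) {
    s <- sample_site(seqs$codes[[i]], seqs$lengths[i], K, log_ratio,
                     control$gamma)
    z[i] <- s$z; u[i] <- s$u
  }
  state$z <- z; state$u <- u
  cnt <- motif_counts(seqs, state)
  state$theta0 <- sample_background(cnt$background, control$alpha)
  state$ppm <- sample_ppm_repulsive(cnt$motif, control$beta_dirichlet,
                                    other_ppms, beta, control$gap_c,
                                    current_ppm = state$ppm,
                                    max_tries = control$slice_max_tries)
  accepted <- NA
  if (control$kmin < control$kmax) {
    mv <- propose_length_move(seqs, state, control)
    state <- mv$state
    accepted <- mv$accepted
  }
  list(state = state, accepted = accepted)
}

# The interacting parallel loop.  Each replica owns a deterministic RNG
# substream derived from the master seed, so the `zero` force policy
# reproduces M independent Gibbs chains draw-for-draw.
run_rpmcmc <- function(seqs, control, seed) {
  if (length(seqs) == 0L) stop("empty sequence set")
  M <- control$replicas
  N <- control$iterations
  set.seed(seed)
  replica_seeds <- sample.int(.Machine$integer.max, M)

  rng_states <- vector("list", M)
  use_stream <- function(i) {
    if (is.null(rng_states[[i]])) set.seed(replica_seeds[i])
    else assign(".Random.seed", rng_states[[i]], envir = globalenv())
  }
  stash_stream <- function(i) rng_states[[i]] <<- get(".Random.seed", envir = globalenv())

  text <- seed_text(seqs)
  states <- vector("list", M)
  for (i in seq_len(M)) {
    use_stream(i)
    states[[i]] <- init_replica(seqs, control, text = text)
    stash_stream(i)
  }

  n_keep <- N - control$burnin
  samples <- vector("list", n_keep)
  loglik <- matrix(NA_real_, N, M)
  beta_mat <- matrix(NA_real_, N, M)
  accept <- matrix(NA, N, M)

  for (it in seq_len(N)) {
    for (i in seq_len(M)) {
      beta_i <- beta_severity(control$beta_policy, states[[i]]$z)
      beta_mat[it, i] <- beta_i
      use_stream(i)
      upd <- update_replica(seqs, states[[i]], states[-i] |> lapply(`[[`, "ppm"),
                            beta_i, control)
      stash_stream(i)
      states[[i]] <- upd$state
      accept[it, i] <- upd$accepted
      loglik[it, i] <- motif_loglik(seqs, states[[i]])
    }
    ppms <- lapply(states, `[[`, "ppm")
    min_d <- c(0, vapply(seq_len(M)[-1], function(i)
      min_dissimilarity(ppms[[i]], ppms[seq_len(i - 1L)], control$gap_c),
      numeric(1)))[seq_len(M)]
    if (it > control$burnin) {
      samples[[it - control$burnin]] <- list(
        replicas = states,
        loglik = loglik[it, ],
        log_psi = sum(min_d),
        log_repulsion = sum(beta_mat[it, ] * min_d),
        beta = beta_mat[it, ],
        iteration = it
      )
    }
    if (control$verbose && it %% 10L == 0L) {
      message(sprintf("iter %4d | mean logL %.1f | beta %.1f | width-move acc %.2f",
                      it, mean(loglik[it, ]), mean(beta_mat[it, ]),
                      mean(accept[seq_len(it), ], na.rm = TRUE)))
    }
  }

  list(samples = samples, loglik = loglik, beta = beta_mat,
       accept_width = accept, replica_seeds = replica_seeds)
}
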