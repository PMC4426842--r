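#' Construct a replica state
#'
#' One sampler replica carries the full parameter/latent state of the ZOOPS
#' model: per-sequence presence indicators `z`, start sites `u` (concatenated
#' coordinates, `NA` where `z = 0`), motif width `K`, the motif PPM and the
#' background base probabilities.
#'
#' @param z integer/logical vector of presence indicators.
#' @param u integer vector of start sites (NA where z = 0).
#' @param K motif width.
#' @param ppm a [ppm] of width `K`.
#' @param theta0 background probability 4-vector (sums to 1).
#' @return list of class `replica_state`.
#' @export
replica_state <- function(z, u, K, ppm, theta0) {
  z <- as.integer(z)
  u <- as.integer(u)
  stopifnot(length(z) == length(u), all(z %in% c(0L, 1L)),
            ncol(ppm) == K, length(theta0) == 4L,
            abs(sum(theta0) - 1) < 1e-9, all(theta0 > 0))
  structure(list(z = z, u = u, K = as.integer(K), ppm = ppm,
                 theta0 = as.numeric(theta0)),
            class = "replica_state")
}

check_state <- function(seqs, state) {
  occ <- which(state$z == 1L)
  for (i in occ) {
    vs <- valid_starts(seqs$lengths[i], state$K)
    if (!(state$u[i] %in% vs))
      stop(sprintf("start site %d invalid for sequence %d at width %d",
                   state$u[i], i, state$K))
  }
  invisible(TRUE)
}

#' Sufficient statistics of the ZOOPS likelihood
#'
#' Tallies, over sequences with `z = 1`, the base occupying each motif column
#' (a 4 x K matrix whose column sums all equal `sum(z)`), and the background
#' counts: total letter counts of all concatenated sequences minus the
#' motif-occupied letters.  The latter are the sufficient statistics of the
#' background probabilities once the motif-position ratio factor of the
#' likelihood is accounted for.
#'
#' @param seqs a [motif_seqs] object.
#' @param state a [replica_state].
#' @return list with `motif` (4 x K matrix) and `background` (4-vector).
#' @export
motif_counts <- function(seqs, state) {
  K <- state$K
  occ <- which(state$z == 1L)
  m <- matrix(0L, 4L, K, dimnames = list(DNA_BASES, NULL))
  if (length(occ) > 0L) {
    B <- vapply(occ, function(i) seqs$codes[[i]][state$u[i] + 0:(K - 1L)],
                integer(K))                       # K x n_occupied
    if (K == 1L) B <- matrix(B, nrow = 1L)
    for (k in seq_len(K)) m[, k] <- tabulate(B[k, ], nbins = 4L)
  }
  bg <- seqs$total_counts - rowSums(m)
  list(motif = m, background = as.numeric(bg))
}

#' ZOOPS log-likelihood
#'
#' The likelihood factorises into the background probability of every letter
#' of every concatenated sequence and, for each sequence carrying a motif, the
#' ratio `theta_k,sigma / theta_0,sigma` over its K occupied positions.  A
#' referenced zero probability yields `-Inf`, never an error.
#'
#' @param seqs a [motif_seqs] object.
#' @param state a [replica_state].
#' @return log-likelihood scalar (up to the model's constant factor).
#' @export
motif_loglik <- function(seqs, state) {
  cnt <- motif_counts(seqs, state)
  bg_term <- sum(seqs$total_counts * log(state$theta0))
  bg_term + motif_ratio_loglik(cnt$motif, state$ppm, state$theta0)
}

# Ratio factor only (background term dropped); the piece that changes with
# (Z, U, K, Theta) at fixed theta0 -- used by the width move.  Zero counts at
# zero-probability cells contribute 0; positive counts there give -Inf.
motif_ratio_loglik <- function(m, ppm, theta0) {
  pos <- m > 0L
  if (!any(pos)) return(0)
  lp <- log(ppm)[pos]
  if (any(!is.finite(lp))) return(-Inf)
  sum(m[pos] * lp) - sum(rowSums(m) * log(theta0))
}

ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' ZOOPS log-prior
#'
#' Dirichlet priors on the PPM columns and the background, a geometric-in-K
#' occupancy prior `p(z = 1 | K) = gamma^K`, uniform start sites over the
#' `2(L - K + 1)` admissible positions, and a uniform width prior on
#' `[kmin, kmax]`.
#'
#' @param seqs a [motif_seqs] object (for the sequence lengths).
#' @param state a [replica_state].
#' @param control a [rpmcmc_control] list.
#' @return log-prior scalar; `-Inf` when `K` is outside `[kmin, kmax]` or an
#'   impossible configuration is evaluated (e.g. `z = 1` under `gamma = 0`).
#' @export
motif_log_prior <- function(seqs, state, control) {
  K <- state$K
  if (K < control$kmin || K > control$kmax) return(-Inf)
  lp <- -log(control$kmax - control$kmin + 1)
  gK <- control$gamma^K
  n1 <- sum(state$z)
  n0 <- length(state$z) - n1
  if (n1 > 0L && gK == 0) return(-Inf)
  if (n0 > 0L && gK == 1) return(-Inf)
  lp <- lp + n1 * K * log(control$gamma) + n0 * log1p(-gK)
  occ <- which(state$z == 1L)
  if (length(occ) > 0L)
    lp <- lp - sum(log(2 * (seqs$lengths[occ] - K + 1)))
  bd <- control$beta_dirichlet
  if (length(bd) == 1L) bd <- rep(bd, 4L)
  for (k in seq_len(K)) lp <- lp + ldirichlet(state$ppm[, k], bd)
  lp + ldirichlet(state$theta0, control$alpha)
}
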