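#' Tuning parameters of the RPMCMC sampler
#'
#' Defaults follow the published defaults of the algorithm: occupancy prior
#' `gamma = 0.755`, motif widths 8-15, flat Dirichlet priors
#' (`alpha = beta_dirichlet = 1`), `M = 50` replicas, `N = 520` iterations
#' with a fixed burn-in of 20, dynamic force severity `beta = 10 * sum(z)`
#' recomputed per replica each iteration, clustering threshold
#' `lambda = 0.3` and gap penalty `gap_c = 0.3`.
#'
#' @param gamma occupancy prior parameter in `[0, 1]`; `p(z = 1 | K) = gamma^K`.
#' @param kmin,kmax minimum/maximum motif width (uniform prior on widths).
#' @param alpha Dirichlet concentration 4-vector of the background prior.
#' @param beta_dirichlet Dirichlet concentration of each PPM column prior
#'   (scalar or 4-vector).
#' @param replicas number of interacting replicas M.
#' @param iterations total MCMC iterations N.
#' @param burnin iterations discarded before samples are kept.
#' @param beta_policy force-severity rule: `"dynamic10"` (`10 * sum(z)` per
#'   replica), `"zero"` (independent chains), or `"constant:<value>"`; a
#'   plain number is treated as a constant severity.
#' @param lambda clustering threshold on the PPM dissimilarity.
#' @param gap_c gap penalty per column of width difference in the
#'   dissimilarity.
#' @param enrich_threshold minimum fraction of sequences a motif must occupy
#'   (`sum(z)/n`) to be flagged enriched in reports.
#' @param weight_mode importance-weight mode, `"exponent"` or `"literal"`;
#'   see [importance_weights].
#' @param slice_max_tries maximum conjugate proposals per slice update before
#'   falling back to the unrepelled conjugate draw.
#' @param init_pseudocount per-cell pseudocount used when seeding each
#'   replica's PPM from a data word; small values give a sharp seed, which
#'   the occupancy prior requires for a chain to lock onto a motif.
#' @param seed_candidates number of candidate words scored per replica when
#'   seeding; one is picked with probability proportional to its exact
#'   both-strand occurrence count (enriched-word seeding).
#' @param verbose print a progress line every 10 iterations.
#' @return a classed list of validated settings.
#' @export
rpmcmc_control <- function(gamma = 0.755, kmin = 8L, kmax = 15L,
                           alpha = rep(1, 4), beta_dirichlet = 1,
                           replicas = 50L, iterations = 520L, burnin = 20L,
                           beta_policy = "dynamic10",
                           lambda = 0.3, gap_c = 0.3,
                           enrich_threshold = 0.05,
                           weight_mode = c("exponent", "literal"),
                           slice_max_tries = 50L,
                           init_pseudocount = 0.06,
                           seed_candidates = 100L,
                           verbose = FALSE) {
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  replicas <- as.integer(replicas); iterations <- as.integer(iterations)
  burnin <- as.integer(burnin)
  if (length(alpha) == 1L) alpha <- rep(alpha, 4L)
  stopifnot(gamma >= 0, gamma <= 1, kmin >= 1L, kmin <= kmax,
            replicas >= 1L, iterations > burnin, burnin >= 0L,
            lambda > 0, gap_c > 0, enrich_threshold >= 0,
            all(alpha > 0), all(beta_dirichlet > 0))
  if (is.numeric(beta_policy)) beta_policy <- paste0("constant:", beta_policy)
  if (!beta_policy %in% c("dynamic10", "zero") &&
      !grepl("^constant:[0-9.eE+-]+$", beta_policy))
    stop("beta_policy must be 'dynamic10', 'zero', 'constant:<value>' or a number")
  structure(list(gamma = gamma, kmin = kmin, kmax = kmax, alpha = alpha,
                 beta_dirichlet = beta_dirichlet, replicas = replicas,
                 iterations = iterations, burnin = burnin,
                 beta_policy = beta_policy, lambda = lambda, gap_c = gap_c,
                 enrich_threshold = enrich_threshold,
                 weight_mode = match.arg(weight_mode),
                 slice_max_tries = as.integer(slice_max_tries),
                 init_pseudocount = init_pseudocount,
                 seed_candidates = as.integer(seed_candidates),
                 verbose = isTRUE(verbose)),
            class = "rpmcmc_control")
}

# Force severity of one replica at the current state.
beta_severity <- function(policy, z) {
  if (policy == "zero") return(0)
  if (policy == "dynamic10") return(10 * sum(z))
  as.numeric(sub("^constant:", "", policy))
}
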