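#' Fit the repulsive parallel MCMC motif sampler
#'
#' Runs M interacting Gibbs motif samplers under the ZOOPS model (zero or one
#' motif occurrence per sequence, scanned on both strands).  The replicas
#' share one augmented target in which a repulsive factor penalises nearby
#' position probability matrices, so different replicas are driven to explore
#' different motifs; the bias so introduced is corrected afterwards by
#' importance weights.  Motif widths are sampled by reversible jump between
#' `kmin` and `kmax`.
#'
#' @param x sequences: a [motif_seqs] object, a character vector of DNA
#'   strings, or the path of a FASTA file.
#' @param control a [rpmcmc_control] list of tuning parameters.
#' @param seed integer master seed; every source of randomness in the run
#'   derives from it, so equal seeds give bitwise-identical fits.
#' @return an object of class `rpmcmc` holding the kept joint samples (one
#'   per post-burn-in iteration, each with all M replica states, its log
#'   repulsive force and its importance weight), the per-iteration
#'   log-likelihood matrix, and the run configuration.
#' @seealso [cluster_motifs] to reduce the samples to a ranked motif list,
#'   [simulate_motif_data] for benchmark data.
#' @examples
#' dat <- simulate_motif_data(n = 20, length_mode = "fixed", fixed_length = 60,
#'                            ppms = list(example_ppm("TATAAAWW")),
#'                            mean_motifs = 0.9, count_model = "bernoulli",
#'                            seed = 1)
#' ctl <- rpmcmc_control(kmin = 8, kmax = 8, replicas = 2, iterations = 60,
#'                       burnin = 10)
#' fit <- rpmcmc(dat$sequences, ctl, seed = 1)
#' fit
#' @export
rpmcmc <- function(x, control = rpmcmc_control(), seed = 1L) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) x <- read_fasta(x)
  seqs <- motif_seqs(x)
  stopifnot(inherits(control, "rpmcmc_control"))
  run <- run_rpmcmc(seqs, control, seed = as.integer(seed))
  log_psi <- vapply(run$samples, `[[`, numeric(1), "log_psi")
  log_rep <- vapply(run$samples, `[[`, numeric(1), "log_repulsion")
  w <- importance_weights(log_psi, log_rep, mode = control$weight_mode)
  structure(list(
    samples = run$samples,
    weights = w,
    log_psi = log_psi,
    log_repulsion = log_rep,
    loglik = run$loglik,
    beta = run$beta,
    accept_width = run$accept_width,
    sequences = seqs,
    control = control,
    seed = as.integer(seed),
    replica_seeds = run$replica_seeds
  ), class = "rpmcmc")
}

#' @export
print.rpmcmc <- function(x, ...) {
  ctl <- x$control
  cat("Repulsive parallel MCMC motif sampler fit\n")
  cat(sprintf("  sequences : %d (lengths %d-%d bp)\n", length(x$sequences),
              min(x$sequences$lengths), max(x$sequences$lengths)))
  cat(sprintf("  replicas  : %d, iterations %d (burn-in %d, %d kept)\n",
              ctl$replicas, ctl$iterations, ctl$burnin, length(x$samples)))
  cat(sprintf("  widths    : %d-%d, beta policy '%s', weight mode '%s'\n",
              ctl$kmin, ctl$kmax, ctl$beta_policy, ctl$weight_mode))
  cat(sprintf("  max sampled log-likelihood: %.2f\n",
              max(x$loglik, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn rpmcmc cluster the samples and summarise the ranked motifs.
#' @param object,... method arguments.
#' @export
summary.rpmcmc <- function(object, ...) {
  cl <- cluster_motifs(object, ...)
  structure(list(fit = object, clusters = cl), class = "summary.rpmcmc")
}

#' @export
print.summary.rpmcmc <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$clusters)
  invisible(x)
}

#' @describeIn rpmcmc representative PPMs of the top-ranked motif clusters.
#' @export
coef.rpmcmc <- function(object, ...) {
  cl <- cluster_motifs(object, ...)
  lapply(cl$representatives, `[[`, "ppm")
}

#' @describeIn rpmcmc per-replica log-likelihood traces (base graphics).
#' @export
plot.rpmcmc <- function(x, ...) {
  ll <- x$loglik
  graphics::matplot(ll, type = "l", lty = 1,
                    xlab = "iteration", ylab = "log-likelihood",
                    main = "Replica log-likelihood traces", ...)
  graphics::abline(v = x$control$burnin, lty = 2)
  invisible(x)
}

#' @export
logLik.rpmcmc <- function(object, ...) {
  structure(max(object$loglik, na.rm = TRUE), df = NA_integer_,
            class = "logLik")
}
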