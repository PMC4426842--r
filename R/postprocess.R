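# Reduction of the M x N sampled states to a ranked list of representative
# motifs: greedy likelihood-ordered clustering in PPM dissimilarity space,
# importance-weighted ranking, and the sequence-enrichment filter.

# Greedy clustering of PPMs.  Samples are sorted by likelihood (descending;
# ties broken by the supplied order index for determinism); the top remaining
# sample seeds a cluster and absorbs every remaining sample within `lambda`
# of it; repeat until none are left.  Returns, per cluster, the indices of
# its members in the original sample order with the seed (= representative,
# the likelihood maximiser of the cluster) first.
cluster_samples <- function(ppms, logliks, lambda, gap_c,
                            tie_order = seq_along(ppms)) {
  stopifnot(length(ppms) == length(logliks), length(ppms) > 0L, lambda >= 0)
  ord <- order(-logliks, tie_order)
  remaining <- ord
  clusters <- list()
  while (length(remaining) > 0L) {
    seed <- remaining[1L]
    d <- vapply(remaining, function(i)
      ppm_dissimilarity(ppms[[seed]], ppms[[i]], gap_c), numeric(1))
    members <- remaining[d <= lambda]
    clusters[[length(clusters) + 1L]] <- members
    remaining <- remaining[d > lambda]
  }
  clusters
}

# Normalised cluster weights w* (sum of member importance weights) and the
# rank order: weight descending, ties by representative likelihood.
rank_clusters <- function(clusters, sample_weights, rep_logliks) {
  w <- vapply(clusters, function(m) sum(sample_weights[m]), numeric(1))
  tot <- sum(w)
  w_star <- if (tot > 0) w / tot else rep(1 / length(w), length(w))
  ord <- order(-w_star, -rep_logliks)
  list(w_star = w_star, order = ord,
       rank = match(seq_along(clusters), ord))
}

# Sequence-level enrichment: a motif is kept when it occupies at least
# `threshold` of the input sequences (inclusive boundary).
filter_enriched <- function(sum_z, n_sequences, threshold = 0.05) {
  if (n_sequences == 0L) stop("enrichment filter needs a nonempty sequence set")
  sum_z / n_sequences >= threshold
}

#' Cluster the sampled motifs into a ranked representative list
#'
#' Flattens the kept ensembles into `M * (N - burnin)` replica states,
#' greedily groups them by PPM dissimilarity (threshold `lambda`), ranks the
#' clusters by their summed importance weights, and flags clusters whose
#' representative occupies at least `enrich_threshold` of the sequences.
#' Each cluster's representative is its likelihood-maximising member; its
#' reported PPM is that representative's draw, and a weighted posterior-mean
#' PPM over equal-width members is attached as `mean_ppm`.
#'
#' @param fit an [rpmcmc] fit.
#' @param lambda,gap_c,enrich_threshold override the fit's control values.
#' @return an object of class `motif_clusters`: a summary data frame (rank,
#'   width, weight, enrichment, log-likelihood, consensus) plus the
#'   representative states and member indices, ordered by rank.
#' @export
cluster_motifs <- function(fit, lambda = NULL, gap_c = NULL,
                           enrich_threshold = NULL) {
  stopifnot(inherits(fit, "rpmcmc"))
  ctl <- fit$control
  if (is.null(lambda)) lambda <- ctl$lambda
  if (is.null(gap_c)) gap_c <- ctl$gap_c
  if (is.null(enrich_threshold)) enrich_threshold <- ctl$enrich_threshold

  M <- ctl$replicas
  n_keep <- length(fit$samples)
  p <- M * n_keep
  ppms <- vector("list", p)
  logliks <- numeric(p)
  weights <- numeric(p)
  replica_idx <- integer(p)
  iter_idx <- integer(p)
  states <- vector("list", p)
  k <- 0L
  for (j in seq_len(n_keep)) {
    ens <- fit$samples[[j]]
    for (i in seq_len(M)) {
      k <- k + 1L
      states[[k]] <- ens$replicas[[i]]
      ppms[[k]] <- ens$replicas[[i]]$ppm
      logliks[k] <- ens$loglik[i]
      weights[k] <- fit$weights[j]       # shared within the ensemble
      replica_idx[k] <- i
      iter_idx[k] <- ens$iteration
    }
  }
  tie_order <- order(replica_idx, iter_idx)
  tie_rank <- match(seq_len(p), tie_order)

  cl <- cluster_samples(ppms, logliks, lambda, gap_c, tie_order = tie_rank)
  rep_idx <- vapply(cl, `[[`, integer(1), 1L)
  rep_ll <- logliks[rep_idx]
  rk <- rank_clusters(cl, weights, rep_ll)

  n <- length(fit$sequences)
  ord <- rk$order
  reps <- states[rep_idx[ord]]
  mean_ppms <- vector("list", length(ord))
  for (ci in seq_along(ord)) {
    members <- cl[[ord[ci]]]
    Kr <- reps[[ci]]$K
    same_k <- members[vapply(members, function(i) ncol(ppms[[i]]) == Kr, logical(1))]
    wm <- weights[same_k]
    if (sum(wm) <= 0) wm <- rep(1, length(same_k))
    acc <- matrix(0, 4L, Kr)
    for (s in seq_along(same_k)) acc <- acc + wm[s] * unclass(ppms[[same_k[s]]])
    mean_ppms[[ci]] <- ppm(acc / sum(wm))
  }
  sum_z <- vapply(reps, function(s) sum(s$z), integer(1))
  summary_df <- data.frame(
    rank = seq_along(ord),
    width = vapply(reps, `[[`, integer(1), "K"),
    weight = rk$w_star[ord],
    n_members = lengths(cl)[ord],
    sum_z = sum_z,
    enrichment = sum_z / n,
    enriched = filter_enriched(sum_z, n, enrich_threshold),
    loglik = rep_ll[ord],
    consensus = vapply(reps, function(s) ppm_consensus(s$ppm), character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(
    summary = summary_df,
    representatives = reps,
    mean_ppms = mean_ppms,
    members = cl[ord],
    lambda = lambda, gap_c = gap_c,
    enrich_threshold = enrich_threshold,
    n_sequences = n,
    sequence_ids = fit$sequences$ids,
    sequence_lengths = fit$sequences$lengths
  ), class = "motif_clusters")
}

#' @export
print.motif_clusters <- function(x, n = 10L, ...) {
  cat(sprintf("%d motif clusters from %d samples (lambda = %g, %d enriched >= %.0f%% of sequences)\n",
              nrow(x$summary), sum(x$summary$n_members), x$lambda,
              sum(x$summary$enriched), 100 * x$enrich_threshold))
  print(utils::head(x$summary, n), row.names = FALSE, digits = 3)
  if (nrow(x$summary) > n) cat("...\n")
  invisible(x)
}

#' Predicted motif sites of clustered motifs
#'
#' Extracts, for each (enriched, by default) cluster representative, the
#' sequences it occupies, with start sites mapped back to 1-based
#' forward-strand coordinates and an explicit strand column.
#'
#' @param clusters a [cluster_motifs] result.
#' @param enriched_only keep only clusters passing the enrichment filter.
#' @param max_rank optionally keep only the top clusters.
#' @return data frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `motif_label`, `rank` (1-based inclusive coordinates).
#' @export
predicted_sites <- function(clusters, enriched_only = TRUE, max_rank = Inf) {
  stopifnot(inherits(clusters, "motif_clusters"))
  keep <- clusters$summary$rank <= max_rank
  if (enriched_only) keep <- keep & clusters$summary$enriched
  out <- list()
  for (ci in which(keep)) {
    st <- clusters$representatives[[ci]]
    occ <- which(st$z == 1L)
    if (length(occ) == 0L) next
    rows <- lapply(occ, function(i) {
      f <- site_to_forward(st$u[i], clusters$sequence_lengths[i], st$K)
      data.frame(seq_id = clusters$sequence_ids[i],
                 start = f$start, end = f$start + st$K - 1L,
                 strand = f$strand,
                 motif_label = sprintf("motif_%d", clusters$summary$rank[ci]),
                 rank = clusters$summary$rank[ci],
                 stringsAsFactors = FALSE)
    })
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (length(out) == 0L)
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), motif_label = character(),
                      rank = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
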