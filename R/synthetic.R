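# Planted-motif benchmark data: i.i.d. multinomial background sequences with
# oligomers sampled from source PPMs overwritten at random non-overlapping
# positions and strands, plus the ground-truth site table.

#' Quick informative PPM from a consensus string
#'
#' Convenience constructor for tests and simulations: each consensus letter
#' contributes `strength` probability to its base(s) (IUPAC two-base codes
#' W, S, R, Y, K, M split it evenly; N is uniform), the remainder spread over
#' the other bases.
#'
#' @param consensus character string of IUPAC letters.
#' @param strength probability mass of the consensus base(s) per column.
#' @return a [ppm].
#' @export
example_ppm <- function(consensus, strength = 0.85) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                W = c("A", "T"), S = c("C", "G"), R = c("A", "G"),
                Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
                N = c("A", "C", "G", "T"))
  ch <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  cols <- lapply(ch, function(b) {
    hit <- iupac[[b]]
    if (is.null(hit)) stop("unsupported consensus letter: ", b)
    v <- rep((1 - strength) / (4 - length(hit)), 4L)
    if (length(hit) == 4L) v <- rep(0.25, 4L)
    else v[match(hit, DNA_BASES)] <- strength / length(hit)
    v
  })
  ppm(do.call(cbind, cols))
}

#' Generate background sequences
#'
#' i.i.d. multinomial letters drawn from the background composition, with
#' either fixed-length sequences (default 1000 bp) or lengths uniform on a
#' range (default 200-2000 bp).
#'
#' @param n number of sequences.
#' @param length_mode `"fixed"` or `"variable"`.
#' @param fixed_length length in fixed mode.
#' @param length_range integer range (inclusive) in variable mode.
#' @param background base probability 4-vector (A, C, G, T).
#' @return a [motif_seqs] object.
#' @export
generate_background <- function(n, length_mode = c("fixed", "variable"),
                                fixed_length = 1000L,
                                length_range = c(200L, 2000L),
                                background = rep(0.25, 4)) {
  length_mode <- match.arg(length_mode)
  stopifnot(n >= 1L, all(background >= 0), abs(sum(background) - 1) < 1e-6)
  lens <- if (length_mode == "fixed") rep(as.integer(fixed_length), n)
          else sample(length_range[1]:length_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE, prob = background),
          collapse = ""), character(1))
  motif_seqs(seqs, ids = sprintf("synth%d", seq_len(n)))
}

# Draw one oligomer column-wise from a PPM.
sample_oligomer <- function(p) {
  paste(vapply(seq_len(ncol(p)), function(k)
    sample(DNA_BASES, 1L, prob = p[, k]), character(1)), collapse = "")
}

#' Plant motif instances into sequences
#'
#' Per sequence, a random number of instances (Poisson with the given mean,
#' or Bernoulli for at most one per sequence) is drawn; each instance picks a
#' source PPM uniformly, samples its letters column-wise, picks a strand
#' uniformly, and overwrites a random window that does not overlap previously
#' planted instances.  Instances that cannot be placed after `max_attempts`
#' tries are dropped (count reported via a message).
#'
#' @param seqs a [motif_seqs] object (backgrounds to plant into).
#' @param ppms list of source [ppm]s.
#' @param mean_motifs mean planted instances per sequence (default 8).
#' @param count_model `"poisson"` or `"bernoulli"` (at most one instance,
#'   probability `mean_motifs`).
#' @param max_attempts placement attempts per instance before dropping it.
#' @return list with `sequences` (new [motif_seqs]) and `truth`, a site data
#'   frame (`seq_id`, `start`, `end`, `strand`, `motif_label`, `rank` = NA)
#'   in 1-based forward coordinates.
#' @export
plant_motifs <- function(seqs, ppms, mean_motifs = 8,
                         count_model = c("poisson", "bernoulli"),
                         max_attempts = 100L) {
  count_model <- match.arg(count_model)
  seqs <- motif_seqs(seqs)
  stopifnot(length(ppms) >= 1L, mean_motifs >= 0)
  if (is.null(names(ppms))) names(ppms) <- paste0("planted_", seq_along(ppms))
  n <- length(seqs)
  bases <- seqs$bases
  truth <- list()
  dropped <- 0L
  for (i in seq_len(n)) {
    L <- seqs$lengths[i]
    n_inst <- if (count_model == "poisson") stats::rpois(1L, mean_motifs)
              else stats::rbinom(1L, 1L, min(mean_motifs, 1))
    if (n_inst == 0L) next
    occupied <- matrix(integer(0), ncol = 2L)   # start, end (1-based)
    chars <- strsplit(bases[i], "", fixed = TRUE)[[1L]]
    for (inst in seq_len(n_inst)) {
      m <- sample.int(length(ppms), 1L)
      p <- ppms[[m]]
      K <- ncol(p)
      if (K > L) { dropped <- dropped + 1L; next }
      oligo <- sample_oligomer(p)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        start <- sample.int(L - K + 1L, 1L)
        end <- start + K - 1L
        clash <- nrow(occupied) > 0L &&
          any(start <= occupied[, 2L] & end >= occupied[, 1L])
        if (!clash) {
          ins <- if (strand == "+") oligo else reverse_complement(oligo)
          chars[start:end] <- strsplit(ins, "", fixed = TRUE)[[1L]]
          occupied <- rbind(occupied, c(start, end))
          truth[[length(truth) + 1L]] <- data.frame(
            seq_id = seqs$ids[i], start = start, end = end, strand = strand,
            motif_label = names(ppms)[m], rank = NA_integer_,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) dropped <- dropped + 1L
    }
    bases[i] <- paste(chars, collapse = "")
  }
  if (dropped > 0L)
    message(sprintf("plant_motifs: dropped %d instances that could not be placed", dropped))
  truth_df <- if (length(truth) > 0L) do.call(rbind, truth)
  else data.frame(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), motif_label = character(),
                  rank = integer(), stringsAsFactors = FALSE)
  list(sequences = motif_seqs(bases, ids = seqs$ids), truth = truth_df)
}

#' Simulate a planted-motif benchmark dataset
#'
#' Background generation plus motif planting under one seed, mirroring the
#' synthetic benchmark design the sampler is evaluated on: i.i.d. background
#' sequences of fixed (1000 bp) or variable (200-2000 bp) length with an
#' average of `mean_motifs` (default 8) instances per sequence drawn from the
#' supplied PPMs.
#'
#' @inheritParams generate_background
#' @inheritParams plant_motifs
#' @param ppms list of source [ppm]s; defaults to the packaged synthetic
#'   motif collection (see [synthetic_motif_file]).
#' @param mean_motifs mean planted instances per sequence.
#' @param seed RNG seed for the whole simulation.
#' @return list with `sequences` and `truth` as in [plant_motifs].
#' @export
simulate_motif_data <- function(n = 300L, length_mode = c("fixed", "variable"),
                                fixed_length = 1000L,
                                length_range = c(200L, 2000L),
                                background = rep(0.25, 4),
                                ppms = NULL, mean_motifs = 8,
                                count_model = c("poisson", "bernoulli"),
                                seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(ppms)) ppms <- read_meme(synthetic_motif_file())
  bg <- generate_background(n, match.arg(length_mode), fixed_length,
                            length_range, background)
  plant_motifs(bg, ppms, mean_motifs, match.arg(count_model))
}

#' Path of the packaged synthetic motif collection
#'
#' Ten synthetic PPMs of widths 8-15 in MEME minimal format, standing in for
#' a curated transcription-factor motif collection in simulations and tests
#' (they are generated, not derived from any database).
#'
#' @return file path within the installed package.
#' @export
synthetic_motif_file <- function() {
  system.file("extdata", "synthetic_motifs.meme", package = "rpmotif",
              mustWork = TRUE)
}
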