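# Nucleotide-level scoring of predicted motif sites against known (planted)
# sites, and the log-likelihood-ratio score of a predicted site set.

# Expand a site table into unique "seq_id:position" nucleotide keys on the
# forward strand.  Reverse-strand sites are assumed already projected to
# forward coordinates (start/end columns are strand-agnostic genomic
# positions).
site_nucleotides <- function(sites) {
  if (nrow(sites) == 0L) return(character(0))
  keys <- unlist(lapply(seq_len(nrow(sites)), function(r)
    paste0(sites$seq_id[r], ":", sites$start[r]:sites$end[r])))
  unique(keys)
}

#' Match predicted outputs to known motifs
#'
#' For each known motif, finds among the ranked predicted outputs the one
#' with the largest nucleotide overlap; ties go to the better (smaller) rank.
#'
#' @param known site data frame with columns `seq_id`, `start`, `end`,
#'   `motif_label` (one known motif per label).
#' @param predicted site data frame with columns `seq_id`, `start`, `end`,
#'   `rank` (one output per rank value).
#' @return data frame with one row per known motif: the matched output rank
#'   (`NA` when there are no predictions), the overlap in nucleotides, and
#'   the known/matched-output nucleotide totals.
#' @export
match_outputs <- function(known, predicted) {
  labels <- unique(known$motif_label)
  ranks <- sort(unique(predicted$rank))
  pred_nt <- lapply(ranks, function(r)
    site_nucleotides(predicted[predicted$rank == r, , drop = FALSE]))
  names(pred_nt) <- as.character(ranks)
  rows <- lapply(labels, function(lab) {
    kn <- site_nucleotides(known[known$motif_label == lab, , drop = FALSE])
    if (length(ranks) == 0L)
      return(data.frame(motif_label = lab, matched_rank = NA_integer_,
                        overlap = 0L, known_nt = length(kn), output_nt = 0L,
                        stringsAsFactors = FALSE))
    ov <- vapply(pred_nt, function(p) length(intersect(kn, p)), integer(1))
    best <- ranks[which.max(ov)]          # which.max: first max = best rank
    data.frame(motif_label = lab, matched_rank = best,
               overlap = max(ov), known_nt = length(kn),
               output_nt = length(pred_nt[[as.character(best)]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nucleotide-level sensitivity and positive predictive value
#'
#' Multi-motif SN/PPV: each of the J known motifs is matched to its
#' best-overlapping predicted output (ties to the better rank), and
#' `SN = sum_j overlap_j / sum_j |known_j|`,
#' `PPV = sum_j overlap_j / sum_j |matched output p_j|`.
#' Only matched outputs enter the PPV denominator, so unmatched extra outputs
#' do not dilute precision.
#'
#' @param known,predicted site data frames as in [match_outputs].
#' @return list with `SN`, `PPV`, the per-motif match table, and
#'   `undefined_ppv` flag (no predictions: both reported as 0).
#' @export
sn_ppv <- function(known, predicted) {
  stopifnot(nrow(known) > 0L)
  m <- match_outputs(known, predicted)
  if (nrow(predicted) == 0L || all(is.na(m$matched_rank)))
    return(list(SN = 0, PPV = 0, matches = m, undefined_ppv = TRUE))
  sn <- sum(m$overlap) / sum(m$known_nt)
  ppv <- sum(m$overlap) / sum(m$output_nt)
  list(SN = min(max(sn, 0), 1), PPV = min(max(ppv, 0), 1),
       matches = m, undefined_ppv = FALSE)
}

#' Log-likelihood ratio of an aligned site set
#'
#' `LLR = sum_k sum_sigma n' f_{k,sigma} log(f_{k,sigma} / b_sigma)` over the
#' K columns of n' aligned K-mer sites, with `0 log 0 := 0` and natural
#' logarithms; equivalently n' times the summed Kullback-Leibler divergence
#' of the column base frequencies from the background.  Nonnegative for any
#' probability background; a zero background frequency with positive column
#' frequency yields `+Inf` with a warning.
#'
#' @param sites character vector of n' equal-length site strings (A/C/G/T).
#' @param background background base frequency 4-vector (A, C, G, T).
#' @return scalar LLR (natural-log units).
#' @export
llr <- function(sites, background = rep(0.25, 4)) {
  stopifnot(length(sites) >= 1L, length(background) == 4L)
  K <- unique(nchar(sites))
  if (length(K) != 1L) stop("all sites must have the same length")
  n <- length(sites)
  codes <- vapply(sites, encode_bases, integer(K), USE.NAMES = FALSE)
  if (K == 1L) codes <- matrix(codes, nrow = 1L)
  total <- 0
  for (k in seq_len(K)) {
    f <- tabulate(codes[k, ], nbins = 4L) / n
    pos <- f > 0
    if (any(background[pos] == 0)) {
      warning("zero background frequency at an observed base; LLR is +Inf")
      return(Inf)
    }
    total <- total + sum(f[pos] * log(f[pos] / background[pos]))
  }
  n * total
}

#' Read/write site tables
#'
#' Sites interchange as a BED-like 1-based inclusive TSV with columns
#' `seq_id`, `start`, `end`, `strand`, `motif_label`, `rank`.
#'
#' @param sites site data frame.
#' @param path file path.
#' @return `write_sites` returns `path` invisibly; `read_sites` the data
#'   frame.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(seq_id = "character"))
  need <- c("seq_id", "start", "end", "strand", "motif_label", "rank")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("site table lacks columns: ", paste(missing, collapse = ", "))
  df
}
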