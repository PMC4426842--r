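DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Watson-Crick complement, reversed.  Vectorised over its argument.
#'
#' @param x character vector of DNA strings over the alphabet A, C, G, T.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("ACGT")   # palindrome: "ACGT"
#' reverse_complement("AAAC")   # "GTTT"
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-ACGT character at position %d of string %d", bad[i], i))
  }
  comp <- chartr("ACGT", "TGCA", x)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

encode_bases <- function(s) {
  code <- match(strsplit(s, "", fixed = TRUE)[[1L]], DNA_BASES)
  if (anyNA(code)) stop("non-ACGT character in sequence")
  code
}

decode_bases <- function(code) paste(DNA_BASES[code], collapse = "")

#' Build the sequence container scanned by the motif sampler
#'
#' Each input sequence is stored together with its reverse complement as one
#' concatenated strand-doubled sequence of length 2L; the sampler places
#' candidate motif sites on either half, so both strands are scanned
#' symmetrically.  Start sites never straddle the boundary between the two
#' halves.
#'
#' @param x character vector of DNA sequences (A/C/G/T only).
#' @param ids sequence identifiers; defaults to names of `x` or `seq1`, ...
#' @return an object of class `motif_seqs`: the forward sequences, their
#'   lengths, integer-encoded concatenated (forward + reverse complement)
#'   sequences, and per-sequence nucleotide counts of the concatenated form.
#' @export
motif_seqs <- function(x, ids = NULL) {
  if (inherits(x, "motif_seqs")) return(x)
  stopifnot(is.character(x), length(x) > 0L)
  if (is.null(ids)) ids <- if (!is.null(names(x))) names(x) else paste0("seq", seq_along(x))
  x <- toupper(x)
  rc <- reverse_complement(x)
  concat <- paste0(x, rc)
  codes <- lapply(concat, encode_bases)
  counts <- vapply(codes, tabulate, integer(4), nbins = 4L)
  rownames(counts) <- DNA_BASES
  structure(list(
    ids = as.character(ids),
    bases = unname(x),
    lengths = nchar(x),
    codes = codes,
    counts = counts,
    total_counts = rowSums(counts)
  ), class = "motif_seqs")
}

#' @export
length.motif_seqs <- function(x) length(x$ids)

#' @export
print.motif_seqs <- function(x, ...) {
  cat(sprintf("motif_seqs: %d sequences, lengths %d-%d bp (scanned with reverse complements)\n",
              length(x), min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Valid motif start sites on a strand-doubled sequence
#'
#' For a sequence of length L and motif width K the admissible starts are
#' 1..L-K+1 on the forward half and L+1..2L-K+1 on the reverse-complement
#' half (1-based), 2(L-K+1) positions in total.
#'
#' @param L sequence length.
#' @param K motif width.
#' @return integer vector of admissible start positions in concatenated
#'   coordinates, or an empty vector when `K > L`.
#' @export
valid_starts <- function(L, K) {
  if (K > L) return(integer(0))
  c(seq_len(L - K + 1L), L + seq_len(L - K + 1L))
}

# Map a start site in concatenated coordinates to forward-strand coordinates.
# Returns list(start, strand) with start the 1-based forward position of the
# leftmost motif base on the forward strand.
site_to_forward <- function(u, L, K) {
  if (u <= L - K + 1L) {
    list(start = u, strand = "+")
  } else {
    list(start = 2L * L + 2L - u - K, strand = "-")
  }
}

# Inverse of site_to_forward.
forward_to_site <- function(start, strand, L, K) {
  if (strand == "+") start else 2L * L + 2L - start - K
}

#' Read sequences from a FASTA file
#'
#' Standard multi-record FASTA (wrapped lines accepted), case-folded to upper
#' case.  Ambiguous IUPAC letters (including N) are replaced by a uniformly
#' drawn base with a warning, which keeps the multinomial model exact; runs
#' meant to be reproducible should set the RNG seed before loading.  Records
#' can optionally be filtered by length.
#'
#' @param path FASTA file.
#' @param min_length,max_length optional length window; out-of-range records
#'   are dropped with a message reporting the count.
#' @return a [motif_seqs] object.
#' @export
read_fasta <- function(path, min_length = NULL, max_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  x <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  n_bad <- 0L
  for (i in seq_along(x)) {
    ch <- strsplit(x[[i]], "", fixed = TRUE)[[1L]]
    bad <- !(ch %in% DNA_BASES)
    if (any(bad)) {
      n_bad <- n_bad + sum(bad)
      ch[bad] <- sample(DNA_BASES, sum(bad), replace = TRUE)
      x[[i]] <- paste(ch, collapse = "")
    }
  }
  if (n_bad > 0L)
    warning(sprintf("replaced %d non-ACGT letters by random bases", n_bad))
  len <- nchar(x)
  keep <- rep(TRUE, length(x))
  if (!is.null(min_length)) keep <- keep & len >= min_length
  if (!is.null(max_length)) keep <- keep & len <= max_length
  if (!all(keep)) {
    message(sprintf("read_fasta: dropped %d/%d records outside length window",
                    sum(!keep), length(keep)))
    x <- x[keep]; ids <- ids[keep]
    if (length(x) == 0L) stop("no sequences left after length filtering")
  }
  motif_seqs(x, ids = ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a [motif_seqs] object (forward strands are written).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- motif_seqs(seqs)
  set <- Biostrings::DNAStringSet(seqs$bases)
  names(set) <- seqs$ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
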