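#' Construct a position probability matrix (PPM)
#'
#' A motif model is a 4 x K matrix of column-stochastic base probabilities
#' (rows A, C, G, T).  Columns must sum to one within `1e-9`.
#'
#' @param mat numeric 4 x K matrix (or K x 4, which is transposed).
#' @return the validated matrix with rownames A, C, G, T and class `ppm`.
#' @export
ppm <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L && ncol(mat) == 4L) mat <- t(mat)
  if (nrow(mat) != 4L) stop("a PPM needs 4 rows (A, C, G, T)")
  if (any(mat < -1e-12) || any(mat > 1 + 1e-12)) stop("PPM entries must lie in [0, 1]")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) stop("PPM columns must sum to 1 (tolerance 1e-9)")
  mat <- pmin(pmax(mat, 0), 1)
  dimnames(mat) <- list(DNA_BASES, NULL)
  class(mat) <- c("ppm", "matrix", "array")
  mat
}

ppm_width <- function(p) ncol(p)

#' @export
print.ppm <- function(x, digits = 3, ...) {
  cat(sprintf("PPM, width %d, consensus %s\n", ncol(x), ppm_consensus(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Consensus string of a PPM
#'
#' @param p a PPM.
#' @return single character string; the modal base per column, in lower case
#'   when its probability is below 0.5.
#' @export
ppm_consensus <- function(p) {
  idx <- apply(p, 2L, which.max)
  ch <- DNA_BASES[idx]
  weak <- p[cbind(idx, seq_len(ncol(p)))] < 0.5
  ch[weak] <- tolower(ch[weak])
  paste(ch, collapse = "")
}

#' Dissimilarity between two PPMs
#'
#' The shorter matrix is slid along the longer one over all
#' `|K_p - K_q| + 1` contiguous offsets; the smallest Frobenius norm between
#' the aligned `K* = min(K_p, K_q)`-column windows is taken, a gap penalty
#' `gap_c * |K_p - K_q|` is added for the width difference, and the sum is
#' divided by `K*`.  The measure is symmetric, nonnegative, and zero exactly
#' for equal-width, equal-column PPMs.
#'
#' @param p,q PPMs (4 x K matrices).
#' @param gap_c gap penalty per column of width difference (default 0.3).
#' @return nonnegative scalar.
#' @export
ppm_dissimilarity <- function(p, q, gap_c = 0.3) {
  stopifnot(gap_c >= 0)
  kp <- ncol(p); kq <- ncol(q)
  if (kp >= kq) { long <- p; short <- q } else { long <- q; short <- p }
  ks <- min(kp, kq)
  dk <- abs(kp - kq)
  best <- Inf
  for (o in 0:dk) {
    d <- long[, o + seq_len(ks), drop = FALSE] - short
    fr <- sqrt(sum(d * d))
    if (fr < best) best <- fr
  }
  (best + gap_c * dk) / ks
}

# Smallest dissimilarity from `p` to any PPM in `others` (Inf when empty).
min_dissimilarity <- function(p, others, gap_c) {
  if (length(others) == 0L) return(Inf)
  min(vapply(others, ppm_dissimilarity, numeric(1), p = p, gap_c = gap_c))
}

#' Log repulsive force of a replica ensemble
#'
#' Each replica interacts with its nearest predecessor in the ensemble
#' ordering: `log psi = sum_i min_{j<i} D(Theta_i, Theta_j)`, with the first
#' replica contributing 0 (empty minimum).  The force is therefore always
#' `>= 0` (psi >= 1) and vanishes when all replicas share one PPM or M = 1.
#'
#' @param ppms list of PPMs, one per replica.
#' @param gap_c gap penalty passed to [ppm_dissimilarity].
#' @return nonnegative scalar, `log psi`.
#' @export
repulsive_force_log <- function(ppms, gap_c = 0.3) {
  M <- length(ppms)
  if (M <= 1L) return(0)
  total <- 0
  for (i in 2:M) {
    total <- total + min_dissimilarity(ppms[[i]], ppms[seq_len(i - 1L)], gap_c)
  }
  total
}

#' Importance weights correcting the repulsion bias
#'
#' Samples drawn under a nonzero force severity beta are biased with respect
#' to the product of independent posteriors; each joint draw of the M replicas
#' is reweighted by the inverse of the repulsive factor it was drawn under.
#' In mode `"exponent"` the raw log-weight is `-sum_i beta_i * minD_i`, the
#' Radon-Nikodym factor of the augmented target actually sampled (this equals
#' `1/psi` when beta is constant at 1); mode `"literal"` uses `1/psi`, i.e.
#' `-log psi`, regardless of beta.  All M replicas of one ensemble share the
#' ensemble weight.
#'
#' @param log_psi numeric vector, `log psi` of each kept ensemble.
#' @param log_repulsion numeric vector, `sum_i beta_i * minD_i` of each kept
#'   ensemble (the beta-weighted analogue of `log_psi`).
#' @param mode `"exponent"` or `"literal"`.
#' @return normalised weights summing to one.
#' @export
importance_weights <- function(log_psi, log_repulsion = log_psi,
                               mode = c("exponent", "literal")) {
  mode <- match.arg(mode)
  lw <- if (mode == "exponent") -log_repulsion else -log_psi
  if (all(!is.finite(lw))) {
    warning("all raw importance weights underflowed; falling back to uniform weights")
    return(rep(1 / length(lw), length(lw)))
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Read motifs in MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME minimal motif file
#' (version header, optional alphabet/background lines, one
#' `letter-probability matrix` block per motif).
#'
#' @param path file in MEME minimal format.
#' @return named list of [ppm] objects; `nsites` attributes are attached when
#'   present in the file.
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  motif_at <- grep("^MOTIF\\s+", lines)
  if (length(motif_at) == 0L) stop("no MOTIF blocks in ", path)
  out <- list()
  for (m in seq_along(motif_at)) {
    start <- motif_at[m]
    end <- if (m < length(motif_at)) motif_at[m + 1L] - 1L else length(lines)
    block <- lines[start:end]
    name <- strsplit(trimws(block[1L]), "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) != 1L) stop("motif ", name, ": missing letter-probability matrix header")
    w <- regmatches(block[hdr], regexec("w=\\s*(\\d+)", block[hdr]))[[1L]][2L]
    ns <- regmatches(block[hdr], regexec("nsites=\\s*(\\d+)", block[hdr]))[[1L]][2L]
    w <- as.integer(w)
    if (is.na(w)) stop("motif ", name, ": header lacks w=")
    rows <- block[(hdr + 1L):(hdr + w)]
    vals <- lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1L]]))
    if (any(vapply(vals, length, 0L) != 4L)) stop("motif ", name, ": malformed matrix row")
    mat <- t(do.call(rbind, vals))
    mat <- sweep(mat, 2L, colSums(mat), "/")  # renormalise printed rounding
    p <- ppm(mat)
    if (!is.na(ns)) attr(p, "nsites") <- as.integer(ns)
    out[[name]] <- p
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param ppms named list of [ppm] objects.
#' @param path output file.
#' @param nsites optional integer vector of site counts per motif.
#' @param background background base frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(ppms, path, nsites = NULL, background = rep(0.25, 4)) {
  if (is.null(names(ppms))) names(ppms) <- paste0("motif_", seq_along(ppms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1], background[2],
                       background[3], background[4]), ""), con)
  for (i in seq_along(ppms)) {
    p <- ppms[[i]]
    ns <- if (!is.null(nsites)) nsites[i] else attr(p, "nsites")
    if (is.null(ns) || is.na(ns)) ns <- 20L
    writeLines(sprintf("MOTIF %s", names(ppms)[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(p), as.integer(ns)), con)
    for (k in seq_len(ncol(p))) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", p[1, k], p[2, k], p[3, k], p[4, k]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
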