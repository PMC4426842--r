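#' Write a full motif discovery report
#'
#' Serialises a clustered motif list to a directory: `motifs.meme` (the
#' representative PPMs in MEME minimal format, `nsites` set to each motif's
#' occupancy count), `sites.tsv` (predicted sites of the enriched motifs as a
#' 1-based BED-like TSV) and `summary.tsv` (rank, width, weight, enrichment,
#' enriched flag, log-likelihood, consensus; sorted by weight rank).
#'
#' @param clusters a [cluster_motifs] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
write_motif_report <- function(clusters, dir) {
  stopifnot(inherits(clusters, "motif_clusters"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  s <- clusters$summary
  ppms <- lapply(clusters$representatives, `[[`, "ppm")
  names(ppms) <- sprintf("motif_%d", s$rank)
  bg <- clusters$representatives[[1L]]$theta0
  meme_path <- file.path(dir, "motifs.meme")
  write_meme(ppms, meme_path, nsites = s$sum_z, background = bg)
  sites_path <- file.path(dir, "sites.tsv")
  write_sites(predicted_sites(clusters), sites_path)
  summary_path <- file.path(dir, "summary.tsv")
  utils::write.table(s, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(motifs = meme_path, sites = sites_path, summary = summary_path))
}
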