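test_that("background generator honours composition, length modes and the seed", {
  set.seed(50)
  bg <- generate_background(500, "fixed", fixed_length = 1000)
  expect_true(all(bg$lengths == 1000L))
  # 5e5 letters: each base frequency within 3 binomial sigma of 0.25
  freq <- bg$total_counts[1:4] / 2  # concatenated counts double every letter
  tot <- 5e5
  expect_true(all(abs(freq / tot - 0.25) < 3 * sqrt(0.25 * 0.75 / tot)))

  set.seed(51)
  v <- generate_background(200, "variable", length_range = c(200L, 2000L))
  expect_true(all(v$lengths >= 200L & v$lengths <= 2000L))
  expect_gt(length(unique(v$lengths)), 20L)

  set.seed(52); a <- generate_background(20, "fixed", fixed_length = 100)
  set.seed(52); b <- generate_background(20, "fixed", fixed_length = 100)
  expect_identical(a$bases, b$bases)

  skewed <- generate_background(50, "fixed", fixed_length = 400,
                                background = c(0.7, 0.1, 0.1, 0.1))
  f <- skewed$total_counts / sum(skewed$total_counts)
  expect_gt(f[1] + f[4], 0.7)   # concatenation symmetrises A with T
})

test_that("planting is a no-op at rate zero and averages the configured rate", {
  set.seed(60)
  bg <- generate_background(100, "fixed", fixed_length = 300)
  none <- plant_motifs(bg, list(example_ppm("GGATTCGC")), mean_motifs = 0)
  expect_identical(none$sequences$bases, bg$bases)
  expect_identical(nrow(none$truth), 0L)

  set.seed(61)
  bg2 <- generate_background(2000, "fixed", fixed_length = 1000)
  planted <- plant_motifs(bg2, list(example_ppm("GGATTCGC")), mean_motifs = 8)
  rate <- nrow(planted$truth) / 2000
  expect_lt(abs(rate - 8), 3 * sqrt(8 / 2000))
})

test_that("ground truth and emitted sequences are mutually consistent", {
  ppms <- list(gc = example_ppm("GGGCGGAG", strength = 0.85),
               at = example_ppm("TTATAATA", strength = 0.85))
  dat <- simulate_motif_data(n = 60, length_mode = "fixed", fixed_length = 200,
                             ppms = ppms, mean_motifs = 3, seed = 62)
  expect_gt(nrow(dat$truth), 50)
  for (r in seq_len(nrow(dat$truth))) {
    row <- dat$truth[r, ]
    i <- match(row$seq_id, dat$sequences$ids)
    oligo <- substr(dat$sequences$bases[i], row$start, row$end)
    if (row$strand == "-") oligo <- reverse_complement(oligo)
    p <- unclass(ppms[[row$motif_label]])
    code <- match(strsplit(oligo, "")[[1]], c("A", "C", "G", "T"))
    expect_true(all(p[cbind(code, seq_along(code))] > 0))
  }
  # planted instances never overlap within a sequence
  by_seq <- split(dat$truth, dat$truth$seq_id)
  for (tb in by_seq) {
    tb <- tb[order(tb$start), ]
    if (nrow(tb) > 1) expect_true(all(tb$start[-1] > tb$end[-nrow(tb)]))
  }
})

test_that("planted column frequencies converge to the source PPM", {
  src <- example_ppm("GCGTAACG", strength = 0.8)
  dat <- simulate_motif_data(n = 1300, length_mode = "fixed", fixed_length = 200,
                             ppms = list(src = src), mean_motifs = 8, seed = 63)
  expect_gt(nrow(dat$truth), 9000)
  oligos <- vapply(seq_len(nrow(dat$truth)), function(r) {
    row <- dat$truth[r, ]
    i <- match(row$seq_id, dat$sequences$ids)
    s <- substr(dat$sequences$bases[i], row$start, row$end)
    if (row$strand == "-") reverse_complement(s) else s
  }, character(1))
  codes <- vapply(oligos, function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T")),
                  integer(8), USE.NAMES = FALSE)
  for (k in 1:8) {
    f <- tabulate(codes[k, ], 4) / length(oligos)
    expect_lt(sum(abs(f - unclass(src)[, k])) / 2, 0.05)
  }
})

test_that("bernoulli count model plants at most one instance per sequence", {
  dat <- simulate_motif_data(n = 200, length_mode = "fixed", fixed_length = 100,
                             ppms = list(m = example_ppm("GGATCGCC")),
                             mean_motifs = 0.7, count_model = "bernoulli", seed = 64)
  expect_true(all(table(dat$truth$seq_id) == 1L))
  expect_lt(abs(nrow(dat$truth) / 200 - 0.7), 3 * sqrt(0.7 * 0.3 / 200))
})

test_that("the packaged synthetic motif collection loads as valid PPMs", {
  ppms <- read_meme(synthetic_motif_file())
  expect_length(ppms, 10L)
  widths <- vapply(ppms, ncol, integer(1))
  expect_true(all(widths >= 8L & widths <= 15L))
  for (p in ppms) expect_equal(unname(colSums(p)), rep(1, ncol(p)), tolerance = 1e-6)
})
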