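# Sliding-window variation frequencies, ARG/DR and region calling.

# brute-force recount oracle: loop over every window and variant
brute_window_counts <- function(variants, genome, window, step) {
  out <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    len <- genome$length[ci]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    for (ws in starts) {
      we <- min(ws + window, len)
      if ((we - ws) < step && ws != 0L) next
      for (s in unique(variants$sample_id)) {
        for (g in unique(resevar:::variant_group(variants$type))) {
          n <- sum(variants$chrom == ch & variants$pos >= ws &
                     variants$pos < we & variants$sample_id == s &
                     resevar:::variant_group(variants$type) == g)
          out[[length(out) + 1L]] <- tibble::tibble(
            chrom = ch, start = as.integer(ws), end = as.integer(we),
            sample_id = s, group = g, count = as.integer(n))
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

full_masks <- function(genome, samples) {
  tidyr::expand_grid(sample_id = samples,
                     tibble::tibble(chrom = genome$chrom, start = 0L,
                                    end = genome$length))
}

test_that("window counts equal a brute-force recount on random fixtures", {
  set.seed(301)
  genome <- tibble::tibble(chrom = c("c1", "c2"), seq = "",
                           length = c(260000L, 140000L))
  samples <- c("S1", "S2")
  v <- resevar:::as_variant_tbl(tibble::tibble(
    sample_id = sample(samples, 400, TRUE),
    chrom = sample(genome$chrom, 400, TRUE),
    pos = as.integer(ifelse(
      sample(genome$chrom, 400, TRUE) == "c1",
      sample(260000L, 400, TRUE), sample(140000L, 400, TRUE)) - 1L),
    ref = "A",
    alt = sample(c("C", "G", "T"), 400, TRUE),
    type = sample(c("SNP", "SNP", "INS", "DEL", "SV"), 400, TRUE),
    zygosity = "hom", qual = 60, support = 10L))
  v <- dplyr::filter(
    v, pos < genome$length[match(chrom, genome$chrom)])
  v <- dplyr::distinct(v, sample_id, chrom, pos, .keep_all = TRUE)
  scan <- window_frequencies(v, full_masks(genome, samples), genome)
  want <- brute_window_counts(v, genome, 100000L, 50000L)
  got <- dplyr::arrange(tidy(scan)[, names(want)],
                        chrom, start, sample_id, group)
  want <- dplyr::arrange(want, chrom, start, sample_id, group)
  expect_equal(as.data.frame(got), as.data.frame(want))
  # a variant at 60 kb is counted in [0,100k) and [50k,150k)
  hits <- dplyr::filter(tidy(scan), chrom == "c1", sample_id == "S1")
  v60 <- resevar:::as_variant_tbl(tibble::tibble(
    sample_id = "S1", chrom = "c1", pos = 60000L, ref = "A", alt = "G",
    type = "SNP", zygosity = "hom", qual = 60, support = 10L))
  s60 <- window_frequencies(v60, full_masks(genome, "S1"), genome)
  w <- dplyr::filter(tidy(s60), count > 0)
  expect_identical(sort(w$start), c(0L, 50000L))
})

test_that("step-disjoint windows conserve total counts per chromosome", {
  ds <- tiny_dataset()
  scan <- window_frequencies(ds$variants, ds$mask, ds$genome,
                             window = 20000L, step = 10000L)
  w <- tidy(scan)
  disjoint <- dplyr::filter(w, start %% 20000L == 0L)
  per_chr <- dplyr::count(
    dplyr::mutate(ds$variants, group = resevar:::variant_group(type)),
    chrom, sample_id, group, name = "n")
  agg <- dplyr::summarise(
    dplyr::group_by(disjoint, chrom, sample_id, group),
    n = sum(count), .groups = "drop")
  joined <- dplyr::left_join(per_chr, agg,
                             by = c("chrom", "sample_id", "group"))
  expect_equal(joined$n.x, joined$n.y)
})

test_that("frequencies, masking and the ARG follow their definitions", {
  genome <- tibble::tibble(chrom = "c1", seq = "", length = 200000L)
  # sample covered everywhere except a window left almost uncovered
  mask <- tibble::tibble(
    sample_id = "S1", chrom = "c1",
    start = c(0L, 199000L), end = c(150000L, 200000L))
  v <- resevar:::as_variant_tbl(tibble::tibble(
    sample_id = "S1", chrom = "c1",
    pos = as.integer(seq(1000, 99000, length.out = 10)), ref = "A",
    alt = "G", type = "SNP", zygosity = "hom", qual = 60, support = 10L))
  scan <- window_frequencies(v, mask, genome)
  w <- tidy(scan)
  # fully covered first window: frequency 10 / 100000
  w0 <- dplyr::filter(w, start == 0L)
  expect_equal(w0$freq, 1e-4)
  # window [150k,200k+): only 1 kb of 50 kb covered -> masked
  w150 <- dplyr::filter(w, start == 150000L)
  expect_true(w150$masked)
  arg <- compute_arg(scan)
  unmasked <- dplyr::filter(w, !masked)
  expect_equal(arg$arg, mean(unmasked$freq))
  expect_error(window_frequencies(v, mask, genome, window = 100000L,
                                  step = 30000L), "multiple of step")
})

test_that("uniform density gives ARG = density and DR = n_samples", {
  genome <- tibble::tibble(chrom = "c1", seq = "", length = 200000L)
  samples <- c("S1", "S2", "S3")
  # one variant every 1 kb in every sample: density 1e-3 everywhere
  pos <- as.integer(seq(500, 199500, by = 1000))
  v <- resevar:::as_variant_tbl(tidyr::expand_grid(
    sample_id = samples, pos = pos) |>
    dplyr::mutate(chrom = "c1", ref = "A", alt = "G", type = "SNP",
                  zygosity = "hom", qual = 60, support = 10L))
  scan <- window_frequencies(v, full_masks(genome, samples), genome)
  arg <- compute_arg(scan)
  expect_equal(arg$arg, 1e-3, tolerance = 1e-9)
  dr <- compute_dr(scan, arg)
  expect_true(all(abs(dr$dr - 3) < 1e-9))
  # single unmasked window: ARG equals that window's frequency
  one <- dplyr::filter(tidy(scan), start == 0L, sample_id == "S1")
  sub <- scan; sub$windows <- dplyr::filter(scan$windows, start == 0L,
                                            sample_id == "S1")
  expect_equal(compute_arg(sub)$arg, one$freq)
})

test_that("region calling uses strict thresholds and recovers planted
           regions with exact window boundaries", {
  genome <- tibble::tibble(chrom = "c1", seq = "", length = 500000L)
  samples <- c("S1", "S2")
  # background density 1e-4; hotspot at [200k,250k) with 10x density in
  # both samples; cold (zero-variant) windows beyond 400k
  bg_pos <- as.integer(seq(5000, 395000, by = 10000))
  hot_pos <- as.integer(seq(200100, 249900, by = 200))
  v <- resevar:::as_variant_tbl(tidyr::expand_grid(
    sample_id = samples, pos = c(bg_pos, hot_pos)) |>
    dplyr::mutate(chrom = "c1", ref = "A", alt = "G", type = "SNP",
                  zygosity = "hom", qual = 60, support = 10L))
  scan <- window_frequencies(v, full_masks(genome, samples), genome)
  arg <- compute_arg(scan)
  regions <- call_regions(scan, arg)
  high <- dplyr::filter(regions, label == "high", sample_id == "S1")
  # hotspot windows: [150k,250k), [200k,300k) overlap the spike
  expect_identical(nrow(high), 1L)
  expect_identical(high$start, 150000L)
  expect_identical(high$end, 300000L)
  low <- dplyr::filter(regions, label == "low", sample_id == "S1")
  expect_identical(nrow(low), 1L)
  expect_identical(low$start, 400000L)
  expect_identical(low$end, 500000L)
  # identical labels across both samples -> same regions in the intersection
  both <- intersect_regions(scan, samples, arg)
  expect_identical(dplyr::filter(both, label == "high")$start, 150000L)
  expect_identical(dplyr::filter(both, label == "high")$end, 300000L)
  # boundary convention: a window at exactly 4x ARG is not high
  lab_freqs <- dplyr::left_join(scan$windows, arg, by = "group")
  exact <- dplyr::select(
    dplyr::mutate(lab_freqs, freq = 4 * arg, masked = FALSE), -arg)
  sub <- scan; sub$windows <- exact
  expect_identical(nrow(dplyr::filter(call_regions(sub, arg),
                                      label == "high")), 0L)
})

test_that("raising the high threshold never increases high regions", {
  ds <- tiny_dataset()
  scan <- window_frequencies(ds$variants, ds$mask, ds$genome,
                             window = 20000L, step = 10000L)
  arg <- compute_arg(scan)
  n_high <- vapply(c(1.5, 2, 4, 8), function(f) {
    sum(dplyr::filter(call_regions(scan, arg, high_fold = f),
                      label == "high")$n_windows)
  }, double(1))
  expect_true(all(diff(n_high) <= 0))
})
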