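# Sliding-window variation-frequency profiles, the whole-genome average
# rate (ARG), per-window deviation ratios (DR) and high/low-variation
# region calling.
#
# Windows start at 0, step, 2*step, ...; with the default 100 kb window and
# 50 kb step every variant falls in at most two windows. Frequency is the
# variant count divided by the covered bases in the window (uncovered
# nucleotides excluded); windows with under `min_covered_frac` of their
# span covered are masked from the ARG and from region calling.

window_grid <- function(genome, window, step) {
  bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    ends <- pmin(starts + window, len)
    keep <- (ends - starts) >= step | starts == 0L
    tibble(chrom = genome$chrom[i], start = as.integer(starts[keep]),
           end = as.integer(ends[keep]))
  }))
}

#' Windowed variation frequencies
#'
#' @param variants Variant tibble (all samples to be scanned).
#' @param masks Coverage-mask tibble.
#' @param genome Genome tibble (defines chromosome lengths).
#' @param window Window size in bp (default 100 kb).
#' @param step Step size in bp (default 50 kb); `window` must be a multiple
#'   of `step`.
#' @param min_covered_frac Windows with a smaller covered fraction of their
#'   span are masked (default 0.1).
#' @return A `window_scan` object. `tidy()` returns the per-window tibble
#'   (`chrom`, `start`, `end`, `sample_id`, `group`, `count`, `covered`,
#'   `freq`, `masked`); `glance()` returns the per-type ARG.
#' @export
window_frequencies <- function(variants, masks, genome, window = 100000L,
                               step = 50000L, min_covered_frac = 0.1) {
  if (window %% step != 0) {
    stop("window size must be a multiple of step", call. = FALSE)
  }
  grid <- window_grid(genome, window, step)
  samples <- sort(unique(variants$sample_id))
  groups <- sort(unique(variant_group(variants$type)))
  if (!length(groups)) groups <- "SNP"
  v <- variants |> mutate(group = variant_group(.data$type))
  # count variants per window: each variant hits the windows whose span
  # contains its position (at most window/step of them)
  k_max <- window %/% step
  counts <- bind_rows(lapply(seq_len(k_max), function(k) {
    v |> mutate(wstart = (.data$pos %/% step - (k - 1L)) * step) |>
      filter(.data$wstart >= 0)
  })) |>
    count(.data$chrom, .data$wstart, .data$sample_id, .data$group,
          name = "count") |>
    rename(start = "wstart")
  full <- tidyr::expand_grid(grid,
                             sample_id = samples, group = groups) |>
    left_join(counts, by = c("chrom", "start", "sample_id", "group")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
  # covered bases per window per sample
  cov_tbl <- grid |>
    tidyr::expand_grid(sample_id = samples) |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      m <- masks |> filter(.data$sample_id == key$sample_id)
      df$covered <- covered_in_window(df$start, df$end, df$chrom, m)
      df
    }) |>
    ungroup()
  out <- full |>
    inner_join(cov_tbl, by = c("chrom", "start", "end", "sample_id")) |>
    mutate(
      masked = .data$covered < min_covered_frac * (.data$end - .data$start),
      freq = if_else(.data$masked | .data$covered == 0L, NA_real_,
                     .data$count / .data$covered)) |>
    arrange(.data$chrom, .data$start, .data$sample_id, .data$group)
  structure(list(windows = out, window = window, step = step,
                 samples = samples, groups = groups),
            class = "window_scan")
}

#' Average variation rate over the whole genome (ARG)
#'
#' Arithmetic mean of the unmasked window frequencies across all
#' chromosomes, per variant type, pooled across samples (per-sample ARG via
#' `per_sample = TRUE`).
#'
#' @param scan A `window_scan` object (or its `tidy()` tibble).
#' @param per_sample Compute one ARG per sample instead of pooling.
#' @return A tibble `group`, (`sample_id`,) `arg`.
#' @export
compute_arg <- function(scan, per_sample = FALSE) {
  w <- if (inherits(scan, "window_scan")) scan$windows else scan
  w <- w |> filter(!.data$masked)
  if (!nrow(w)) stop("all windows are masked; cannot compute ARG",
                     call. = FALSE)
  if (per_sample) {
    w |> group_by(.data$group, .data$sample_id) |>
      summarise(arg = mean(.data$freq), .groups = "drop")
  } else {
    w |> group_by(.data$group) |>
      summarise(arg = mean(.data$freq), .groups = "drop")
  }
}

#' Per-window deviation ratio (DR)
#'
#' Sum over samples of (window rate / ARG) per variant type; `NA` where any
#' in-scope sample is masked.
#'
#' @param scan A `window_scan` object.
#' @param arg Output of [compute_arg()]; computed if missing.
#' @return A tibble `chrom`, `start`, `end`, `group`, `dr`.
#' @export
compute_dr <- function(scan, arg = NULL) {
  if (is.null(arg)) arg <- compute_arg(scan)
  scan$windows |>
    left_join(arg, by = "group") |>
    group_by(.data$chrom, .data$start, .data$end, .data$group) |>
    summarise(dr = if (any(.data$masked)) NA_real_
              else sum(.data$freq / .data$arg), .groups = "drop")
}

#' Call high/low-variation regions
#'
#' A window is labeled `high` if its rate is strictly greater than
#' `high_fold` times the ARG, `low` if strictly below `ARG / low_fold`;
#' boundary-equal windows are unlabeled. Adjacent (overlapping or abutting)
#' same-label windows are merged into regions.
#'
#' @param scan A `window_scan` object.
#' @param arg Output of [compute_arg()]; computed if missing.
#' @param high_fold High-region multiplier (default 4).
#' @param low_fold Low-region divisor (default 20).
#' @return A region tibble: `sample_id`, `group`, `chrom`, `start`, `end`,
#'   `label`, `n_windows`.
#' @export
call_regions <- function(scan, arg = NULL, high_fold = 4, low_fold = 20) {
  if (is.null(arg)) arg <- compute_arg(scan)
  lab <- scan$windows |>
    left_join(arg, by = "group") |>
    mutate(label = dplyr::case_when(
      .data$masked ~ NA_character_,
      .data$freq > high_fold * .data$arg ~ "high",
      .data$freq < .data$arg / low_fold ~ "low",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$label))
  merge_labeled_windows(lab, c("sample_id", "group", "label"))
}

#' Regions with the same label across samples
#'
#' Windows where every in-scope sample carries the same high/low label,
#' merged into regions — the pair or three-way "identical region" rule.
#'
#' @param scan A `window_scan` object.
#' @param samples Samples in scope (default all in the scan).
#' @param arg,high_fold,low_fold As in [call_regions()].
#' @return A region tibble: `group`, `chrom`, `start`, `end`, `label`,
#'   `n_windows`, plus a `scope` string.
#' @export
intersect_regions <- function(scan, samples = NULL, arg = NULL,
                              high_fold = 4, low_fold = 20) {
  if (is.null(samples)) samples <- scan$samples
  if (is.null(arg)) arg <- compute_arg(scan)
  lab <- scan$windows |>
    filter(.data$sample_id %in% samples) |>
    left_join(arg, by = "group") |>
    mutate(label = dplyr::case_when(
      .data$masked ~ NA_character_,
      .data$freq > high_fold * .data$arg ~ "high",
      .data$freq < .data$arg / low_fold ~ "low",
      TRUE ~ NA_character_)) |>
    group_by(.data$chrom, .data$start, .data$end, .data$group) |>
    filter(dplyr::n() == length(samples), !any(is.na(.data$label)),
           dplyr::n_distinct(.data$label) == 1) |>
    summarise(label = first(.data$label), .groups = "drop")
  out <- merge_labeled_windows(lab, c("group", "label"))
  out$scope <- paste(samples, collapse = "+")
  out
}

merge_labeled_windows <- function(lab, keys) {
  if (!nrow(lab)) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  label = character(), n_windows = integer())
    for (k in setdiff(keys, "label")) out[[k]] <- character()
    return(out)
  }
  lab |>
    group_by(dplyr::across(dplyr::all_of(c(keys, "chrom")))) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      ov <- IRanges::countOverlaps(ir, IRanges::IRanges(df$start + 1L,
                                                        df$end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
             n_windows = as.integer(ov))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

#' @export
print.window_scan <- function(x, ...) {
  cat("<window_scan> window", x$window, "bp, step", x$step, "bp;",
      length(unique(x$windows$chrom)), "chromosome(s),",
      length(x$samples), "sample(s)\n")
  print(glance(x))
  invisible(x)
}

#' @rdname window_frequencies
#' @param x A `window_scan` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.window_scan <- function(x, ...) x$windows

#' @rdname window_frequencies
#' @exportS3Method generics::glance
glance.window_scan <- function(x, ...) {
  arg <- compute_arg(x)
  arg$n_windows <- nrow(distinct(x$windows, .data$chrom, .data$start))
  arg$n_masked <- x$windows |>
    filter(.data$masked) |>
    distinct(.data$chrom, .data$start, .data$sample_id) |> nrow()
  arg
}
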