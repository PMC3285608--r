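# Multi-sample locus classification: shared / different / unique /
# ineligible under the coverage-eligibility rule, with pairwise, three-way
# and union summaries.
#
# Locus identity: SNPs and InDels are keyed by (chrom, pos, type); the
# allele that decides shared-ness is the full ALT string, so "shared" for an
# InDel means the same inserted/deleted sequence. SVs are matched across
# samples by equal type plus reciprocal span overlap (default >= 50%).

locus_alt_key <- function(v) paste(v$chrom, v$pos, v$type, v$alt, sep = "|")

# Assign a shared locus id to SVs across samples: same chrom+type and
# reciprocal overlap >= min_frac are the same locus (connected components).
sv_locus_ids <- function(sv, min_frac = 0.5) {
  if (!nrow(sv)) return(character(0))
  sv$idx <- seq_len(nrow(sv))
  parent <- sv$idx
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (grp in split(sv, paste(sv$chrom, sv$sv_type))) {
    if (nrow(grp) < 2) next
    ir <- IRanges::IRanges(grp$pos + 1L, grp$sv_end)
    hits <- IRanges::findOverlaps(ir, ir)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- qi < si
    qi <- qi[keep]; si <- si[keep]
    for (k in seq_along(qi)) {
      w <- IRanges::width(IRanges::pintersect(ir[qi[k]], ir[si[k]]))
      if (w / IRanges::width(ir[qi[k]]) >= min_frac &&
          w / IRanges::width(ir[si[k]]) >= min_frac) {
        ri <- find(grp$idx[qi[k]]); rj <- find(grp$idx[si[k]])
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(sv$idx, find, integer(1))
  paste0(sv$chrom[match(roots, sv$idx)], "|sv", roots)
}

locus_ids <- function(variants, sv_min_overlap = 0.5) {
  ids <- character(nrow(variants))
  is_sv <- variants$type == "SV"
  ids[!is_sv] <- paste(variants$chrom[!is_sv], variants$pos[!is_sv],
                       variants$type[!is_sv], sep = "|")
  if (any(is_sv)) {
    ids[is_sv] <- sv_locus_ids(variants[is_sv, , drop = FALSE],
                               sv_min_overlap)
  }
  ids
}

#' Determine comparison-eligible loci
#'
#' A locus enters between-sample comparison only if every compared sample
#' has coverage at its position (the at-least-one-mapped-read rule).
#'
#' @param variants Variant tibble for the compared samples.
#' @param masks Coverage-mask tibble containing every compared sample.
#' @param samples Samples to compare; default all in `variants`.
#' @return A tibble of distinct loci (`locus`, `chrom`, `pos`, `type`) with
#'   an `eligible` flag.
#' @export
eligible_loci <- function(variants, masks, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  missing_masks <- setdiff(samples, unique(masks$sample_id))
  if (length(missing_masks)) {
    stop("no coverage mask for sample(s): ",
         paste(missing_masks, collapse = ", "), call. = FALSE)
  }
  v <- variants |> filter(.data$sample_id %in% samples)
  v$locus <- locus_ids(v)
  loci <- v |> distinct(.data$locus, .keep_all = TRUE) |>
    select(dplyr::all_of(c("locus", "chrom", "pos", "type")))
  elig <- rep(TRUE, nrow(loci))
  for (s in samples) {
    m <- masks |> filter(.data$sample_id == s)
    elig <- elig & positions_covered(loci$chrom, loci$pos, m)
  }
  loci$eligible <- elig
  loci
}

classify_alts <- function(alts, n_samples) {
  n_car <- length(alts)
  if (n_car == 0) stop("locus with no non-reference sample", call. = FALSE)
  if (n_car == n_samples) {
    if (length(unique(alts)) == 1) "shared"
    else if (!anyDuplicated(alts)) "different"
    else "partial"
  } else if (n_car == 1) "unique"
  else "partial"
}

#' Classify a single locus from per-sample alternate alleles
#'
#' @param alts Named character vector: the non-reference allele carried by
#'   each carrying sample (omit samples that are reference).
#' @param samples All compared samples (all assumed covered at the locus).
#' @return One of `"shared"`, `"different"`, `"unique"`, `"partial"`.
#' @export
classify_locus <- function(alts, samples) {
  stopifnot(all(names(alts) %in% samples))
  classify_alts(unname(alts), length(samples))
}

#' Compare variant sets across samples
#'
#' Classifies every variant locus across the compared samples into
#' shared (identical alternate allele in every sample), different (every
#' sample non-reference with pairwise-distinct alleles), unique (exactly
#' one sample non-reference), partial (any other carrier pattern, only
#' possible with 3+ samples), or ineligible (some compared sample lacks
#' coverage at the locus).
#'
#' @param variants Variant tibble covering the compared samples.
#' @param masks Coverage-mask tibble.
#' @param samples Samples to compare (2 or more); default all.
#' @param require_coverage If `FALSE`, skip the eligibility rule (all loci
#'   compared).
#' @param sv_min_overlap Reciprocal-overlap fraction for SV locus matching.
#' @return A `variant_comparison` object; `tidy()` gives the per-locus
#'   classification, `glance()` the class-by-type counts.
#' @export
compare_samples <- function(variants, masks = NULL, samples = NULL,
                            require_coverage = TRUE, sv_min_overlap = 0.5) {
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  if (length(samples) < 2) stop("need at least two samples", call. = FALSE)
  v <- variants |> filter(.data$sample_id %in% samples)
  v$locus <- locus_ids(v, sv_min_overlap)
  if (require_coverage) {
    if (is.null(masks)) stop("masks required when require_coverage = TRUE",
                             call. = FALSE)
    el <- eligible_loci(v, masks, samples)
    elig_map <- setNames(el$eligible, el$locus)
  } else {
    elig_map <- NULL
  }
  per_locus <- v |>
    group_by(.data$locus) |>
    summarise(
      chrom = first(.data$chrom), pos = min(.data$pos),
      type = first(.data$type),
      carriers = list(setNames(.data$alt, .data$sample_id)),
      n_carriers = dplyr::n_distinct(.data$sample_id),
      .groups = "drop")
  cls <- vapply(per_locus$carriers, function(a) {
    classify_alts(unname(a), length(samples))
  }, character(1))
  if (!is.null(elig_map)) {
    cls[!elig_map[per_locus$locus]] <- "ineligible"
  }
  per_locus$class <- cls
  structure(
    list(loci = per_locus, samples = samples,
         require_coverage = require_coverage),
    class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("<variant_comparison> of", length(x$samples), "samples:",
      paste(x$samples, collapse = ", "), "\n")
  print(glance(x))
  invisible(x)
}

#' @rdname compare_samples
#' @param x A `variant_comparison` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.variant_comparison <- function(x, ...) {
  x$loci |>
    mutate(alts = purrr::map_chr(.data$carriers,
                                 ~ paste(unname(.x), collapse = ","))) |>
    select(dplyr::all_of(c("locus", "chrom", "pos", "type", "class",
                           "n_carriers", "alts")))
}

#' @rdname compare_samples
#' @exportS3Method generics::glance
glance.variant_comparison <- function(x, ...) {
  x$loci |>
    mutate(group = variant_group(.data$type)) |>
    count(.data$group, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
}

#' Per-chromosome shared/different counts for a pair of samples
#'
#' @param variants,masks As for [compare_samples()].
#' @param pair Character vector of the two samples.
#' @param ... Passed to [compare_samples()].
#' @return A tibble: `chrom`, `group` (SNP/InDel/SV), `shared`, `different`,
#'   `unique`, `ineligible` counts.
#' @export
pairwise_summary <- function(variants, masks, pair, ...) {
  stopifnot(length(pair) == 2)
  cmp <- compare_samples(variants, masks, samples = pair, ...)
  comparison_table(cmp)
}

#' Per-chromosome class counts for a three-way comparison
#'
#' @param variants,masks As for [compare_samples()].
#' @param samples The three samples; default all.
#' @param ... Passed to [compare_samples()].
#' @return As [pairwise_summary()].
#' @export
threeway_summary <- function(variants, masks, samples = NULL, ...) {
  cmp <- compare_samples(variants, masks, samples = samples, ...)
  comparison_table(cmp)
}

comparison_table <- function(cmp) {
  cmp$loci |>
    mutate(group = variant_group(.data$type)) |>
    count(.data$chrom, .data$group, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L) |>
    (\(df) {
      for (cl in c("shared", "different", "unique", "partial", "ineligible")) {
        if (!cl %in% names(df)) df[[cl]] <- 0L
      }
      df
    })() |>
    arrange(.data$chrom, .data$group)
}

#' Non-redundant union size by inclusion-exclusion
#'
#' Computes |A u B u C| = sum of per-sample totals minus the pairwise
#' shared counts plus the three-way shared count. Works for two samples as
#' well (pass one pairwise count and `threeway_shared = 0`).
#'
#' @param totals Per-sample variant totals.
#' @param pairwise_shared Shared counts for each unordered sample pair.
#' @param threeway_shared Count shared by all three samples.
#' @return The union size (scalar).
#' @export
union_accounting <- function(totals, pairwise_shared, threeway_shared = 0) {
  if (any(pairwise_shared < threeway_shared)) {
    stop("inconsistent counts: pairwise shared < three-way shared",
         call. = FALSE)
  }
  out <- sum(totals) - sum(pairwise_shared) + threeway_shared
  if (out < 0 || out > sum(totals)) {
    stop("inconsistent counts: union outside [0, sum of totals]",
         call. = FALSE)
  }
  out
}

#' Direct non-redundant union of variant records
#'
#' Counts distinct variant events (locus + alternate allele) across
#' samples; the set-theoretic check on [union_accounting()].
#'
#' @param variants Variant tibble.
#' @return Number of distinct (chrom, pos, type, alt) events.
#' @export
union_size <- function(variants) {
  v <- variants
  v$locus <- locus_ids(v)
  dplyr::n_distinct(paste(v$locus, v$alt))
}
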