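# Report tables, heterozygosity, GO/PFAM tallies and the cross-checking
# arithmetic that ties the stages together.

#' Per-chromosome variant count table
#'
#' @param variants Variant tibble.
#' @param genome Optional genome tibble; chromosomes absent from it raise
#'   an error.
#' @param totals Append a `"Total"` row per sample x type.
#' @return A tibble `chrom`, `sample_id`, `group`, `count`.
#' @export
per_chromosome_table <- function(variants, genome = NULL, totals = FALSE) {
  if (!is.null(genome)) {
    bad <- setdiff(unique(variants$chrom), genome$chrom)
    if (length(bad)) {
      stop("chromosome(s) absent from genome: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  out <- variants |>
    mutate(group = variant_group(.data$type)) |>
    count(.data$chrom, .data$sample_id, .data$group, name = "count")
  if (totals) {
    tot <- out |>
      group_by(.data$sample_id, .data$group) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      mutate(chrom = "Total")
    out <- bind_rows(out, tot)
  }
  out
}

#' Per-sample heterozygosity rate
#'
#' Heterozygous calls divided by the covered bases of the sample's mask.
#'
#' @param variants Variant tibble with `zygosity`.
#' @param masks Coverage-mask tibble.
#' @return A tibble `sample_id`, `n_het`, `covered`, `het_rate`.
#' @export
heterozygosity_rate <- function(variants, masks) {
  cov <- covered_bases(masks) |>
    group_by(.data$sample_id) |>
    summarise(covered = sum(.data$covered), .groups = "drop")
  samples <- sort(unique(variants$sample_id))
  uncovered <- setdiff(samples, cov$sample_id[cov$covered > 0])
  if (length(uncovered) || any(cov$covered == 0)) {
    stop("zero covered bases for sample(s): ",
         paste(union(uncovered, cov$sample_id[cov$covered == 0]),
               collapse = ", "), call. = FALSE)
  }
  het <- variants |>
    filter(.data$zygosity == "het") |>
    count(.data$sample_id, name = "n_het")
  cov |>
    left_join(het, by = "sample_id") |>
    mutate(n_het = dplyr::coalesce(.data$n_het, 0L),
           het_rate = .data$n_het / .data$covered) |>
    select(dplyr::all_of(c("sample_id", "n_het", "covered", "het_rate")))
}

#' Top GO/PFAM terms among genes carrying variants
#'
#' Counts distinct genes per term (default) or variants per term among the
#' supplied gene-mapped variants, ranks descending with a deterministic
#' alphabetical tie-break, and returns the top `n` per namespace. Genes
#' absent from the mapping are tallied under `"unannotated"`.
#'
#' @param mapped Variants with a `gene_id` column (see
#'   [map_variants_to_genes()]); rows with `NA` gene are ignored.
#' @param term_map Tibble `gene_id`, `namespace`, `term` (see
#'   [read_gene_term_map()]).
#' @param n Top terms to keep per namespace (default 10).
#' @param level `"gene"` (count distinct genes) or `"variant"`.
#' @return A tibble `namespace`, `term`, `count`, `rank`.
#' @export
go_top_tally <- function(mapped, term_map, n = 10, level = c("gene",
                                                             "variant")) {
  level <- match.arg(level)
  v <- mapped |> filter(!is.na(.data$gene_id))
  namespaces <- unique(term_map$namespace)
  if (!length(namespaces)) namespaces <- "GO"
  joined <- v |> left_join(term_map, by = "gene_id",
                           relationship = "many-to-many")
  un <- joined |> filter(is.na(.data$term))
  ann <- joined |> filter(!is.na(.data$term))
  tally_one <- function(df) {
    if (level == "gene") {
      df |> group_by(.data$namespace, .data$term) |>
        summarise(count = dplyr::n_distinct(.data$gene_id),
                  .groups = "drop")
    } else {
      df |> count(.data$namespace, .data$term, name = "count")
    }
  }
  out <- tally_one(ann)
  if (nrow(un)) {
    n_un <- if (level == "gene") dplyr::n_distinct(un$gene_id) else nrow(un)
    message(n_un, " gene(s)/variant(s) without annotation counted as ",
            "'unannotated'")
    out <- bind_rows(out, tibble(namespace = namespaces[1],
                                 term = "unannotated", count = n_un))
  }
  out |>
    arrange(.data$namespace, dplyr::desc(.data$count), .data$term) |>
    group_by(.data$namespace) |>
    mutate(rank = row_number()) |>
    filter(.data$rank <= n) |>
    ungroup()
}

#' Non-synonymous/synonymous ratio per protein domain
#'
#' Descriptive report of the per-domain Non-syn/Syn SNP ratio (domains such
#' as leucine-rich repeats and NB-ARC are expected to rank high in disease
#' -resistance gene families). Optionally a per-domain binomial test
#' against the genome-wide Non-syn fraction, Benjamini-Hochberg adjusted.
#'
#' @param effects Output of [classify_snp_effects()].
#' @param term_map Gene-to-domain map (namespace `"PFAM"` rows used; all
#'   rows if none).
#' @param test Run per-domain binomial tests (default FALSE).
#' @return A tibble `term`, `syn`, `nonsyn`, `ratio` (and test columns).
#' @export
domain_ns_ratio <- function(effects, term_map, test = FALSE) {
  pf <- term_map |> filter(.data$namespace == "PFAM")
  if (!nrow(pf)) pf <- term_map
  e <- effects |>
    filter(.data$effect %in% c("synonymous", "nonsynonymous")) |>
    inner_join(pf, by = "gene_id", relationship = "many-to-many")
  out <- e |>
    group_by(.data$term) |>
    summarise(syn = sum(.data$effect == "synonymous"),
              nonsyn = sum(.data$effect == "nonsynonymous"),
              .groups = "drop") |>
    mutate(ratio = .data$nonsyn / pmax(.data$syn, 1L))
  if (test) {
    tot_ns <- sum(out$nonsyn); tot_s <- sum(out$syn)
    p0 <- tot_ns / max(tot_ns + tot_s, 1L)
    out$p_value <- vapply(seq_len(nrow(out)), function(i) {
      k <- out$nonsyn[i]; m <- out$nonsyn[i] + out$syn[i]
      if (m == 0) return(NA_real_)
      stats::binom.test(k, m, p0, alternative = "greater")$p.value
    }, double(1))
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  }
  arrange(out, dplyr::desc(.data$ratio), .data$term)
}

# ---------------------------------------------------------------------
# Reported genome-wide counts for the three rice restorer lines (IR24,
# MH63, SH527 against the 9311 reference), bundled as plain-text fixtures.

#' Reported restorer-line variant counts
#'
#' Per-chromosome variant counts reported for the three elite rice
#' restorer lines IR24, MH63 and SH527 resequenced against the indica 9311
#' reference, bundled with the package in tidy form. These drive the
#' arithmetic cross-checks (column totals, inclusion-exclusion union).
#'
#' @param table One of `"per_sample"` (per-chromosome SNP/InDel/SV counts
#'   per line), `"pairwise"` (shared/different counts per line pair),
#'   `"threeway"` (shared/different counts across all three),
#'   `"coding_effects"` (Syn/Non-syn CDS SNP counts), `"indel_cds"`
#'   (CDS/non-CDS InDel counts), `"large_effect"` (ATG-change / premature
#'   stop / stop-change counts among shared SNPs), or
#'   `"large_effect_different"` (large-effect totals among the
#'   allelic-different SNPs).
#' @return A tidy tibble (layout depends on `table`).
#' @export
reported_counts <- function(table = c("per_sample", "pairwise", "threeway",
                                      "coding_effects", "indel_cds",
                                      "large_effect",
                                      "large_effect_different")) {
  table <- match.arg(table)
  file <- c(
    per_sample = "per_sample_variant_counts.tsv",
    pairwise = "pairwise_comparison_counts.tsv",
    threeway = "threeway_comparison_counts.tsv",
    coding_effects = "coding_effect_counts.tsv",
    indel_cds = "indel_cds_counts.tsv",
    large_effect = "large_effect_counts.tsv",
    large_effect_different = "different_large_effect_counts.tsv")[table]
  path <- system.file("extdata", "reported_counts", file,
                      package = "resevar", mustWork = TRUE)
  if (table == "large_effect_different") {
    return(readr::read_tsv(path, col_types = readr::cols(
      effect = "c", count = "i")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = "i", chrom = "c"))
  wide_cols <- setdiff(names(raw), "chrom")
  long <- raw |>
    tidyr::pivot_longer(dplyr::all_of(wide_cols), names_to = "key",
                        values_to = "count")
  switch(table,
    per_sample = long |>
      tidyr::separate_wider_delim("key", "_",
                                  names = c("group", "sample")) |>
      mutate(group = c(snp = "SNP", indel = "InDel", sv = "SV")[.data$group]),
    pairwise = long |>
      tidyr::separate_wider_regex("key", c(
        group = "snp|indel", "_", class = "shared|different", "_",
        pair = ".*")) |>
      mutate(group = c(snp = "SNP", indel = "InDel")[.data$group],
             pair = sub("_", "+", .data$pair)),
    threeway = long |>
      tidyr::separate_wider_delim("key", "_",
                                  names = c("group", "class")) |>
      mutate(group = c(snp = "SNP", indel = "InDel")[.data$group]),
    coding_effects = long |>
      tidyr::separate_wider_regex("key", c(
        effect = "syn|nonsyn", "_", class = "shared|different", "_",
        comparison = ".*")),
    indel_cds = long |>
      tidyr::separate_wider_regex("key", c(
        region = "noncds|cds", "_", class = "shared|different", "_",
        comparison = ".*")),
    large_effect = long |>
      tidyr::separate_wider_regex("key", c(
        effect = "atg|premature|stop", "_", comparison = ".*"))
  )
}

#' Cross-check reported per-chromosome tables against printed totals
#'
#' Verifies, for each bundled reported-count table (or a caller-supplied
#' replacement), that every column's per-chromosome sum equals the printed
#' total, and that the inclusion-exclusion union identity holds. A single
#' perturbed cell fails its check.
#'
#' @param tables Optional named list overriding any of the bundled tables
#'   (`per_sample`, `pairwise`, `threeway`, `coding_effects`, `indel_cds`,
#'   `large_effect`) with a tibble of the same tidy layout.
#' @return A tibble `check`, `pass`, `detail`.
#' @export
reported_cross_checks <- function(tables = list()) {
  totals <- readr::read_tsv(
    system.file("extdata", "reported_counts", "printed_totals.tsv",
                package = "resevar", mustWork = TRUE),
    col_types = readr::cols(table = "c", key = "c", total = "i"))
  spec <- c(per_sample = "per_sample_variant",
            pairwise = "pairwise_comparison",
            threeway = "threeway_comparison",
            coding_effects = "coding_effect",
            indel_cds = "indel_cds",
            large_effect = "large_effect")
  checks <- list()
  key_of <- function(tab, df) {
    # rebuild the wide column key from the tidy columns
    switch(tab,
      per_sample = paste0(c(SNP = "snp", InDel = "indel",
                            SV = "sv")[df$group], "_", df$sample),
      pairwise = paste0(c(SNP = "snp", InDel = "indel")[df$group], "_",
                        df$class, "_", sub("\\+", "_", df$pair)),
      threeway = paste0(c(SNP = "snp", InDel = "indel")[df$group], "_",
                        df$class),
      coding_effects = paste0(df$effect, "_", df$class, "_",
                              df$comparison),
      indel_cds = paste0(df$region, "_", df$class, "_", df$comparison),
      large_effect = paste0(df$effect, "_", df$comparison))
  }
  for (tab in names(spec)) {
    df <- tables[[tab]] %||% reported_counts(tab)
    df$key <- key_of(tab, df)
    got <- df |> group_by(.data$key) |>
      summarise(total = sum(.data$count), .groups = "drop")
    want <- totals |> filter(.data$table == spec[[tab]])
    cmpd <- left_join(want, got, by = "key",
                      suffix = c("_printed", "_summed"))
    ok <- !is.na(cmpd$total_summed) &
      cmpd$total_printed == cmpd$total_summed
    checks[[tab]] <- tibble(
      check = paste0(tab, ": column sums equal printed totals"),
      pass = all(ok),
      detail = if (all(ok)) "ok" else
        paste("mismatch:", paste(cmpd$key[!ok], collapse = ", ")))
  }
  per_sample <- tables$per_sample %||% reported_counts("per_sample")
  pairwise <- tables$pairwise %||% reported_counts("pairwise")
  threeway <- tables$threeway %||% reported_counts("threeway")
  ie <- union_accounting(
    (per_sample |> filter(.data$group == "SNP") |>
       group_by(.data$sample) |>
       summarise(n = sum(.data$count)))$n,
    (pairwise |> filter(.data$group == "SNP", .data$class == "shared") |>
       group_by(.data$pair) |> summarise(n = sum(.data$count)))$n,
    sum(threeway$count[threeway$group == "SNP" &
                         threeway$class == "shared"]))
  checks$union <- tibble(
    check = "non-redundant SNP union identity",
    pass = ie == 568787,
    detail = sprintf("inclusion-exclusion union = %d", as.integer(ie)))
  bind_rows(checks)
}

#' Headline quantities derived from the reported counts
#'
#' Recomputes, by arithmetic on the bundled per-chromosome tables: the
#' per-line totals, the inclusion-exclusion non-redundant SNP union, the
#' three-way different-SNP count, the shared synonymous-CDS count for the
#' IR24/MH63 pair, and the genome-wide large-effect totals (shared plus
#' different).
#'
#' @return A named list of scalars.
#' @export
reported_summary <- function() {
  per_sample <- reported_counts("per_sample")
  pairwise <- reported_counts("pairwise")
  threeway <- reported_counts("threeway")
  coding <- reported_counts("coding_effects")
  large <- reported_counts("large_effect")
  large_diff <- reported_counts("large_effect_different")
  tot <- per_sample |>
    group_by(.data$sample, .data$group) |>
    summarise(count = sum(.data$count), .groups = "drop")
  snp_totals <- tot |> filter(.data$group == "SNP")
  pair_shared <- pairwise |>
    filter(.data$group == "SNP", .data$class == "shared") |>
    group_by(.data$pair) |> summarise(count = sum(.data$count),
                                      .groups = "drop")
  three_shared <- sum(threeway$count[threeway$group == "SNP" &
                                       threeway$class == "shared"])
  union_snps <- union_accounting(snp_totals$count, pair_shared$count,
                                 three_shared)
  eff_tot <- function(effect) {
    sum(large$count[large$effect == effect]) +
      large_diff$count[match(
        c(atg = "atg_change", premature = "premature_stop",
          stop = "stop_change")[effect], large_diff$effect)]
  }
  list(
    snp_total_IR24 = sum(per_sample$count[per_sample$group == "SNP" &
                                            per_sample$sample == "IR24"]),
    snp_total_MH63 = sum(per_sample$count[per_sample$group == "SNP" &
                                            per_sample$sample == "MH63"]),
    snp_total_SH527 = sum(per_sample$count[per_sample$group == "SNP" &
                                             per_sample$sample == "SH527"]),
    indel_total_MH63 = sum(per_sample$count[per_sample$group == "InDel" &
                                              per_sample$sample == "MH63"]),
    union_snps = union_snps,
    threeway_different_snps = sum(
      threeway$count[threeway$group == "SNP" &
                       threeway$class == "different"]),
    syn_cds_shared_IR24_MH63 = sum(
      coding$count[coding$effect == "syn" & coding$class == "shared" &
                     coding$comparison == "IR24_MH63"]),
    premature_stop_total = eff_tot("premature"),
    atg_change_total = eff_tot("atg"),
    stop_change_total = eff_tot("stop")
  )
}

#' Build a structured report with internal cross-checks
#'
#' Assembles per-chromosome tables, pairwise/three-way comparison
#' summaries, heterozygosity rates and the union identity, and runs the
#' arithmetic cross-checks (every total equals the sum of its parts; the
#' inclusion-exclusion union equals the direct union).
#'
#' @param variants Variant tibble (all samples).
#' @param masks Coverage-mask tibble.
#' @param genome Genome tibble.
#' @param strict Error (instead of flagging) when a cross-check fails.
#' @return A `variation_report` list with elements `per_chromosome`,
#'   `pairwise`, `threeway`, `heterozygosity`, `union`, `cross_checks`.
#' @export
build_report <- function(variants, masks, genome, strict = FALSE) {
  samples <- sort(unique(variants$sample_id))
  per_chrom <- per_chromosome_table(variants, genome, totals = TRUE)
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  pw <- bind_rows(lapply(pairs, function(p) {
    pairwise_summary(variants, masks, p) |>
      mutate(pair = paste(p, collapse = "+"))
  }))
  tw <- if (length(samples) >= 3) threeway_summary(variants, masks)
        else NULL
  het <- heterozygosity_rate(variants, masks)
  # union identity on SNPs, computed without the eligibility mask so that
  # the inclusion-exclusion terms and the direct union use the same sets
  snp_tot <- variants |> filter(.data$type == "SNP") |>
    count(.data$sample_id)
  cmp_pair <- vapply(pairs, function(p) {
    cmp <- compare_samples(variants |> filter(.data$type == "SNP"),
                           samples = p, require_coverage = FALSE)
    sum(cmp$loci$class == "shared")
  }, double(1))
  three_shared <- if (length(samples) >= 3) {
    cmp <- compare_samples(variants |> filter(.data$type == "SNP"),
                           samples = samples, require_coverage = FALSE)
    sum(cmp$loci$class == "shared")
  } else 0
  ie_union <- union_accounting(snp_tot$n, cmp_pair, three_shared)
  direct_union <- union_size(variants |> filter(.data$type == "SNP"))
  checks <- tibble(
    check = c("total rows equal column sums", "union identity"),
    pass = c(
      {
        tot <- per_chrom |> filter(.data$chrom == "Total")
        parts <- per_chrom |> filter(.data$chrom != "Total") |>
          group_by(.data$sample_id, .data$group) |>
          summarise(count = sum(.data$count), .groups = "drop")
        all(dplyr::arrange(tot, .data$sample_id, .data$group)$count ==
              dplyr::arrange(parts, .data$sample_id, .data$group)$count)
      },
      ie_union == direct_union),
    detail = c("per-chromosome table",
               sprintf("inclusion-exclusion %d vs direct %d",
                       as.integer(ie_union), as.integer(direct_union))))
  if (strict && !all(checks$pass)) {
    stop("report cross-check failed: ",
         paste(checks$check[!checks$pass], collapse = "; "), call. = FALSE)
  }
  structure(list(per_chromosome = per_chrom, pairwise = pw, threeway = tw,
                 heterozygosity = het,
                 union = list(inclusion_exclusion = ie_union,
                              direct = direct_union),
                 cross_checks = checks),
            class = "variation_report")
}

#' @export
print.variation_report <- function(x, ...) {
  cat("<variation_report>\n")
  cat("SNP union (inclusion-exclusion):", x$union$inclusion_exclusion,
      "| direct:", x$union$direct, "\n")
  cat("Cross-checks:",
      sum(x$cross_checks$pass), "/", nrow(x$cross_checks), "passed\n")
  invisible(x)
}

#' Write a report's tables to a directory
#'
#' @param report A `variation_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$per_chromosome,
                   file.path(dir, "per_chromosome_counts.tsv"))
  readr::write_tsv(report$pairwise, file.path(dir, "pairwise_counts.tsv"))
  if (!is.null(report$threeway)) {
    readr::write_tsv(report$threeway, file.path(dir, "threeway_counts.tsv"))
  }
  readr::write_tsv(report$heterozygosity,
                   file.path(dir, "heterozygosity.tsv"))
  readr::write_tsv(report$cross_checks, file.path(dir, "cross_checks.tsv"))
  summary_lines <- c(
    "Variation report",
    sprintf("SNP union: inclusion-exclusion %s, direct %s",
            report$union$inclusion_exclusion, report$union$direct),
    sprintf("Cross-checks passed: %d/%d", sum(report$cross_checks$pass),
            nrow(report$cross_checks)))
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
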