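# Coverage-mask and read-evidence generation for the synthetic data.

truth_footprint <- function(truth) {
  truth |>
    mutate(
      fstart = .data$pos,
      fend = dplyr::case_when(
        .data$type == "SV" ~ .data$sv_end,
        TRUE ~ .data$pos + nchar(.data$ref)
      )
    ) |>
    select(dplyr::all_of(c("sample_id", "chrom", "fstart", "fend",
                           "uncovered_sample", "locus_id")))
}

#' Generate per-sample coverage masks
#'
#' Carves random uncovered gaps out of each chromosome until the covered
#' fraction matches `coverage_fraction` (within 1%). Gaps avoid every
#' spiked locus footprint, except that loci flagged with an
#' `uncovered_sample` get a deliberate gap in that sample, exercising the
#' ineligible classification downstream.
#'
#' @param genome Genome tibble.
#' @param truth Truth tibble from [spike_variants()].
#' @param config A [sim_config()].
#' @return A coverage-mask tibble for all samples.
#' @export
simulate_coverage <- function(genome, truth, config) {
  set.seed(seed_stream(config$seed, 4L))
  samples <- config$sample_ids
  fp <- truth_footprint(truth)
  gap_unit <- 500L
  masks <- list()
  for (s in samples) {
    # positions that must stay covered for this sample: every locus footprint
    # except those deliberately uncovered here
    protect <- fp |> filter(is.na(.data$uncovered_sample) |
                              .data$uncovered_sample != s)
    forced <- fp |> filter(!is.na(.data$uncovered_sample) &
                             .data$uncovered_sample == s) |>
      distinct(.data$chrom, .data$fstart, .data$fend)
    for (ci in seq_len(nrow(genome))) {
      chrom <- genome$chrom[ci]
      len <- genome$length[ci]
      # protected[i]: 1-based base i must stay covered; gapped[i]: in a gap
      protected <- logical(len)
      pr <- protect[protect$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(pr))) {
        protected[(pr$fstart[k] + 1L):pr$fend[k]] <- TRUE
      }
      gapped <- logical(len)
      fo <- forced[forced$chrom == chrom, , drop = FALSE]
      for (k in seq_len(nrow(fo))) {
        gapped[max(1L, fo$fstart[k] - 24L):min(len, fo$fend[k] + 25L)] <- TRUE
      }
      total_gap <- round((1 - config$coverage_fraction) * len)
      budget <- total_gap - sum(gapped)
      tries <- 0L
      while (budget >= 50L) {
        gl <- min(gap_unit, budget)
        start <- sample.int(len - gl, 1)  # 1-based first gapped base
        idx <- start:(start + gl - 1L)
        if (!any(protected[idx]) && !any(gapped[idx])) {
          gapped[idx] <- TRUE
          budget <- budget - gl
        }
        tries <- tries + 1L
        if (tries > 5000L) {
          stop("coverage_fraction too low to keep all spiked loci covered",
               call. = FALSE)
        }
      }
      r <- rle(!gapped)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      masks[[length(masks) + 1L]] <- tibble(
        sample_id = s, chrom = chrom,
        start = starts[keep] - 1L, end = ends[keep])
    }
  }
  merge_mask(bind_rows(masks))
}

qual_string <- function(q, n) {
  paste(rep(rawToChar(as.raw(q + 33L)), n), collapse = "")
}

draw_bases <- function(n, alleles, error) {
  # alleles: length-1 (hom) or length-2 (het) emission alleles
  pick <- sample(alleles, n, replace = TRUE)
  err <- runif(n) < error
  pick[err] <- vapply(pick[err], function(b) sample(setdiff(DNA_BASES, b), 1),
                      character(1))
  paste(pick, collapse = "")
}

#' Generate per-sample site-level read evidence
#'
#' For every spiked locus (and a set of homozygous-reference control sites)
#' emits base calls at a configured mean depth and error rate, plus gapped
#' read-pair counts at InDel loci and abnormal read-pair records at SV loci.
#' Sites with zero depth are omitted.
#'
#' @param genome Genome tibble.
#' @param truth Truth tibble.
#' @param mask Coverage-mask tibble (control sites are drawn inside it).
#' @param config A [sim_config()].
#' @return A named list of per-sample pileup tibbles.
#' @export
simulate_pileups <- function(genome, truth, mask, config) {
  set.seed(seed_stream(config$seed, 5L))
  samples <- config$sample_ids
  out <- list()
  all_loci <- truth |> distinct(.data$chrom, .data$pos, .data$locus_id,
                                .keep_all = TRUE)
  for (s in samples) {
    own <- truth |> filter(.data$sample_id == s)
    other <- all_loci |> anti_join(own, by = "locus_id")
    m_s <- mask |> filter(.data$sample_id == s)
    # O(1) coverage lookup
    cov_vec <- setNames(lapply(genome$length, logical), genome$chrom)
    for (k in seq_len(nrow(m_s))) {
      cov_vec[[m_s$chrom[k]]][(m_s$start[k] + 1L):m_s$end[k]] <- TRUE
    }
    is_cov <- function(chrom, pos) cov_vec[[chrom]][pos + 1L]
    rows <- list()
    emit <- function(chrom, pos, ref, alleles, gap_type = NA_character_,
                     gap_seq = NA_character_, n_gapped = NA_integer_,
                     n_abn = NA_integer_, signature = NA_character_) {
      depth <- max(config$pileup_min_depth, rpois(1, config$pileup_depth))
      if (depth == 0L) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom, pos = as.integer(pos), ref = ref,
        bases = draw_bases(depth, alleles, config$base_error),
        quals = qual_string(config$base_qual, depth),
        gap_type = gap_type, gap_seq = gap_seq,
        n_gapped_pairs = as.integer(n_gapped),
        n_abnormal_pairs = as.integer(n_abn),
        abnormal_signature = signature, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(own))) {
      r <- own[i, ]
      if (!is_cov(r$chrom, r$pos)) next
      anchor <- substr(r$ref, 1, 1)
      if (r$type == "SNP") {
        alleles <- if (r$zygosity == "het") c(r$ref, r$alt) else r$alt
        emit(r$chrom, r$pos, r$ref, alleles)
      } else if (r$type %in% c("INS", "DEL")) {
        gseq <- if (r$type == "INS") substr(r$alt, 2, nchar(r$alt))
          else substr(r$ref, 2, nchar(r$ref))
        depth_gap <- max(config$pileup_min_depth,
                         rpois(1, config$pileup_depth))
        emit(r$chrom, r$pos, anchor, anchor, gap_type = r$type,
             gap_seq = gseq, n_gapped = depth_gap)
      } else if (r$type == "SV") {
        n_abn <- max(3L, round(config$pileup_depth / 2))
        emit(r$chrom, r$pos, anchor, anchor,
             n_abn = ceiling(n_abn / 2), signature = r$sv_type)
        emit(r$chrom, r$sv_end - 1L,
             genome_base(genome, r$chrom, r$sv_end - 1L),
             genome_base(genome, r$chrom, r$sv_end - 1L),
             n_abn = floor(n_abn / 2) + 1L, signature = r$sv_type)
      }
    }
    # reference evidence at other samples' loci (keeps them eligible)
    for (i in seq_len(nrow(other))) {
      r <- other[i, ]
      if (!is_cov(r$chrom, r$pos)) next
      anchor <- substr(r$ref, 1, 1)
      emit(r$chrom, r$pos, anchor, anchor)
    }
    # hom-ref control sites
    taken <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(all_loci))) {
      assign(paste(all_loci$chrom[k], all_loci$pos[k]), TRUE, envir = taken)
    }
    n_ctrl <- 0L
    while (n_ctrl < config$n_ref_sites) {
      ci <- sample.int(nrow(genome), 1, prob = genome$length)
      pos <- sample.int(genome$length[ci] - 2L, 1)
      chrom <- genome$chrom[ci]
      key <- paste(chrom, pos)
      if (!is.null(taken[[key]])) next
      if (!is_cov(chrom, pos)) next
      emit(chrom, pos, genome_base(genome, chrom, pos),
           genome_base(genome, chrom, pos))
      assign(key, TRUE, envir = taken)
      n_ctrl <- n_ctrl + 1L
    }
    out[[s]] <- as_tibble(bind_rows(rows)) |>
      arrange(.data$chrom, .data$pos)
  }
  out
}

#' Generate a complete synthetic dataset
#'
#' Runs genome, gene-model, variant, coverage and evidence generation in
#' order and (optionally) writes every artifact to disk in its standard
#' format.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; created if missing. When supplied,
#'   writes `genome.fa`, `genes.gff3`, `<sample>.vcf`, `<sample>.bed`,
#'   `<sample>.pileup.tsv` and `truth.tsv`.
#' @return A list with `genome`, `genes`, `variants`, `truth`, `mask`,
#'   `pileups`, `config` and (if `dir` given) `paths`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  genome0 <- simulate_genome(config)
  gm <- simulate_gene_models(genome0, config)
  sp <- spike_variants(gm$genome, gm$genes, config)
  mask <- simulate_coverage(gm$genome, sp$truth, config)
  pileups <- simulate_pileups(gm$genome, sp$truth, mask, config)
  out <- list(genome = gm$genome, genes = gm$genes,
              variants = sp$variants, truth = sp$truth, mask = mask,
              pileups = pileups, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      genes = file.path(dir, "genes.gff3"),
      truth = file.path(dir, "truth.tsv")
    )
    write_genome_fasta(out$genome, paths$genome)
    write_gene_models_gff3(out$genes, paths$genes)
    readr::write_tsv(out$truth, paths$truth)
    for (s in config$sample_ids) {
      paths[[paste0("vcf_", s)]] <- file.path(dir, paste0(s, ".vcf"))
      write_variants_vcf(filter(out$variants, .data$sample_id == s),
                         paths[[paste0("vcf_", s)]], sample_id = s)
      paths[[paste0("bed_", s)]] <- file.path(dir, paste0(s, ".bed"))
      write_coverage_bed(filter(mask, .data$sample_id == s),
                         paths[[paste0("bed_", s)]])
      paths[[paste0("pileup_", s)]] <- file.path(dir,
                                                 paste0(s, ".pileup.tsv"))
      write_pileup(pileups[[s]], paths[[paste0("pileup_", s)]])
    }
    out$paths <- paths
  }
  out
}
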