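# Synthetic-data generator: toy genome, gene models with valid ORFs,
# spiked per-sample variant sets with a known truth table, coverage masks
# and site-level read evidence. Deterministic under a single integer seed;
# each stage draws from a seed stream derived from it so stages can be
# regenerated independently.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a three-line inbred resequencing
#' comparison: three samples sharing most variants against a divergent
#' reference background, small sets of pair-shared, sample-unique and
#' allelic-different loci, ~85% per-sample genome coverage, a heterozygous
#' call fraction of 2e-4 per covered base, InDels of at most 5 bp, and a
#' handful of structural variants.
#'
#' @param seed Integer seed driving every stage.
#' @param n_chroms,chrom_length Number and length (bp) of toy chromosomes.
#' @param n_genes Genes to place (both strands, non-overlapping, valid ORFs).
#' @param sample_ids Sample names (default three lines).
#' @param snp_shared_all,snp_shared_pair,snp_unique,snp_different Counts of
#'   spiked SNP loci per comparison class (`snp_shared_pair` per pair,
#'   `snp_unique` per sample).
#' @param cds_effects Named counts of additional shared-all coding SNPs per
#'   intended effect class (`synonymous`, `nonsynonymous`, `premature_stop`,
#'   `start_loss`, `stop_loss`).
#' @param indel_shared_all,indel_shared_pair,indel_unique,indel_different
#'   Counts of spiked InDel loci per comparison class.
#' @param indel_max_len Maximum InDel length (bp); capped at 5.
#' @param sv_shared_all,sv_unique Structural-variant locus counts.
#' @param sv_span SV span in bp.
#' @param n_uncovered Loci deliberately left uncovered in one sample to
#'   exercise the ineligible class.
#' @param coverage_fraction Per-sample covered fraction of the genome.
#' @param het_fraction Expected heterozygous calls per covered base.
#' @param pileup_depth,pileup_min_depth Mean and floor of per-site read depth.
#' @param base_error Per-read base-miscall rate in the simulated evidence.
#' @param base_qual Phred quality attached to every simulated base.
#' @param n_ref_sites Homozygous-reference evidence sites per sample (for
#'   false-positive checks of the caller).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 250000L,
                       n_genes = 20L,
                       sample_ids = c("S1", "S2", "S3"),
                       snp_shared_all = 500L,
                       snp_shared_pair = 60L,
                       snp_unique = 40L,
                       snp_different = 10L,
                       cds_effects = c(synonymous = 6L, nonsynonymous = 6L,
                                       premature_stop = 4L, start_loss = 2L,
                                       stop_loss = 2L),
                       indel_shared_all = 40L,
                       indel_shared_pair = 10L,
                       indel_unique = 8L,
                       indel_different = 4L,
                       indel_max_len = 5L,
                       sv_shared_all = 2L,
                       sv_unique = 1L,
                       sv_span = 400L,
                       n_uncovered = 7L,
                       coverage_fraction = 0.85,
                       het_fraction = 2e-4,
                       pileup_depth = 10,
                       pileup_min_depth = 6L,
                       base_error = 0.01,
                       base_qual = 30L,
                       n_ref_sites = 200L) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    sample_ids = sample_ids,
    snp_shared_all = as.integer(snp_shared_all),
    snp_shared_pair = as.integer(snp_shared_pair),
    snp_unique = as.integer(snp_unique),
    snp_different = as.integer(snp_different),
    cds_effects = cds_effects,
    indel_shared_all = as.integer(indel_shared_all),
    indel_shared_pair = as.integer(indel_shared_pair),
    indel_unique = as.integer(indel_unique),
    indel_different = as.integer(indel_different),
    indel_max_len = as.integer(indel_max_len),
    sv_shared_all = as.integer(sv_shared_all),
    sv_unique = as.integer(sv_unique),
    sv_span = as.integer(sv_span),
    n_uncovered = as.integer(n_uncovered),
    coverage_fraction = coverage_fraction,
    het_fraction = het_fraction,
    pileup_depth = pileup_depth,
    pileup_min_depth = as.integer(pileup_min_depth),
    base_error = base_error,
    base_qual = as.integer(base_qual),
    n_ref_sites = as.integer(n_ref_sites)
  )
  counts <- unlist(cfg[grepl("^(snp|indel|sv)_|n_uncovered|n_genes|n_ref",
                             names(cfg))])
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (!(coverage_fraction > 0 && coverage_fraction <= 1)) {
    stop("coverage_fraction must be in (0, 1]", call. = FALSE)
  }
  if (cfg$indel_max_len > 5L || cfg$indel_max_len < 1L) {
    stop("indel_max_len must be in [1, 5]", call. = FALSE)
  }
  if (any(cfg$cds_effects < 0)) stop("cds_effects must be >= 0", call. = FALSE)
  if (length(cfg$sample_ids) < 2) stop("need at least 2 samples", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

MIN_GENE_SPAN <- 200L

#' Generate a toy genome
#'
#' Uniform random base composition; deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return A genome tibble (`chrom`, `seq`, `length`).
#' @export
simulate_genome <- function(config) {
  if (config$chrom_length <= 0) stop("chrom_length must be > 0", call. = FALSE)
  if (config$n_genes > 0 && config$chrom_length < 3L * MIN_GENE_SPAN) {
    stop("chrom_length too small to host genes (need >= ",
         3L * MIN_GENE_SPAN, ")", call. = FALSE)
  }
  set.seed(seed_stream(config$seed, 1L))
  tibble(
    chrom = sprintf("chr%02d", seq_len(config$n_chroms)),
    seq = vapply(seq_len(config$n_chroms), function(i) {
      paste(sample(DNA_BASES, config$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1)),
    length = config$chrom_length
  )
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE != "*"], character(0))
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE == "*"]

#' Generate gene models with valid ORFs
#'
#' Places non-overlapping genes on both strands. Each gene's CDS starts with
#' ATG, ends with a stop codon, has length divisible by three and may be
#' split across up to three exons; the CDS nucleotides are written into the
#' genome (reverse-complemented for minus-strand genes), so extracting and
#' translating any emitted CDS yields `M...*`.
#'
#' @param genome Genome tibble from [simulate_genome()].
#' @param config A [sim_config()].
#' @return A list with the updated `genome` and the `genes` tibble (same
#'   layout as [read_gene_models()]).
#' @export
simulate_gene_models <- function(genome, config) {
  set.seed(seed_stream(config$seed, 2L))
  n <- config$n_genes
  if (n == 0) {
    return(list(genome = genome, genes = gene_model_tbl(list())))
  }
  rows <- list()
  seqs <- genome$seq
  cursor <- rep(50L, nrow(genome))  # per-chrom placement cursor
  for (g in seq_len(n)) {
    ci <- ((g - 1L) %% nrow(genome)) + 1L
    strand <- if (g %% 2L == 0L) "-" else "+"
    n_codons <- sample(30:60, 1)
    n_exons <- sample(1:3, 1)
    cds_len <- 3L * n_codons
    exon_lens <- as.integer(diff(round(seq(0, cds_len,
                                           length.out = n_exons + 1L))))
    intron_lens <- if (n_exons > 1) sample(60:150, n_exons - 1L,
                                           replace = TRUE) else integer(0)
    span <- sum(exon_lens) + sum(intron_lens)
    start <- cursor[ci] + sample(80:200, 1)
    if (start + span + 50L > genome$length[ci]) {
      stop("cannot place ", n, " genes without overlap; request fewer genes ",
           "or a longer genome", call. = FALSE)
    }
    cursor[ci] <- start + span
    # build the coding sequence: ATG + sense codons + stop
    cds_seq <- paste0(
      "ATG",
      paste(sample(setdiff(SENSE_CODONS, "ATG"), n_codons - 2L,
                   replace = TRUE), collapse = ""),
      sample(STOP_CODONS, 1))
    # exon genomic intervals (genomic order)
    ex_starts <- start + cumsum(c(0L, head(exon_lens, -1) +
                                    intron_lens))
    ex <- tibble(start = as.integer(ex_starts),
                 end = as.integer(ex_starts + exon_lens))
    # write CDS into the genome: plus strand left-to-right; minus strand the
    # genome carries the reverse complement, transcription runs right-to-left
    genomic_seq <- if (strand == "+") cds_seq else reverse_complement(cds_seq)
    offset <- 0L
    for (e in seq_len(nrow(ex))) {
      w <- ex$end[e] - ex$start[e]
      substr(seqs[ci], ex$start[e] + 1L, ex$end[e]) <-
        substr(genomic_seq, offset + 1L, offset + w)
      offset <- offset + w
    }
    cds_tx <- if (strand == "+") ex else ex[rev(seq_len(nrow(ex))), ]
    rows[[g]] <- tibble(
      gene_id = sprintf("gene%03d", g), chrom = genome$chrom[ci],
      strand = strand, start = as.integer(start),
      end = as.integer(start + span), cds_len = cds_len, phase = 0L,
      annotatable = TRUE, cds = list(cds_tx)
    )
  }
  genome$seq <- seqs
  list(genome = genome, genes = gene_model_tbl(rows))
}

# Genomic positions of a gene's CDS bases in transcription order (0-based).
cds_genomic_positions <- function(gene) {
  segs <- gene$cds[[1]]
  unlist(lapply(seq_len(nrow(segs)), function(i) {
    if (gene$strand == "+") seq(segs$start[i], segs$end[i] - 1L)
    else seq(segs$end[i] - 1L, segs$start[i])
  }))
}

# extract the CDS nucleotide string in transcription order
cds_sequence <- function(gene, genome) {
  segs <- gene$cds[[1]]
  chrom_seq <- genome_sequence(genome, gene$chrom)
  parts <- vapply(seq_len(nrow(segs)), function(i) {
    substr(chrom_seq, segs$start[i] + 1L, segs$end[i])
  }, character(1))
  if (gene$strand == "+") paste(parts, collapse = "")
  else paste(vapply(parts, reverse_complement, character(1)), collapse = "")
}
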