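# Shared fixtures, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

# small but fully featured synthetic dataset reused across test files
tiny_config <- function(seed = 11L, ...) {
  sim_config(
    seed = seed, n_chroms = 2L, chrom_length = 60000L, n_genes = 6L,
    snp_shared_all = 60L, snp_shared_pair = 10L, snp_unique = 8L,
    snp_different = 4L,
    cds_effects = c(synonymous = 3L, nonsynonymous = 3L,
                    premature_stop = 2L, start_loss = 1L, stop_loss = 1L),
    indel_shared_all = 10L, indel_shared_pair = 3L, indel_unique = 3L,
    indel_different = 2L, sv_shared_all = 1L, sv_unique = 1L,
    sv_span = 300L, n_uncovered = 3L, n_ref_sites = 40L,
    ...
  )
}

tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    .fixture_env$tiny <- simulate_dataset(tiny_config())
  }
  .fixture_env$tiny
}

# truth-table class counts at locus level
truth_class_counts <- function(truth, types = NULL) {
  t1 <- dplyr::distinct(truth, locus_id, .keep_all = TRUE)
  if (!is.null(types)) t1 <- dplyr::filter(t1, type %in% types)
  table(t1$comparison_class)
}

# a hand-built two-exon gene on the given strand, with its genome
toy_gene_genome <- function(strand = "+", seed = 42L) {
  set.seed(seed)
  # CDS: ATG + 8 sense codons + TAA = 30 nt, split 18 + 12 across 2 exons
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], "ATG")
  cds <- paste0("ATG", paste(sample(sense, 8, replace = TRUE),
                             collapse = ""), "TAA")
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  intron <- flank(20)
  genomic_cds <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  left <- substr(genomic_cds, 1, 18)
  right <- substr(genomic_cds, 19, 30)
  seq <- paste0(flank(10), left, intron, right, flank(10))
  genome <- tibble::tibble(chrom = "chrT", seq = seq, length = nchar(seq))
  ex <- tibble::tibble(start = c(10L, 48L), end = c(28L, 60L))
  cds_tx <- if (strand == "+") ex else ex[2:1, ]
  genes <- tibble::tibble(
    gene_id = "toy1", chrom = "chrT", strand = strand,
    start = 10L, end = 60L, cds_len = 30L, phase = 0L,
    annotatable = TRUE, cds = list(cds_tx))
  list(genome = genome, genes = genes, cds = cds)
}

# Oracle: classify a CDS substitution by full re-translation of the CDS.
# Independent of the codon-incremental path in classify_snp_effects().
retranslate_effect <- function(cds_ref, cds_alt) {
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  p_ref <- tr(cds_ref); p_alt <- tr(cds_alt)
  n <- nchar(p_ref)
  first_ref <- substr(cds_ref, 1, 3); first_alt <- substr(cds_alt, 1, 3)
  ref_stops <- which(strsplit(p_ref, "")[[1]] == "*")
  alt_stops <- which(strsplit(p_alt, "")[[1]] == "*")
  if (first_ref == "ATG" && first_alt != "ATG") return("start_loss")
  early_alt <- setdiff(alt_stops, n)
  early_ref <- setdiff(ref_stops, n)
  if (length(setdiff(early_alt, early_ref))) return("premature_stop")
  if (n %in% ref_stops && !(n %in% alt_stops)) return("stop_loss")
  if (p_ref == p_alt) return("synonymous")
  "nonsynonymous"
}

expect_variant_sets_equal <- function(got, want) {
  key <- function(v) sort(paste(v$chrom, v$pos, v$ref, v$alt, v$type))
  expect_identical(key(got), key(want))
}
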