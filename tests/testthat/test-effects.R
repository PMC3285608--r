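# Gene localization and coding-effect classification.

snp_at <- function(pos, ref, alt, chrom = "chrT", sample = "S1") {
  resevar:::as_variant_tbl(tibble::tibble(
    sample_id = sample, chrom = chrom, pos = as.integer(pos), ref = ref,
    alt = alt, type = "SNP", zygosity = "hom", qual = 60, support = 10L))
}

test_that("variants localize to CDS, intron and intergenic space", {
  tg <- toy_gene_genome("+")
  base_at <- function(p) substr(tg$genome$seq, p + 1, p + 1)
  v <- dplyr::bind_rows(
    snp_at(12, base_at(12), setdiff(c("A", "C", "G", "T"), base_at(12))[1]),
    snp_at(35, base_at(35), setdiff(c("A", "C", "G", "T"), base_at(35))[1]),
    snp_at(65, base_at(65), setdiff(c("A", "C", "G", "T"), base_at(65))[1]))
  m <- map_variants_to_genes(v, tg$genes, tg$genome)
  expect_identical(m$region, c("CDS", "noncds_gene", "intergenic"))
  expect_identical(m$gene_id, c("toy1", "toy1", NA))
  expect_error(
    map_variants_to_genes(snp_at(9999, "A", "G"), tg$genes, tg$genome),
    "beyond chromosome end")
})

test_that("canonical codon changes get the expected effect labels", {
  # + strand gene whose CDS is known; craft specific codon substitutions
  tg <- toy_gene_genome("+")
  cds <- tg$cds
  cds_pos <- resevar:::cds_genomic_positions(tg$genes[1, ])
  # codon 1 (ATG): any substitution is a start loss
  v <- snp_at(cds_pos[1], substr(cds, 1, 1), "C")
  e <- classify_snp_effects(v, tg$genes, tg$genome)
  expect_identical(e$effect, "start_loss")
  # terminal stop codon TAA -> CAA: stop loss
  v <- snp_at(cds_pos[28], substr(cds, 28, 28), "C")
  e <- classify_snp_effects(v, tg$genes, tg$genome)
  expect_identical(e$effect, "stop_loss")
  # reference mismatch is refused
  wrong_ref <- setdiff(c("A", "C", "G", "T"),
                       substr(cds, 4, 4))[1]
  expect_error(
    classify_snp_effects(snp_at(cds_pos[4], wrong_ref, "A"),
                         tg$genes, tg$genome),
    "reference mismatch")
})

test_that("incremental codon classification agrees with full re-translation
           for every substitution on both strands", {
  for (strand in c("+", "-")) {
    tg <- toy_gene_genome(strand, seed = 7)
    cds <- tg$cds
    cds_pos <- resevar:::cds_genomic_positions(tg$genes[1, ])
    rows <- list()
    want <- character(0)
    for (i in seq_len(nchar(cds))) {
      ref_tx <- substr(cds, i, i)
      gpos <- cds_pos[i]
      ref_g <- substr(tg$genome$seq, gpos + 1, gpos + 1)
      for (alt_tx in setdiff(c("A", "C", "G", "T"), ref_tx)) {
        alt_cds <- cds
        substr(alt_cds, i, i) <- alt_tx
        want <- c(want, retranslate_effect(cds, alt_cds))
        alt_g <- if (strand == "+") alt_tx else
          chartr("ACGT", "TGCA", alt_tx)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = "S1", chrom = "chrT", pos = gpos, ref = ref_g,
          alt = alt_g, type = "SNP", zygosity = "hom", qual = 60,
          support = 10L)
      }
    }
    v <- resevar:::as_variant_tbl(dplyr::bind_rows(rows))
    # as_variant_tbl sorts; classify in the constructed order instead
    v <- dplyr::bind_rows(rows)
    got <- classify_snp_effects(v, tg$genes, tg$genome)
    expect_identical(got$effect, want,
                     label = paste("strand", strand, "effects"))
  }
})

test_that("minus-strand classification equals the reverse-complemented
           plus-strand construction", {
  # same CDS on both strands (metamorphic pair built from one seed)
  plus <- toy_gene_genome("+", seed = 33)
  minus <- toy_gene_genome("-", seed = 33)
  expect_identical(plus$cds, minus$cds)
  pos_p <- resevar:::cds_genomic_positions(plus$genes[1, ])
  pos_m <- resevar:::cds_genomic_positions(minus$genes[1, ])
  for (i in c(1, 5, 14, 27)) {
    ref_tx <- substr(plus$cds, i, i)
    alt_tx <- setdiff(c("A", "C", "G", "T"), ref_tx)[1]
    vp <- snp_at(pos_p[i], ref_tx, alt_tx)
    vm <- snp_at(pos_m[i],
                 chartr("ACGT", "TGCA", ref_tx),
                 chartr("ACGT", "TGCA", alt_tx))
    ep <- classify_snp_effects(vp, plus$genes, plus$genome)
    em <- classify_snp_effects(vm, minus$genes, minus$genome)
    expect_identical(em$effect, ep$effect)
  }
})

test_that("every CDS SNP receives exactly one effect label", {
  ds <- tiny_dataset()
  snps <- dplyr::filter(ds$variants, type == "SNP", sample_id == "S1")
  e <- classify_snp_effects(snps, ds$genes, ds$genome)
  in_cds <- e[e$region == "CDS", ]
  expect_true(all(in_cds$effect %in%
    c("synonymous", "nonsynonymous", "premature_stop", "start_loss",
      "stop_loss")))
  expect_true(all(e$effect[e$region != "CDS"] == "none"))
})

test_that("spiked effect classes are recovered exactly", {
  ds <- tiny_dataset()
  cfg <- tiny_config()
  eff_truth <- ds$truth |>
    dplyr::filter(sample_id == "S1",
                  effect_class %in% names(cfg$cds_effects))
  snps <- dplyr::semi_join(
    dplyr::filter(ds$variants, sample_id == "S1"),
    eff_truth, by = c("chrom", "pos"))
  got <- classify_snp_effects(snps, ds$genes, ds$genome)
  joined <- dplyr::inner_join(
    got, eff_truth[, c("chrom", "pos", "effect_class")],
    by = c("chrom", "pos"))
  expect_identical(nrow(joined), nrow(eff_truth))
  expect_identical(joined$effect, joined$effect_class)
})

test_that("InDel CDS intersection and frameshift metadata are correct", {
  tg <- toy_gene_genome("+")
  seqv <- tg$genome$seq
  mk <- function(pos, ref_len, alt_len) {
    ref <- substr(seqv, pos + 1, pos + ref_len)
    alt <- if (alt_len > ref_len) paste0(ref, strrep("A", alt_len - ref_len))
           else substr(ref, 1, alt_len)
    resevar:::as_variant_tbl(tibble::tibble(
      sample_id = "S1", chrom = "chrT", pos = as.integer(pos), ref = ref,
      alt = alt, type = if (alt_len > ref_len) "INS" else "DEL",
      zygosity = "hom", qual = 60, support = 10L))
  }
  inside_cds <- mk(12, 4, 1)      # 3 bp deletion inside exon 1
  in_intron <- mk(32, 1, 3)       # insertion in the intron
  straddle <- mk(26, 5, 1)        # deletion straddling the exon boundary
  got <- classify_indel_region(
    dplyr::bind_rows(inside_cds, in_intron, straddle), tg$genes)
  got <- got[order(got$pos), ]  # pos order: 12 (exonic), 26 (straddle), 32
  expect_identical(got$region, c("CDS", "CDS", "non-CDS"))
  expect_identical(got$frameshift, c(FALSE, TRUE, FALSE))
})

test_that("gene survey separates DNA-span from exonic counts", {
  tg <- toy_gene_genome("+")
  base_at <- function(p) substr(tg$genome$seq, p + 1, p + 1)
  mkv <- function(p) snp_at(p, base_at(p),
                            setdiff(c("A", "C", "G", "T"), base_at(p))[1])
  # 2 exonic (positions 12, 50) + 3 intronic (30, 35, 40)
  v <- dplyr::bind_rows(mkv(12), mkv(50), mkv(30), mkv(35), mkv(40))
  sv <- gene_survey(v, tg$genes)
  expect_identical(sv$dna, 5L)
  expect_identical(sv$mrna, 2L)
  # a sample with no variants inside the span counts 0/0
  far <- snp_at(70, substr(tg$genome$seq, 71, 71),
                setdiff(c("A", "C", "G", "T"),
                        substr(tg$genome$seq, 71, 71))[1])
  none <- gene_survey(far, tg$genes)
  expect_identical(none$dna, 0L)
  expect_identical(none$mrna, 0L)
  expect_error(gene_survey(v, tg$genes, "nope"), "unknown gene id")
})
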