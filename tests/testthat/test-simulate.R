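# Synthetic-data generator: determinism, construction invariants, truth
# bookkeeping.

test_that("genome generation is deterministic and validates inputs", {
  cfg <- sim_config(seed = 5, n_chroms = 2, chrom_length = 50000,
                    n_genes = 0)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  expect_identical(g1$length, c(50000L, 50000L))
  expect_error(simulate_genome(sim_config(chrom_length = 0)),
               "chrom_length")
  # byte-identical FASTA under the same seed
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g1, p1); write_genome_fasta(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated genes carry valid ORFs on both strands", {
  ds <- tiny_dataset()
  expect_true(all(c("+", "-") %in% ds$genes$strand))
  for (i in seq_len(nrow(ds$genes))) {
    cds <- resevar:::cds_sequence(ds$genes[i, ], ds$genome)
    expect_identical(nchar(cds) %% 3L, 0L)
    prot <- resevar:::translate_cds(cds)
    expect_identical(substr(prot, 1, 1), "M")
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    # no internal stops
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("zero genes yields an empty valid gene table and placement is
           refused when space runs out", {
  cfg <- sim_config(seed = 3, n_genes = 0, chrom_length = 50000)
  gm <- simulate_gene_models(simulate_genome(cfg), cfg)
  expect_identical(nrow(gm$genes), 0L)
  cfg_full <- sim_config(seed = 3, n_chroms = 1, chrom_length = 1000,
                         n_genes = 50)
  expect_error(simulate_gene_models(simulate_genome(cfg_full), cfg_full),
               "fewer genes")
})

test_that("spiked truth table has exact class counts and exclusive classes", {
  cfg <- tiny_config()
  ds <- tiny_dataset()
  counts <- truth_class_counts(ds$truth, types = "SNP")
  n_eff <- sum(cfg$cds_effects)
  expect_identical(unname(counts["shared_all"]),
                   as.integer(cfg$snp_shared_all + n_eff))
  expect_identical(unname(counts["shared_pair"]),
                   as.integer(3L * cfg$snp_shared_pair))
  expect_identical(unname(counts["unique"]), as.integer(3L * cfg$snp_unique))
  expect_identical(unname(counts["different"]), cfg$snp_different)
  expect_identical(unname(counts["ineligible"]), cfg$n_uncovered)
  # each locus appears once with one class
  per_locus <- dplyr::distinct(ds$truth, locus_id, comparison_class)
  expect_identical(nrow(per_locus),
                   dplyr::n_distinct(ds$truth$locus_id))
})

test_that("allelic-different loci carry distinct alternate bases", {
  ds <- tiny_dataset()
  diff <- dplyr::filter(ds$truth, comparison_class == "different",
                        type == "SNP")
  for (l in unique(diff$locus_id)) {
    alts <- diff$alt[diff$locus_id == l]
    expect_identical(length(alts), 3L)
    expect_false(anyDuplicated(alts) > 0)
    expect_false(any(alts == diff$ref[diff$locus_id == l][1]))
  }
})

test_that("shared-all request with everything else zero gives identical VCFs", {
  cfg <- sim_config(seed = 2, n_chroms = 1, chrom_length = 50000,
                    n_genes = 0, snp_shared_all = 10, snp_shared_pair = 0,
                    snp_unique = 0, snp_different = 0,
                    cds_effects = c(synonymous = 0), indel_shared_all = 0,
                    indel_shared_pair = 0, indel_unique = 0,
                    indel_different = 0, sv_shared_all = 0, sv_unique = 0,
                    n_uncovered = 0, het_fraction = 0)
  gm <- simulate_gene_models(simulate_genome(cfg), cfg)
  sp <- spike_variants(gm$genome, gm$genes, cfg)
  by_sample <- split(sp$variants[, c("chrom", "pos", "ref", "alt")],
                     sp$variants$sample_id)
  expect_identical(nrow(by_sample$S1), 10L)
  expect_identical(by_sample$S1, by_sample$S2, ignore_attr = TRUE)
  expect_equal(as.data.frame(by_sample$S1), as.data.frame(by_sample$S3))
})

test_that("coverage matches the requested fraction and protects loci", {
  cfg <- tiny_config()
  ds <- tiny_dataset()
  cov <- dplyr::summarise(dplyr::group_by(ds$mask, sample_id),
                          covered = sum(end - start))
  frac <- cov$covered / sum(ds$genome$length)
  expect_true(all(abs(frac - cfg$coverage_fraction) <= 0.01))
  # every spiked variant position is covered in its carrier sample
  for (s in cfg$sample_ids) {
    own <- dplyr::filter(ds$truth, sample_id == s)
    m <- dplyr::filter(ds$mask, sample_id == s)
    expect_true(all(resevar:::positions_covered(own$chrom, own$pos, m)))
  }
  # deliberately uncovered loci are uncovered in exactly their flagged sample
  unc <- dplyr::distinct(dplyr::filter(ds$truth, !is.na(uncovered_sample)),
                         locus_id, .keep_all = TRUE)
  for (i in seq_len(nrow(unc))) {
    m <- dplyr::filter(ds$mask, sample_id == unc$uncovered_sample[i])
    expect_false(resevar:::positions_covered(unc$chrom[i], unc$pos[i], m))
  }
})

test_that("full coverage yields one interval per chromosome", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length = 30000,
                    n_genes = 0, snp_shared_all = 5, snp_shared_pair = 0,
                    snp_unique = 0, snp_different = 0,
                    cds_effects = c(synonymous = 0), indel_shared_all = 0,
                    indel_shared_pair = 0, indel_unique = 0,
                    indel_different = 0, sv_shared_all = 0, sv_unique = 0,
                    n_uncovered = 0, het_fraction = 0,
                    coverage_fraction = 1)
  gm <- simulate_gene_models(simulate_genome(cfg), cfg)
  sp <- spike_variants(gm$genome, gm$genes, cfg)
  mask <- simulate_coverage(gm$genome, sp$truth, cfg)
  per <- dplyr::count(mask, sample_id, chrom)
  expect_true(all(per$n == 1))
  expect_true(all(mask$start == 0 & mask$end == 30000))
})

test_that("pileups carry the configured evidence", {
  ds <- tiny_dataset()
  cfg <- tiny_config()
  p1 <- ds$pileups$S1
  expect_true(all(nchar(p1$bases) == nchar(p1$quals)))
  expect_true(all(nchar(p1$bases) >= cfg$pileup_min_depth))
  own <- dplyr::filter(ds$truth, sample_id == "S1")
  # gap evidence at every covered InDel locus
  ind <- dplyr::filter(own, type %in% c("INS", "DEL"))
  gap_rows <- dplyr::filter(p1, !is.na(gap_type))
  expect_setequal(paste(gap_rows$chrom, gap_rows$pos),
                  paste(ind$chrom, ind$pos))
  expect_true(all(gap_rows$n_gapped_pairs >= 3))
  # abnormal-pair evidence at SV loci
  svs <- dplyr::filter(own, type == "SV")
  ab <- dplyr::filter(p1, !is.na(abnormal_signature))
  expect_identical(nrow(ab), 2L * nrow(svs))
})

test_that("error-free hom-alt evidence is pure and het evidence is balanced", {
  cfg <- sim_config(seed = 21, n_chroms = 1, chrom_length = 40000,
                    n_genes = 0, snp_shared_all = 20, snp_shared_pair = 0,
                    snp_unique = 0, snp_different = 0,
                    cds_effects = c(synonymous = 0), indel_shared_all = 0,
                    indel_shared_pair = 0, indel_unique = 0,
                    indel_different = 0, sv_shared_all = 0, sv_unique = 0,
                    n_uncovered = 0, het_fraction = 0, base_error = 0,
                    pileup_depth = 10, n_ref_sites = 10)
  ds <- simulate_dataset(cfg)
  p <- ds$pileups$S1
  own <- dplyr::filter(ds$truth, sample_id == "S1")
  alt_of <- setNames(own$alt, paste(own$chrom, own$pos))
  for (i in seq_len(nrow(p))) {
    key <- paste(p$chrom[i], p$pos[i])
    expected <- if (key %in% names(alt_of)) alt_of[[key]] else p$ref[i]
    expect_identical(unique(strsplit(p$bases[i], "")[[1]]), expected)
  }
  # het site with large depth and no error: alt fraction ~ 1/2
  set.seed(99)
  bases <- resevar:::draw_bases(10000, c("A", "G"), 0)
  frac_g <- mean(strsplit(bases, "")[[1]] == "G")
  expect_true(abs(frac_g - 0.5) < 0.02)  # ~4 binomial sd
})

test_that("the full dataset is byte-identical under a repeated seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 31, n_chroms = 1, chrom_length = 40000,
                    n_genes = 3, snp_shared_all = 10, snp_shared_pair = 2,
                    snp_unique = 2, snp_different = 2,
                    cds_effects = c(synonymous = 1), indel_shared_all = 2,
                    indel_shared_pair = 1, indel_unique = 1,
                    indel_different = 1, sv_shared_all = 1, sv_unique = 0,
                    n_uncovered = 1, n_ref_sites = 10)
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
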