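# Simplified Bayesian diploid genotype caller and the acceptance filters for
# SNPs, short InDels and structural variants.
#
# The caller is a standard independent-reads diploid model: for each of the
# 10 diploid genotypes, likelihood = product over reads of P(base|genotype)
# with per-base error eps = 10^(-q/10) spread equally over the three other
# bases; a heterozygote emits each of its alleles with probability 1/2
# (each then subject to the same error). Posterior = prior x likelihood,
# normalized; the reported quality value is the phred-scaled posterior of
# the argmax genotype, Q = -10 log10(1 - posterior).

DIPLOID_GENOTYPES <- {
  g <- expand.grid(a1 = DNA_BASES, a2 = DNA_BASES, stringsAsFactors = FALSE)
  g <- g[g$a1 <= g$a2, ]
  rownames(g) <- NULL
  g
}

#' Genotype priors for an inbred diploid
#'
#' Probability mass on homozygous-reference, each homozygous-alternate and
#' each heterozygous genotype; normalized over the 10 diploid genotypes.
#' The defaults encode the inbred-line expectation that non-reference and
#' especially heterozygous genotypes are rare.
#'
#' @param p_hom_ref,p_hom_alt,p_het Prior mass on the hom-ref genotype, on
#'   each of the 3 hom-alt genotypes, and on each of the 6 heterozygous
#'   genotypes.
#' @return A function of the reference base returning a named vector of 10
#'   normalized prior probabilities.
#' @export
genotype_priors <- function(p_hom_ref = 0.998, p_hom_alt = 5e-4,
                            p_het = 1e-4) {
  force(p_hom_ref); force(p_hom_alt); force(p_het)
  function(ref) {
    g <- DIPLOID_GENOTYPES
    p <- ifelse(g$a1 == g$a2,
                ifelse(g$a1 == ref, p_hom_ref, p_hom_alt),
                p_het)
    p <- p / sum(p)
    setNames(p, paste0(g$a1, g$a2))
  }
}

phred_to_error <- function(q) 10^(-q / 10)

#' Call the genotype at one site
#'
#' @param bases Character vector of observed bases (A/C/G/T), one per read,
#'   or a single collapsed string.
#' @param quals Numeric phred qualities, one per read (recycled if length 1).
#' @param ref Reference base at the site.
#' @param prior A prior function from [genotype_priors()].
#' @return A one-row tibble: `genotype` (e.g. `"AG"`), `zygosity`
#'   (`hom_ref`/`hom_alt`/`het`), `alt` (non-reference allele or `NA`),
#'   `posterior`, `qual` (phred posterior), `support` (reads carrying the
#'   called non-reference allele), `depth`.
#' @export
genotype_site <- function(bases, quals, ref, prior = genotype_priors()) {
  if (length(bases) == 1 && nchar(bases[1]) > 1) {
    bases <- strsplit(bases, "")[[1]]
  }
  n <- length(bases)
  if (n == 0) stop("no evidence at site", call. = FALSE)
  if (!all(bases %in% DNA_BASES)) {
    stop("observed bases must be A/C/G/T", call. = FALSE)
  }
  quals <- rep_len(quals, n)
  eps <- phred_to_error(quals)
  g <- DIPLOID_GENOTYPES
  loglik <- vapply(seq_len(nrow(g)), function(i) {
    p1 <- ifelse(bases == g$a1[i], 1 - eps, eps / 3)
    p2 <- ifelse(bases == g$a2[i], 1 - eps, eps / 3)
    sum(log(0.5 * p1 + 0.5 * p2))
  }, double(1))
  pr <- prior(ref)
  logpost <- log(pr) + loglik
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  # deterministic tie-break: hom_ref, then hom_alt (allele order), then het
  zyg_rank <- ifelse(g$a1 == g$a2 & g$a1 == ref, 0L,
                     ifelse(g$a1 == g$a2, 1L, 2L))
  ord <- order(-post, zyg_rank, g$a1, g$a2)
  best <- ord[1]
  p_best <- unname(post[best])
  q <- -10 * log10(max(1 - p_best, 1e-100))
  q <- min(q, 1000)
  a1 <- g$a1[best]; a2 <- g$a2[best]
  zyg <- if (a1 == a2 && a1 == ref) "hom_ref"
         else if (a1 == a2) "hom_alt" else "het"
  alt <- setdiff(unique(c(a1, a2)), ref)
  alt <- if (length(alt)) alt[1] else NA_character_
  support <- if (is.na(alt)) 0L else sum(bases == alt)
  tibble(genotype = paste0(a1, a2), zygosity = zyg, alt = alt,
         posterior = p_best, qual = q, support = as.integer(support),
         depth = n)
}

# full posterior vector over the 10 genotypes (used by tests/oracles)
genotype_posteriors <- function(bases, quals, ref,
                                prior = genotype_priors()) {
  if (length(bases) == 1 && nchar(bases[1]) > 1) {
    bases <- strsplit(bases, "")[[1]]
  }
  quals <- rep_len(quals, length(bases))
  eps <- phred_to_error(quals)
  g <- DIPLOID_GENOTYPES
  lik <- vapply(seq_len(nrow(g)), function(i) {
    p1 <- ifelse(bases == g$a1[i], 1 - eps, eps / 3)
    p2 <- ifelse(bases == g$a2[i], 1 - eps, eps / 3)
    prod(0.5 * p1 + 0.5 * p2)
  }, double(1))
  p <- prior(ref) * lik
  setNames(p / sum(p), paste0(g$a1, g$a2))
}

#' Genotype every site of a pileup
#'
#' @param pileup A pileup tibble (see [read_pileup()]).
#' @param prior A prior function from [genotype_priors()].
#' @return The pileup positions with the genotype-call columns of
#'   [genotype_site()] bound on.
#' @export
call_genotypes <- function(pileup, prior = genotype_priors()) {
  sites <- pileup |> filter(is.na(.data$gap_type) &
                              is.na(.data$abnormal_signature))
  if (!nrow(sites)) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  genotype = character(), zygosity = character(),
                  alt = character(), posterior = double(), qual = double(),
                  support = integer(), depth = integer()))
  }
  calls <- purrr::map(seq_len(nrow(sites)), function(i) {
    q <- utf8ToInt(sites$quals[i]) - 33L
    genotype_site(sites$bases[i], q, sites$ref[i], prior)
  })
  bind_rows(
    purrr::map2(calls, seq_len(nrow(sites)), function(cl, i) {
      dplyr::bind_cols(sites[i, c("chrom", "pos", "ref")], cl)
    })
  )
}

#' Filter SNP genotype calls per the acceptance rule
#'
#' Keeps non-reference calls whose quality value is strictly greater than
#' `min_qual` and whose called allele is supported by at least
#' `min_support` reads.
#'
#' @param calls Output of [call_genotypes()].
#' @param sample_id Sample to stamp on the accepted records.
#' @param min_qual Quality threshold (strict `>`); default 20.
#' @param min_support Minimum supporting reads (`>=`); default 2.
#' @return A variant tibble of accepted SNPs.
#' @export
filter_snp_calls <- function(calls, sample_id = "sample", min_qual = 20,
                             min_support = 2L) {
  keep <- calls |>
    filter(.data$zygosity != "hom_ref",
           .data$qual > min_qual,
           .data$support >= min_support)
  as_variant_tbl(keep |>
    mutate(sample_id = sample_id, type = "SNP",
           zygosity = if_else(.data$zygosity == "het", "het", "hom")) |>
    select(dplyr::all_of(c("sample_id", "chrom", "pos", "ref", "alt", "type",
                           "zygosity", "qual", "support"))))
}

#' Call short InDels from gapped-read evidence
#'
#' Keeps gaps of length 1 to `max_len` bp supported by at least
#' `min_gapped_pairs` gapped read pairs; zero-length gap records are skipped
#' with a warning.
#'
#' @param pileup A pileup tibble.
#' @param sample_id Sample to stamp on the records.
#' @param max_len Maximum gap length (default 5 bp).
#' @param min_gapped_pairs Minimum gapped read-pair support (default 3).
#' @return A variant tibble of accepted insertions/deletions.
#' @export
call_indels <- function(pileup, sample_id = "sample", max_len = 5L,
                        min_gapped_pairs = 3L) {
  gaps <- pileup |> filter(!is.na(.data$gap_type))
  if (!nrow(gaps)) return(empty_variants())
  len <- nchar(gaps$gap_seq)
  len[is.na(gaps$gap_seq)] <- 0L
  if (any(len == 0)) {
    warning(sum(len == 0), " gap record(s) of length 0 skipped",
            call. = FALSE)
  }
  keep <- gaps[len >= 1L & len <= max_len &
                 !is.na(gaps$n_gapped_pairs) &
                 gaps$n_gapped_pairs >= min_gapped_pairs, , drop = FALSE]
  if (!nrow(keep)) return(empty_variants())
  as_variant_tbl(tibble(
    sample_id = sample_id, chrom = keep$chrom, pos = keep$pos,
    ref = if_else(keep$gap_type == "DEL",
                  paste0(keep$ref, keep$gap_seq), keep$ref),
    alt = if_else(keep$gap_type == "INS",
                  paste0(keep$ref, keep$gap_seq), keep$ref),
    type = keep$gap_type, zygosity = "hom", qual = NA_real_,
    support = keep$n_gapped_pairs
  ))
}

#' Call structural variants from abnormal read-pair evidence
#'
#' Clusters adjacent sites carrying the same abnormal-pair signature (gap
#' between sites at most `join_distance`), and emits one SV per cluster
#' whose summed abnormal-pair support reaches `min_abnormal_pairs`, typed by
#' the signature and spanning the clustered sites.
#'
#' @param pileup A pileup tibble.
#' @param sample_id Sample to stamp on the records.
#' @param min_abnormal_pairs Minimum summed abnormal-pair support
#'   (default 3).
#' @param join_distance Maximum gap between clustered sites (default 1 kb).
#' @return A variant tibble of accepted SVs.
#' @export
call_svs <- function(pileup, sample_id = "sample", min_abnormal_pairs = 3L,
                     join_distance = 1000L) {
  ab <- pileup |> filter(!is.na(.data$abnormal_signature))
  if (!nrow(ab)) return(empty_variants())
  bad <- setdiff(unique(ab$abnormal_signature), SV_TYPES)
  if (length(bad)) {
    stop("unknown abnormal-pair signature: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  clusters <- ab |>
    arrange(.data$chrom, .data$abnormal_signature, .data$pos) |>
    group_by(.data$chrom, .data$abnormal_signature) |>
    mutate(cluster = cumsum(
      c(TRUE, diff(.data$pos) > join_distance))) |>
    group_by(.data$chrom, .data$abnormal_signature, .data$cluster) |>
    summarise(
      sv_end = max(.data$pos) + 1L, pos = min(.data$pos),
      support = sum(.data$n_abnormal_pairs, na.rm = TRUE),
      ref = first(.data$ref), .groups = "drop") |>
    filter(.data$support >= min_abnormal_pairs)
  if (!nrow(clusters)) return(empty_variants())
  as_variant_tbl(tibble(
    sample_id = sample_id, chrom = clusters$chrom, pos = clusters$pos,
    ref = clusters$ref, alt = sv_alt_symbol(clusters$abnormal_signature),
    type = "SV", zygosity = "hom", qual = NA_real_,
    support = as.integer(clusters$support),
    sv_type = clusters$abnormal_signature, sv_end = clusters$sv_end
  ))
}

#' Run the full calling stage on one sample's evidence
#'
#' Genotypes every base-call site, applies the SNP quality/support filter,
#' and calls InDels and SVs from the gap and abnormal-pair evidence.
#'
#' @param pileup A pileup tibble.
#' @param sample_id Sample identifier.
#' @param prior Genotype prior function.
#' @param min_qual,min_support SNP filter thresholds.
#' @param max_indel_len,min_gapped_pairs InDel filter thresholds.
#' @param min_abnormal_pairs,join_distance SV filter thresholds.
#' @return A variant tibble with all accepted SNPs, InDels and SVs.
#' @export
call_variants <- function(pileup, sample_id = "sample",
                          prior = genotype_priors(),
                          min_qual = 20, min_support = 2L,
                          max_indel_len = 5L, min_gapped_pairs = 3L,
                          min_abnormal_pairs = 3L, join_distance = 1000L) {
  snps <- filter_snp_calls(call_genotypes(pileup, prior), sample_id,
                           min_qual, min_support)
  indels <- call_indels(pileup, sample_id, max_indel_len, min_gapped_pairs)
  svs <- call_svs(pileup, sample_id, min_abnormal_pairs, join_distance)
  as_variant_tbl(bind_rows(snps, indels, svs))
}
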