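# Variant spiking with a known truth table, coverage-mask generation and
# site-level read evidence.

# Occupancy-vector allocator: one logical vector per chromosome marks
# reserved positions, so reservation checks are O(footprint).
new_allocator <- function(genome, avoid = NULL) {
  env <- new.env(parent = emptyenv())
  env$used <- setNames(
    lapply(genome$length, function(n) logical(n)), genome$chrom)
  if (!is.null(avoid) && nrow(avoid)) {
    for (i in seq_len(nrow(avoid))) {
      ch <- avoid$chrom[i]
      env$used[[ch]][(avoid$start[i] + 1L):avoid$end[i]] <- TRUE
    }
  }
  env$genome <- genome
  env
}

alloc_reserve <- function(alloc, chrom, start, end) {
  idx <- (start + 1L):end
  if (any(alloc$used[[chrom]][idx])) return(FALSE)
  alloc$used[[chrom]][idx] <- TRUE
  TRUE
}

# sample a free locus of given footprint (avoid handled at allocator
# construction); returns list(chrom, pos) or errors
alloc_random <- function(alloc, footprint, avoid = NULL, margin = 10L,
                         what = "locus") {
  genome <- alloc$genome
  for (try in seq_len(500L)) {
    ci <- sample.int(nrow(genome), 1, prob = genome$length)
    len <- genome$length[ci]
    if (len - footprint - 2L * margin <= 0) next
    pos <- sample.int(len - footprint - 2L * margin, 1) + margin
    chrom <- genome$chrom[ci]
    if (!is.null(avoid) && nrow(avoid)) {
      a <- avoid[avoid$chrom == chrom, , drop = FALSE]
      if (nrow(a) && any(a$start < pos + footprint & a$end > pos)) next
    }
    if (alloc_reserve(alloc, chrom, pos, pos + footprint)) {
      return(list(chrom = chrom, pos = as.integer(pos)))
    }
  }
  stop("could not place ", what, "; genome too small for requested counts",
       call. = FALSE)
}

cds_ranges_tbl <- function(genes) {
  if (!nrow(genes)) return(tibble(chrom = character(), start = integer(),
                                  end = integer()))
  bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    mutate(genes$cds[[i]], chrom = genes$chrom[i])
  }))[, c("chrom", "start", "end")]
}

gene_spans_tbl <- function(genes) {
  if (!nrow(genes)) return(tibble(chrom = character(), start = integer(),
                                  end = integer()))
  genes[, c("chrom", "start", "end")]
}

# Find a (gene, genomic pos, genomic ref, genomic alt) producing the
# requested coding effect through a single substitution.
find_effect_site <- function(genes, genome, effect, alloc) {
  ann <- genes[genes$annotatable, , drop = FALSE]
  if (!nrow(ann)) stop("no annotatable genes for effect spiking", call. = FALSE)
  for (try in seq_len(500L)) {
    gi <- sample.int(nrow(ann), 1)
    gene <- ann[gi, ]
    cds <- cds_sequence(gene, genome)
    n_codons <- nchar(cds) %/% 3L
    codon_idx <- switch(effect,
      start_loss = 0L,
      stop_loss = n_codons - 1L,
      sample(seq_len(n_codons - 2L), 1))  # interior codon (1..n-2)
    codon <- substr(cds, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
    cand <- list()
    for (p in 0:2) {
      refb <- substr(codon, p + 1L, p + 1L)
      for (altb in setdiff(DNA_BASES, refb)) {
        altc <- codon
        substr(altc, p + 1L, p + 1L) <- altb
        ok <- switch(effect,
          start_loss = codon == "ATG",
          stop_loss = codon_aa(codon) == "*" && codon_aa(altc) != "*",
          premature_stop = codon_aa(codon) != "*" && codon_aa(altc) == "*",
          synonymous = codon_aa(altc) == codon_aa(codon),
          nonsynonymous = codon_aa(altc) != codon_aa(codon) &&
            codon_aa(altc) != "*" && codon_aa(codon) != "*")
        if (isTRUE(ok)) cand[[length(cand) + 1L]] <- list(p = p, alt = altb)
      }
    }
    if (!length(cand)) next
    pick <- cand[[sample.int(length(cand), 1)]]
    offset <- codon_idx * 3L + pick$p
    gpos <- cds_genomic_positions(gene)[offset + 1L]
    if (!alloc_reserve(alloc, gene$chrom, gpos, gpos + 1L)) next
    ref_g <- genome_base(genome, gene$chrom, gpos)
    alt_g <- if (gene$strand == "+") pick$alt else complement_base(pick$alt)
    return(list(chrom = gene$chrom, pos = gpos, ref = ref_g, alt = alt_g,
                gene_id = gene$gene_id))
  }
  stop("requested CDS effect count exceeds available codon sites for '",
       effect, "'", call. = FALSE)
}

random_alt <- function(ref, n = 1) {
  vapply(seq_len(n), function(i) sample(setdiff(DNA_BASES, ref), 1),
         character(1))
}

#' Spike variants into synthetic samples with a known truth table
#'
#' Generates exact requested counts of each comparison class (shared by all
#' samples, shared by a pair, unique to one sample, allelic-different with a
#' distinct alternate base per carrier) and intended coding-effect class,
#' plus per-sample heterozygous background SNPs at `het_fraction`, short
#' InDels and structural variants.
#'
#' @param genome Genome tibble (after [simulate_gene_models()]).
#' @param genes Gene-model tibble.
#' @param config A [sim_config()].
#' @return A list with `variants` (all samples, one tibble) and `truth`
#'   (one row per locus x carrier sample, with `locus_id`,
#'   `comparison_class`, `pair`, `effect_class`, `uncovered_sample`).
#' @export
spike_variants <- function(genome, genes, config) {
  set.seed(seed_stream(config$seed, 3L))
  samples <- config$sample_ids
  n_s <- length(samples)
  alloc <- new_allocator(genome)
  # keep effect sites and random loci apart from gene machinery as needed
  cds_tbl <- cds_ranges_tbl(genes)
  gene_tbl <- gene_spans_tbl(genes)
  # reserve start/stop codons of each gene so random InDels/SVs cannot
  # disturb intended ORFs (SNP loci avoid CDS anyway)
  rows <- list()
  lid <- 0L
  add_locus <- function(chrom, pos, ref, alt_by_sample, type,
                        comparison_class, pair = NA_character_,
                        effect_class = NA_character_,
                        zygosity = "hom", uncovered_sample = NA_character_,
                        sv_type = NA_character_, sv_end = NA_integer_,
                        gene_id = NA_character_) {
    lid <<- lid + 1L
    carriers <- names(alt_by_sample)
    rows[[length(rows) + 1L]] <<- data.frame(
      locus_id = sprintf("L%05d", lid), chrom = chrom, pos = as.integer(pos),
      ref = ref, alt = unname(unlist(alt_by_sample)), type = type,
      sample_id = carriers, zygosity = zygosity,
      comparison_class = comparison_class, pair = pair,
      effect_class = effect_class, uncovered_sample = uncovered_sample,
      sv_type = sv_type, sv_end = sv_end, gene_id = gene_id,
      stringsAsFactors = FALSE
    )
  }
  region_of <- function(chrom, pos) {
    g <- gene_tbl[gene_tbl$chrom == chrom & gene_tbl$start <= pos &
                    gene_tbl$end > pos, , drop = FALSE]
    if (nrow(g)) "noncds_gene" else "intergenic"
  }
  spike_snp_class <- function(n, class, carriers_fun, pair_lab = NA) {
    for (k in seq_len(n)) {
      loc <- alloc_random(alloc, 1L, avoid = cds_tbl, what = "SNP locus")
      ref <- genome_base(genome, loc$chrom, loc$pos)
      info <- carriers_fun(ref)
      add_locus(loc$chrom, loc$pos, ref, info$alts, "SNP", class,
                pair = info$pair %||% pair_lab,
                effect_class = region_of(loc$chrom, loc$pos),
                uncovered_sample = info$uncovered %||% NA_character_)
    }
  }
  pairs <- utils::combn(samples, 2, simplify = FALSE)

  # --- coding-effect SNPs (shared by all samples) ---
  for (eff in names(config$cds_effects)) {
    for (k in seq_len(config$cds_effects[[eff]])) {
      site <- find_effect_site(genes, genome, eff, alloc)
      add_locus(site$chrom, site$pos, site$ref,
                setNames(rep(site$alt, n_s), samples), "SNP", "shared_all",
                effect_class = eff, gene_id = site$gene_id)
    }
  }
  # --- plain SNP comparison classes ---
  spike_snp_class(config$snp_shared_all, "shared_all", function(ref) {
    list(alts = setNames(rep(random_alt(ref), n_s), samples))
  })
  for (p in pairs) {
    lab <- paste(p, collapse = "+")
    spike_snp_class(config$snp_shared_pair, "shared_pair", function(ref) {
      list(alts = setNames(rep(random_alt(ref), 2L), p), pair = lab)
    })
  }
  for (s in samples) {
    spike_snp_class(config$snp_unique, "unique", function(ref) {
      list(alts = setNames(random_alt(ref), s))
    })
  }
  if (config$snp_different > 0 && n_s > 4) {
    stop("allelic-different SNPs need <= 4 samples (distinct bases)",
         call. = FALSE)
  }
  spike_snp_class(config$snp_different, "different", function(ref) {
    list(alts = setNames(sample(setdiff(DNA_BASES, ref), n_s), samples))
  })
  # --- deliberately uncovered loci: carried (same alt) by all samples but
  # one; that one is left uncovered there, making the locus ineligible ---
  for (k in seq_len(config$n_uncovered)) {
    unc <- samples[((k - 1L) %% n_s) + 1L]
    carriers <- setdiff(samples, unc)
    # reserve a wide footprint so the deliberate coverage gap (+/- 25 bp)
    # cannot swallow a neighbouring spiked locus
    wide <- alloc_random(alloc, 61L, avoid = cds_tbl, what = "SNP locus")
    loc <- list(chrom = wide$chrom, pos = wide$pos + 30L)
    ref <- genome_base(genome, loc$chrom, loc$pos)
    add_locus(loc$chrom, loc$pos, ref,
              setNames(rep(random_alt(ref), length(carriers)), carriers),
              "SNP", "ineligible",
              effect_class = region_of(loc$chrom, loc$pos),
              uncovered_sample = unc)
  }
  # --- heterozygous background SNPs (sample-unique, zygosity het) ---
  exp_cov <- round(config$coverage_fraction * sum(genome$length))
  for (s in samples) {
    n_het <- rbinom(1L, exp_cov, config$het_fraction)
    for (k in seq_len(n_het)) {
      loc <- alloc_random(alloc, 1L, avoid = cds_tbl, what = "het SNP locus")
      ref <- genome_base(genome, loc$chrom, loc$pos)
      add_locus(loc$chrom, loc$pos, ref, setNames(random_alt(ref), s),
                "SNP", "het", zygosity = "het",
                effect_class = region_of(loc$chrom, loc$pos))
    }
  }
  # --- InDels ---
  make_indel <- function() {
    len <- sample.int(config$indel_max_len, 1)
    ins <- runif(1) < 0.5
    foot <- if (ins) 1L else len + 1L
    loc <- alloc_random(alloc, foot + 1L, avoid = cds_tbl,
                        what = "InDel locus")
    chrom_seq <- genome_sequence(genome, loc$chrom)
    anchor <- substr(chrom_seq, loc$pos + 1L, loc$pos + 1L)
    if (ins) {
      seqv <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      list(chrom = loc$chrom, pos = loc$pos, ref = anchor,
           alt = paste0(anchor, seqv), type = "INS")
    } else {
      delseq <- substr(chrom_seq, loc$pos + 2L, loc$pos + 1L + len)
      list(chrom = loc$chrom, pos = loc$pos, ref = paste0(anchor, delseq),
           alt = anchor, type = "DEL")
    }
  }
  spike_indel_class <- function(n, class, carriers, pair_lab = NA_character_,
                                different = FALSE) {
    for (k in seq_len(n)) {
      iv <- make_indel()
      if (different) {
        # same anchor, distinct inserted sequences per carrier
        lens <- sample.int(config$indel_max_len, length(carriers),
                           replace = TRUE)
        draw_alt <- function(i) {
          paste0(substr(iv$ref, 1, 1),
                 paste(sample(DNA_BASES, lens[i], replace = TRUE),
                       collapse = ""))
        }
        alts <- vapply(seq_along(carriers), draw_alt, character(1))
        while (anyDuplicated(alts)) {
          alts[duplicated(alts)] <- vapply(which(duplicated(alts)), draw_alt,
                                           character(1))
        }
        add_locus(iv$chrom, iv$pos, substr(iv$ref, 1, 1),
                  setNames(alts, carriers), "INS", class, pair = pair_lab,
                  effect_class = region_of(iv$chrom, iv$pos))
      } else {
        add_locus(iv$chrom, iv$pos, iv$ref,
                  setNames(rep(iv$alt, length(carriers)), carriers),
                  iv$type, class, pair = pair_lab,
                  effect_class = region_of(iv$chrom, iv$pos))
      }
    }
  }
  spike_indel_class(config$indel_shared_all, "shared_all", samples)
  for (p in pairs) {
    spike_indel_class(config$indel_shared_pair, "shared_pair", p,
                      pair_lab = paste(p, collapse = "+"))
  }
  for (s in samples) spike_indel_class(config$indel_unique, "unique", s)
  spike_indel_class(config$indel_different, "different", samples,
                    different = TRUE)
  # --- SVs ---
  spike_sv_class <- function(n, class, carriers) {
    for (k in seq_len(n)) {
      loc <- alloc_random(alloc, config$sv_span + 2L, avoid = gene_tbl,
                          what = "SV locus")
      ref <- genome_base(genome, loc$chrom, loc$pos)
      svt <- SV_TYPES[((lid) %% 4L) + 1L]
      add_locus(loc$chrom, loc$pos, ref,
                setNames(rep(sv_alt_symbol(svt), length(carriers)), carriers),
                "SV", class, effect_class = "intergenic",
                sv_type = svt, sv_end = loc$pos + config$sv_span)
    }
  }
  spike_sv_class(config$sv_shared_all, "shared_all", samples)
  for (s in samples) spike_sv_class(config$sv_unique, "unique", s)

  truth <- as_tibble(bind_rows(rows))
  variants <- truth |>
    mutate(qual = 60, support = NA_integer_) |>
    select(dplyr::all_of(c("sample_id", "chrom", "pos", "ref", "alt", "type",
                           "zygosity", "qual", "support", "sv_type",
                           "sv_end"))) |>
    as_variant_tbl()
  list(variants = variants, truth = truth)
}
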