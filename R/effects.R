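# Coding-effect annotation: gene-model localization, synonymous /
# non-synonymous classification and the three large-effect categories
# (premature stop, start-codon loss, stop-codon loss), plus per-gene
# DNA-vs-mRNA variant surveys.

#' Localize variants against gene models
#'
#' @param variants Variant tibble.
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param genome Optional genome tibble; when supplied, positions beyond a
#'   chromosome end raise an error.
#' @return The variants with `gene_id` (NA for intergenic) and `region`
#'   (`"CDS"`, `"noncds_gene"`, `"intergenic"`) columns, plus a
#'   `near_splice` flag for positions within 2 bp of an internal
#'   exon/intron boundary. A variant hitting several (overlapping) genes
#'   yields one row per gene.
#' @export
map_variants_to_genes <- function(variants, genes, genome = NULL) {
  if (!is.null(genome)) {
    len <- genome$length[match(variants$chrom, genome$chrom)]
    if (any(is.na(len)) || any(variants$pos >= len)) {
      stop("variant position beyond chromosome end", call. = FALSE)
    }
  }
  v <- variants
  v$.row <- seq_len(nrow(v))
  intergenic <- function(df) {
    df$gene_id <- NA_character_
    df$region <- "intergenic"
    df$near_splice <- FALSE
    df
  }
  if (!nrow(genes) || !nrow(v)) {
    return(select(intergenic(v), -dplyr::all_of(".row")))
  }
  # per-gene CDS segment table and internal-boundary table
  cds <- bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    segs <- genes$cds[[i]]
    tibble(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
           start = segs$start, end = segs$end)
  }))
  bnd <- cds |>
    group_by(.data$gene_id, .data$chrom) |>
    dplyr::reframe(b = setdiff(sort(unique(c(.data$start, .data$end))),
                               c(min(.data$start), max(.data$end))))
  pieces <- list()
  for (ch in unique(v$chrom)) {
    g <- genes |> filter(.data$chrom == ch)
    vi <- v |> filter(.data$chrom == ch)
    if (!nrow(g)) { pieces[[ch]] <- intergenic(vi); next }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(vi$pos + 1L, vi$pos + 1L),
      IRanges::IRanges(g$start + 1L, g$end))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    inter <- intergenic(vi[setdiff(seq_len(nrow(vi)), unique(qh)), ,
                           drop = FALSE])
    hit <- vi[qh, , drop = FALSE]
    hit$gene_id <- g$gene_id[sh]
    # CDS membership per (variant, gene) pair
    c_ch <- cds |> filter(.data$chrom == ch)
    in_cds <- rep(FALSE, nrow(hit))
    if (nrow(c_ch)) {
      ov2 <- IRanges::findOverlaps(
        IRanges::IRanges(hit$pos + 1L, hit$pos + 1L),
        IRanges::IRanges(c_ch$start + 1L, c_ch$end))
      q2 <- S4Vectors::queryHits(ov2); s2 <- S4Vectors::subjectHits(ov2)
      match_gene <- hit$gene_id[q2] == c_ch$gene_id[s2]
      in_cds[unique(q2[match_gene])] <- TRUE
    }
    hit$region <- if_else(in_cds, "CDS", "noncds_gene")
    b_ch <- bnd |> filter(.data$chrom == ch)
    hit$near_splice <- FALSE
    if (nrow(b_ch)) {
      key_hit <- paste(hit$gene_id, hit$pos)
      near_keys <- unlist(lapply(-2:2, function(dd) {
        c(paste(b_ch$gene_id, b_ch$b + dd),
          paste(b_ch$gene_id, b_ch$b - 1L + dd))
      }))
      hit$near_splice <- key_hit %in% near_keys
    }
    pieces[[ch]] <- bind_rows(inter, hit)
  }
  bind_rows(pieces) |> arrange(.data$.row) |>
    select(-dplyr::all_of(".row"))
}

#' Classify the coding effect of SNPs
#'
#' For each SNP falling in the CDS of an annotatable gene, rebuilds the
#' affected codon strand-aware, translates reference and alternate codons
#' under the standard genetic code, and assigns exactly one effect:
#' `synonymous`, `nonsynonymous`, `premature_stop` (sense to stop before
#' the terminal codon), `start_loss` (initiation ATG abolished) or
#' `stop_loss` (terminal stop to sense). SNPs outside CDS get effect
#' `none`; CDS SNPs in genes whose CDS length is not a multiple of three
#' get `not_annotatable`.
#'
#' @param snps SNP variant tibble.
#' @param genes Gene-model tibble.
#' @param genome Genome tibble (reference bases are checked against `ref`).
#' @return The SNPs with `gene_id`, `region` and `effect` columns (one row
#'   per variant-gene pair).
#' @export
classify_snp_effects <- function(snps, genes, genome) {
  v <- snps |> filter(.data$type == "SNP")
  mapped <- map_variants_to_genes(v, genes, genome)
  mapped$effect <- "none"
  idx <- which(mapped$region == "CDS")
  if (!length(idx)) return(mapped)
  for (gid in unique(mapped$gene_id[idx])) {
    gene <- genes[genes$gene_id == gid, ]
    gidx <- idx[mapped$gene_id[idx] == gid]
    if (!gene$annotatable) { mapped$effect[gidx] <- "not_annotatable"; next }
    cds_pos <- cds_genomic_positions(gene)
    cds <- cds_sequence(gene, genome)
    pos <- mapped$pos[gidx]
    refb <- substring(genome_sequence(genome, gene$chrom), pos + 1L,
                      pos + 1L)
    bad <- refb != mapped$ref[gidx]
    if (any(bad)) {
      stop("reference mismatch at ", gene$chrom, ":", pos[bad][1] + 1L,
           " (genome ", refb[bad][1], ", record ",
           mapped$ref[gidx][bad][1], ")", call. = FALSE)
    }
    off <- match(pos, cds_pos) - 1L - gene$phase
    codon_idx <- off %/% 3L
    p <- off %% 3L
    n_codons <- (nchar(cds) - gene$phase) %/% 3L
    codon <- substring(cds, gene$phase + codon_idx * 3L + 1L,
                       gene$phase + codon_idx * 3L + 3L)
    alt_tx <- if (gene$strand == "+") mapped$alt[gidx]
              else complement_base(mapped$alt[gidx])
    alt_codon <- paste0(substr(codon, 1, p), alt_tx,
                        substring(codon, p + 2L, 3L))
    ref_aa <- codon_aa(codon); alt_aa <- codon_aa(alt_codon)
    last <- codon_idx == n_codons - 1L
    mapped$effect[gidx] <- dplyr::case_when(
      is.na(off) | off < 0 ~ "none",
      codon_idx == 0L & codon == "ATG" & alt_codon != "ATG" ~ "start_loss",
      alt_aa == "*" & ref_aa != "*" & !last ~ "premature_stop",
      ref_aa == "*" & alt_aa != "*" & last ~ "stop_loss",
      alt_aa == ref_aa ~ "synonymous",
      TRUE ~ "nonsynonymous")
  }
  mapped
}

#' Classify InDels as CDS or non-CDS
#'
#' An InDel is CDS-located iff its reference footprint intersects any CDS
#' segment (an event straddling a CDS boundary counts as CDS). Frameshift
#' potential (length not divisible by 3 within CDS) is emitted as metadata.
#'
#' @param indels InDel variant tibble (`type` INS or DEL).
#' @param genes Gene-model tibble.
#' @return The InDels with `region` (`"CDS"`/`"non-CDS"`) and `frameshift`
#'   columns.
#' @export
classify_indel_region <- function(indels, genes) {
  v <- indels |> filter(.data$type %in% c("INS", "DEL"))
  cds <- cds_ranges_tbl(genes)
  foot_end <- v$pos + nchar(v$ref)
  in_cds <- rep(FALSE, nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    c_ch <- cds |> filter(.data$chrom == ch)
    if (!nrow(c_ch)) next
    in_cds[idx] <- IRanges::overlapsAny(
      IRanges::IRanges(v$pos[idx] + 1L, foot_end[idx]),
      IRanges::IRanges(c_ch$start + 1L, c_ch$end))
  }
  len <- abs(nchar(v$alt) - nchar(v$ref))
  v$region <- if_else(in_cds, "CDS", "non-CDS")
  v$frameshift <- in_cds & (len %% 3L != 0L)
  v
}

#' Per-gene DNA vs mRNA variant survey
#'
#' For each gene and sample: `dna` counts variants anywhere in the gene's
#' genomic span; `mrna` counts variants within exonic (CDS-retained)
#' sequence.
#'
#' @param variants Variant tibble.
#' @param genes Gene-model tibble.
#' @param gene_ids Genes to survey; default all. Unknown ids raise an error
#'   listing the known ones.
#' @return A tibble: `gene_id`, `sample_id`, `dna`, `mrna`.
#' @export
gene_survey <- function(variants, genes, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- genes$gene_id
  unknown <- setdiff(gene_ids, genes$gene_id)
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "),
         "; known: ", paste(genes$gene_id, collapse = ", "), call. = FALSE)
  }
  samples <- sort(unique(variants$sample_id))
  out <- list()
  for (gid in gene_ids) {
    gene <- genes[genes$gene_id == gid, ]
    segs <- gene$cds[[1]]
    v <- variants |> filter(.data$chrom == gene$chrom,
                            .data$pos >= gene$start, .data$pos < gene$end)
    for (s in samples) {
      vs <- v |> filter(.data$sample_id == s)
      exonic <- vapply(vs$pos, function(p) {
        any(p >= segs$start & p < segs$end)
      }, logical(1))
      out[[length(out) + 1L]] <- tibble(
        gene_id = gid, sample_id = s,
        dna = nrow(vs), mrna = sum(exonic))
    }
  }
  bind_rows(out)
}
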