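# Readers/writers for the standard formats the pipeline touches.
# Internal convention: 0-based half-open coordinates everywhere; conversion
# to/from the 1-based conventions of FASTA-indexed formats, VCF and GFF3
# happens only in this file.

#' Read a reference genome from FASTA
#'
#' Loads every record, preserving order, and enforces a strict nucleotide
#' alphabet (A/C/G/T/N after upper-casing).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per chromosome and columns `chrom`, `seq`
#'   (uppercase nucleotide string) and `length`.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path, call. = FALSE)
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    stop("duplicate chromosome name in FASTA: ",
         nms[duplicated(nms)][1], call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0) {
      stop(sprintf("non-nucleotide character '%s' in record '%s' at offset %d",
                   substr(seqs[[i]], bad, bad), nms[i], bad - 1L),
           call. = FALSE)
    }
  }
  tibble(chrom = nms, seq = unname(seqs), length = unname(nchar(seqs)))
}

#' Write a genome tibble to FASTA
#'
#' @param genome Genome tibble as returned by [read_genome_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(setNames(genome$seq, genome$chrom))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features, groups CDS segments per gene in
#' transcription order (descending genomic coordinate on the minus strand)
#' and converts 1-based inclusive GFF3 coordinates to the package's 0-based
#' half-open convention. Genes whose concatenated CDS length is not a
#' multiple of three are flagged `annotatable = FALSE` with a warning; codon
#' effects are not computed for them.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (gene span, 0-based half-open), `cds_len`, `phase`
#'   (phase of the first CDS segment in transcription order), `annotatable`
#'   and a list-column `cds` of per-segment tibbles (`start`, `end`) in
#'   transcription order.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  if (!nrow(df)) return(gene_model_tbl(list()))
  df$type <- as.character(df$type)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  cdss <- df[df$type == "CDS", , drop = FALSE]
  parent_of <- function(x) vapply(x, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  mrna_parent <- setNames(parent_of(mrnas$Parent), mrnas$ID)
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    strand <- as.character(g$strand)
    if (!strand %in% c("+", "-")) {
      stop("unknown strand '", strand, "' for gene ", g$ID, call. = FALSE)
    }
    own_mrnas <- mrnas$ID[parent_of(mrnas$Parent) == g$ID]
    cds_parent <- parent_of(cdss$Parent)
    seg <- cdss[cds_parent %in% c(g$ID, own_mrnas), , drop = FALSE]
    if (nrow(seg) == 0) next
    if (any(seg$start < g$start | seg$end > g$end)) {
      stop("CDS outside parent gene span for gene ", g$ID, call. = FALSE)
    }
    seg <- seg[order(seg$start), ]
    if (strand == "-") seg <- seg[rev(seq_len(nrow(seg))), ]
    phase0 <- suppressWarnings(as.integer(as.character(seg$phase[1])))
    if (is.na(phase0)) phase0 <- 0L
    cds_tbl <- tibble(start = seg$start - 1L, end = as.integer(seg$end))
    cds_len <- sum(cds_tbl$end - cds_tbl$start)
    annotatable <- (cds_len - phase0) %% 3L == 0L
    if (!annotatable) {
      warning("gene ", g$ID, ": CDS length ", cds_len,
              " not divisible by 3; flagged non-annotatable", call. = FALSE)
    }
    out[[i]] <- tibble(
      gene_id = as.character(g$ID), chrom = as.character(g$seqnames),
      strand = strand, start = g$start - 1L, end = as.integer(g$end),
      cds_len = cds_len, phase = phase0, annotatable = annotatable,
      cds = list(cds_tbl)
    )
  }
  gene_model_tbl(out)
}

gene_model_tbl <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  cds_len = integer(), phase = integer(),
                  annotatable = logical(), cds = list()))
  }
  arrange(bind_rows(rows), .data$chrom, .data$start)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features with ID/Parent links, converting back
#' to 1-based inclusive coordinates.
#'
#' @param genes Gene-model tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id
    mid <- paste0(gid, ".1")
    lines <- c(lines,
      paste(g$chrom, "resevar", "gene", g$start + 1L, g$end, ".", g$strand,
            ".", paste0("ID=", gid), sep = "\t"),
      paste(g$chrom, "resevar", "mRNA", g$start + 1L, g$end, ".", g$strand,
            ".", paste0("ID=", mid, ";Parent=", gid), sep = "\t"))
    segs <- g$cds[[1]]
    # phase per segment in transcription order
    lens <- segs$end - segs$start
    phases <- (3L - (cumsum(dplyr::lag(lens, default = 0L)) %% 3L)) %% 3L
    for (j in seq_len(nrow(segs))) {
      lines <- c(lines,
        paste(g$chrom, "resevar", "CDS", segs$start[j] + 1L, segs$end[j], ".",
              g$strand, phases[j],
              paste0("ID=", mid, ".cds", j, ";Parent=", mid), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read variant records from a single-sample VCF
#'
#' Multi-allelic rows are split into one record per ALT allele. Symbolic
#' ALTs (`<DEL>` etc.) or an `SVTYPE` INFO key mark structural variants.
#' A missing genotype is read as homozygous-alternate with a warning, the
#' expectation for predominantly homozygous inbred lines.
#'
#' @param path Path to a VCF 4.x file with at most one sample column.
#' @param sample_id Sample identifier to attach to the records; defaults to
#'   the VCF sample column name (or the file name if the VCF has none).
#' @return A variant tibble (0-based `pos`) with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `type`, `zygosity`, `qual`, `support`,
#'   `sv_type`, `sv_end`.
#' @export
read_variants_vcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(empty_variants())
  }
  gt <- NULL
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(sample_id)) sample_id <- colnames(v@gt)[2]
  }
  if (is.null(sample_id)) sample_id <- sub("\\.vcf$", "", basename(path))
  info <- fix$INFO
  info[is.na(info)] <- ""
  extract_key <- function(key, pattern = "[^;]+") {
    m <- regexpr(paste0("(?:^|;)", key, "=(", pattern, ")"), info,
                 perl = TRUE)
    out <- rep(NA_character_, length(info))
    hit <- m > 0
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(info, m)[seq_len(sum(hit))])
    out
  }
  svtype <- extract_key("SVTYPE")
  endv <- extract_key("END", "[0-9]+")
  supp <- extract_key("SUPPORT", "[0-9]+")
  g <- if (!is.null(gt)) unname(gt[, 1]) else rep(NA_character_, nrow(fix))
  g_missing <- is.na(g) | g %in% c("./.", ".", ".|.")
  if (any(g_missing)) {
    warning(sum(g_missing), " record(s) with missing genotype at e.g. ",
            fix$CHROM[g_missing][1], ":", fix$POS[g_missing][1],
            "; treated as homozygous-alternate", call. = FALSE)
  }
  zyg <- ifelse(g_missing, "hom",
                ifelse(vapply(strsplit(g, "[/|]"), function(a) {
                  length(unique(a)) == 1
                }, logical(1)), "hom", "het"))
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  i <- rep(seq_len(nrow(fix)), n_alt)
  alt <- unlist(alt_list)
  symbolic <- grepl("^<.*>$", alt)
  is_sv <- symbolic | !is.na(svtype[i])
  type <- ifelse(is_sv, "SV", variant_type_from_alleles(fix$REF[i], alt))
  as_variant_tbl(tibble(
    sample_id = sample_id,
    chrom = fix$CHROM[i],
    pos = as.integer(fix$POS[i]) - 1L,
    ref = fix$REF[i],
    alt = alt,
    type = type,
    zygosity = zyg[i],
    qual = suppressWarnings(as.double(fix$QUAL[i])),
    support = suppressWarnings(as.integer(supp[i])),
    sv_type = ifelse(is_sv, normalize_sv_type(svtype[i], alt),
                     NA_character_),
    sv_end = ifelse(is_sv, suppressWarnings(as.integer(endv[i])),
                    NA_integer_)
  ))
}

normalize_sv_type <- function(svtype, alt = NA_character_) {
  alt <- rep_len(alt, length(svtype))
  x <- ifelse(is.na(svtype) & !is.na(alt), gsub("[<>]", "", alt), svtype)
  dplyr::case_when(
    toupper(x) %in% c("DEL", "DELETION") ~ "deletion",
    toupper(x) %in% c("DUP", "DUPLICATION", "REPLICATION") ~ "duplication",
    toupper(x) %in% c("INV", "INVERSION", "REVERSION") ~ "inversion",
    toupper(x) %in% c("TRA", "BND", "TRANSPOSITION") ~ "transposition",
    TRUE ~ NA_character_
  )
}

sv_alt_symbol <- function(sv_type) {
  c(deletion = "<DEL>", duplication = "<DUP>", inversion = "<INV>",
    transposition = "<TRA>")[sv_type]
}

#' Write variant records to a single-sample VCF
#'
#' @param variants A variant tibble for one sample.
#' @param path Output path.
#' @param sample_id Sample column name; defaults to the tibble's single
#'   `sample_id` value.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- unique(variants$sample_id)
    if (length(sample_id) > 1) {
      stop("variants contain multiple samples; supply sample_id", call. = FALSE)
    }
    if (length(sample_id) == 0) sample_id <- "sample"
  }
  v <- arrange(variants, .data$chrom, .data$pos, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=resevar",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of structural variant (1-based inclusive)\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads or read pairs\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    r <- v[i, ]
    info <- character(0)
    alt <- r$alt
    if (identical(r$type, "SV")) {
      svt <- toupper(substr(c(deletion = "DEL", duplication = "DUP",
                              inversion = "INV",
                              transposition = "TRA")[r$sv_type], 1, 3))
      info <- c(info, paste0("SVTYPE=", svt))
      if (!is.na(r$sv_end)) info <- c(info, paste0("END=", r$sv_end))
      alt <- sv_alt_symbol(r$sv_type)
    }
    if (!is.na(r$support)) info <- c(info, paste0("SUPPORT=", r$support))
    gt <- if (identical(r$zygosity, "het")) "0/1" else "1/1"
    body[i] <- paste(
      r$chrom, r$pos + 1L, ".", r$ref, alt,
      ifelse(is.na(r$qual), ".", format(r$qual, trim = TRUE)),
      "PASS", if (length(info)) paste(info, collapse = ";") else ".",
      "GT", gt, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a coverage mask from BED
#'
#' BED is 0-based half-open, matching the internal convention; overlapping
#' intervals are merged on load.
#'
#' @param path Path to a BED file (first three columns used).
#' @param sample_id Sample identifier to attach; defaults to the file name.
#' @return A coverage-mask tibble: `sample_id`, `chrom`, `start`, `end`.
#' @export
read_coverage_bed <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.bed$", "", basename(path))
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (any(as.integer(raw[[3]]) <= as.integer(raw[[2]]))) {
    stop("BED interval with end <= start in ", path, call. = FALSE)
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "bed"))
  mask <- tibble(
    sample_id = sample_id,
    chrom = as.character(gr$seqnames),
    start = as.integer(gr$start) - 1L,
    end = as.integer(gr$end)
  )
  merge_mask(mask)
}

#' Write a coverage mask to BED
#'
#' @param mask A single-sample coverage-mask tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(mask, path) {
  validate_mask(mask)
  m <- arrange(mask, .data$chrom, .data$start)
  writeLines(paste(m$chrom, m$start, m$end, sep = "\t"), path)
  invisible(path)
}

#' Write a phylogenetic tree to newick
#'
#' @param tree An [ape::ape-package] `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read a gene-to-term (GO/PFAM) mapping table
#'
#' @param path Path to a TSV with columns `gene_id`, `namespace`, `term`.
#' @return A tibble with those three columns.
#' @export
read_gene_term_map <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  stopifnot(all(c("gene_id", "namespace", "term") %in% names(out)))
  out
}

#' Read site-level read evidence ("pileup-lite")
#'
#' A TSV carrying, per covered site with evidence: the observed base calls
#' with phred+33 qualities, and InDel/SV support counts (gapped read pairs,
#' abnormal read pairs and their signature).
#'
#' @param path Path to a pileup-lite TSV.
#' @return A tibble with columns `chrom`, `pos` (0-based), `ref`, `bases`,
#'   `quals`, `gap_type`, `gap_seq`, `n_gapped_pairs`, `n_abnormal_pairs`,
#'   `abnormal_signature`.
#' @export
read_pileup <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", bases = "c", quals = "c",
    gap_type = "c", gap_seq = "c", n_gapped_pairs = "i",
    n_abnormal_pairs = "i", abnormal_signature = "c"
  ), na = ".")
}

#' Write site-level read evidence
#'
#' @param pileup Pileup tibble as returned by [read_pileup()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(pileup, path, na = ".")
  invisible(path)
}
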