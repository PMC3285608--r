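# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
SV_TYPES <- c("deletion", "duplication", "inversion", "transposition")
VARIANT_TYPES <- c("SNP", "INS", "DEL", "SV")

# Variant-type group used in windowed scans and report tables: insertions and
# deletions are pooled as "InDel".
variant_group <- function(type) {
  dplyr::case_when(
    type == "SNP" ~ "SNP",
    type %in% c("INS", "DEL") ~ "InDel",
    type == "SV" ~ "SV",
    TRUE ~ NA_character_
  )
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

translate_cds <- function(seq) {
  # Standard nuclear code; returns the amino-acid string including '*' stops.
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seq),
    genetic.code = Biostrings::GENETIC_CODE,
    no.init.codon = TRUE
  ))
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

genome_sequence <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in genome: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  genome$seq[i]
}

genome_base <- function(genome, chrom, pos) {
  # pos is 0-based
  seqs <- genome_sequence(genome, chrom)
  len <- genome$length[match(chrom, genome$chrom)]
  if (any(pos < 0 | pos >= len)) {
    stop("position beyond chromosome end", call. = FALSE)
  }
  substr(seqs, pos + 1, pos + 1)
}

# Coverage masks --------------------------------------------------------

empty_mask <- function() {
  tibble(sample_id = character(), chrom = character(),
         start = integer(), end = integer())
}

validate_mask <- function(mask) {
  stopifnot(all(c("sample_id", "chrom", "start", "end") %in% names(mask)))
  if (any(mask$end <= mask$start)) {
    stop("coverage mask has interval with end <= start", call. = FALSE)
  }
  invisible(mask)
}

# Merge overlapping/adjacent intervals within sample x chrom.
merge_mask <- function(mask) {
  validate_mask(mask)
  mask |>
    group_by(.data$sample_id, .data$chrom) |>
    dplyr::group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    ungroup() |>
    arrange(.data$sample_id, .data$chrom, .data$start)
}

covered_bases <- function(mask) {
  mask |>
    group_by(.data$sample_id, .data$chrom) |>
    summarise(covered = sum(.data$end - .data$start), .groups = "drop")
}

# TRUE for each (chrom, pos) covered in the given single-sample mask rows.
positions_covered <- function(chrom, pos, mask_one) {
  if (length(chrom) == 0) return(logical(0))
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- mask_one[mask_one$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0) { out[idx] <- FALSE; next }
    ir <- IRanges::IRanges(m$start + 1L, m$end)
    q <- IRanges::IRanges(pos[idx] + 1L, pos[idx] + 1L)
    out[idx] <- IRanges::overlapsAny(q, ir)
  }
  out
}

# Intersection length of [start, end) with a single-sample mask, per query.
covered_in_window <- function(start, end, chrom, mask_one) {
  out <- integer(length(start))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- mask_one[mask_one$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0) { out[idx] <- 0L; next }
    ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
    for (j in idx) {
      q <- IRanges::IRanges(start[j] + 1L, end[j])
      out[j] <- sum(IRanges::width(IRanges::pintersect(
        IRanges::findOverlapPairs(q, ir))))
    }
  }
  out
}

# Variant records -------------------------------------------------------

empty_variants <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), type = character(),
    zygosity = character(), qual = double(), support = integer(),
    sv_type = character(), sv_end = integer()
  )
}

as_variant_tbl <- function(df) {
  proto <- empty_variants()
  for (nm in names(proto)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- vctrs::vec_init(proto[[nm]], nrow(df))
    }
  }
  df |>
    mutate(
      pos = as.integer(.data$pos),
      qual = as.double(.data$qual),
      support = as.integer(.data$support),
      sv_end = as.integer(.data$sv_end)
    ) |>
    select(dplyr::all_of(names(empty_variants()))) |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$alt)
}

# Classify type from REF/ALT strings (non-symbolic).
variant_type_from_alleles <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 ~ "SNP",
    nchar(alt) > nchar(ref) ~ "INS",
    nchar(alt) < nchar(ref) ~ "DEL",
    TRUE ~ "MNP"
  )
}

seed_stream <- function(seed, offset) {
  # derived per-stage seeds; keep within 32-bit integer range
  (as.integer(seed) * 101L + as.integer(offset) * 7919L) %% 2147483587L
}
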