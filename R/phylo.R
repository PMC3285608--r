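# SNP p-distances (samples + reference as taxa) and a neighbor-joining
# tree with deterministic tie-breaking.

pair_mismatch <- function(g1, g2) {
  # g1, g2: length-2 allele vectors (hom = same base twice)
  m <- sum(sort(g1) == sort(g2))
  if (m == 2) return(0)
  # optimal pairing: count shared alleles as multisets
  shared <- sum(pmin(table(factor(g1, DNA_BASES)),
                     table(factor(g2, DNA_BASES))))
  1 - shared / 2
}

#' SNP distance matrix across samples (and the reference)
#'
#' Pairwise p-distance: the mean per-locus allele mismatch over eligible
#' SNP loci (positions covered in every sample). The reference genome
#' enters as a taxon carrying the reference allele everywhere. A
#' heterozygous call half-matches a homozygote sharing one allele
#' (contributing 0.5). `correction = "JC"` applies the Jukes-Cantor
#' transform.
#'
#' @param variants SNP-bearing variant tibble.
#' @param masks Coverage-mask tibble.
#' @param samples Samples to include; default all.
#' @param include_reference Add the reference as a taxon (default TRUE).
#' @param reference_name Taxon name for the reference.
#' @param correction `"none"` (p-distance) or `"JC"`.
#' @return A symmetric numeric matrix with taxa as dimnames; attribute
#'   `n_loci` carries the number of eligible loci. Triangle-inequality
#'   violations (possible after correction) are flagged via attribute
#'   `triangle_ok`.
#' @export
snp_distance_matrix <- function(variants, masks, samples = NULL,
                                include_reference = TRUE,
                                reference_name = "reference",
                                correction = c("none", "JC")) {
  correction <- match.arg(correction)
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  snps <- variants |> filter(.data$type == "SNP",
                             .data$sample_id %in% samples)
  el <- eligible_loci(snps, masks, samples)
  loci <- el |> filter(.data$eligible)
  if (!nrow(loci)) stop("zero eligible SNP loci", call. = FALSE)
  snps$locus <- locus_ids(snps)
  snps <- snps |> filter(.data$locus %in% loci$locus)
  taxa <- c(samples, if (include_reference) reference_name)
  # per-locus reference base and per-taxon allele pairs
  ref_of <- snps |> distinct(.data$locus, .keep_all = TRUE) |>
    mutate(refb = substr(.data$ref, 1, 1)) |>
    select(dplyr::all_of(c("locus", "refb")))
  tab <- loci |> left_join(ref_of, by = "locus")
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  genotype_of <- function(sample, tab_loci) {
    v <- snps |> filter(.data$sample_id == sample)
    i <- match(tab_loci$locus, v$locus)
    alt <- v$alt[i]; zyg <- v$zygosity[i]
    a1 <- if_else(is.na(alt), tab_loci$refb,
                  if_else(zyg == "het", tab_loci$refb, alt))
    a2 <- if_else(is.na(alt), tab_loci$refb, alt)
    cbind(a1, a2)
  }
  gmat <- lapply(setNames(samples, samples), genotype_of, tab_loci = tab)
  if (include_reference) {
    gmat[[reference_name]] <- cbind(tab$refb, tab$refb)
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      gi <- gmat[[taxa[i]]]; gj <- gmat[[taxa[j]]]
      mm <- vapply(seq_len(nrow(tab)), function(k) {
        pair_mismatch(gi[k, ], gj[k, ])
      }, double(1))
      p <- mean(mm)
      if (correction == "JC") {
        if (p >= 0.75) stop("p-distance too large for JC correction",
                            call. = FALSE)
        p <- -3 / 4 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  tri_ok <- TRUE
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (d[i, j] > d[i, k] + d[k, j] + 1e-12) tri_ok <- FALSE
  }
  if (!tri_ok) message("triangle inequality violated in distance matrix")
  attr(d, "n_loci") <- nrow(tab)
  attr(d, "triangle_ok") <- tri_ok
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a symmetric distance matrix with a
#' deterministic tie-break (among minimal Q entries, the pair whose sorted
#' taxon labels are lexicographically smallest is joined; each internal
#' node is labeled by the smallest original taxon beneath it). Negative
#' branch lengths are clamped to zero and flagged via the
#' `negative_branches` attribute.
#'
#' @param d Symmetric distance matrix with dimnames, zero diagonal.
#' @return An unrooted `ape` `phylo` object.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-9)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(d)))
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  D <- unname(d)
  nodes <- as.list(taxa)          # newick fragment per active node
  labels <- taxa                  # tie-break label per active node
  n_neg <- 0L
  fmt <- function(x) formatC(max(x, 0), digits = 12, format = "g")
  while (length(labels) > 3) {
    m <- length(labels)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      paste(sort(c(labels[ij[1]], labels[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0 || lj < 0) n_neg <- n_neg + 1L
    new_frag <- paste0("(", nodes[[i]], ":", fmt(li), ",",
                       nodes[[j]], ":", fmt(lj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    D <- D2
    nodes <- c(nodes[keep], new_frag)
    labels <- c(labels[keep], min(labels[c(i, j)]))
  }
  # final trifurcation via the three-point formulas
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", nodes[[1]], ":", fmt(a), ",",
                   nodes[[2]], ":", fmt(b), ",",
                   nodes[[3]], ":", fmt(c3), ");")
  if (any(c(a, b, c3) < 0)) n_neg <- n_neg + 1L
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_branches") <- n_neg
  tree
}

#' Build the SNP tree for a set of samples
#'
#' Convenience wrapper: distance matrix + neighbor joining.
#'
#' @inheritParams snp_distance_matrix
#' @return An `ape` `phylo` object with the distance matrix attached as
#'   attribute `distance`.
#' @export
snp_tree <- function(variants, masks, samples = NULL,
                     include_reference = TRUE,
                     correction = c("none", "JC")) {
  d <- snp_distance_matrix(variants, masks, samples = samples,
                           include_reference = include_reference,
                           correction = correction)
  tree <- neighbor_joining(d)
  attr(tree, "distance") <- d
  tree
}
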