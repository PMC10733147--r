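# Variant filters, the genotype matrix container, and interval intersection.

#' Filter variants on quality, read support and size
#'
#' Retains records with `qual >= min_qual`, supporting-read fraction at or
#' above the type-specific threshold (deletions 20%, insertions 5%), and
#' `svlen >= min_svlen`. Records with missing support fractions fail the
#' support test. Filtering is idempotent.
#'
#' @param x A variants tibble (columns `svtype`, `svlen`, `qual`,
#'   `support_fraction`) or an `sv_callset` (its genotype matrix is subset
#'   alongside the variants).
#' @param min_qual Minimum QUAL retained (default 5).
#' @param min_del_support Minimum supporting-read fraction for deletions
#'   (default 0.20; a deletion supported by exactly 20% of reads is kept).
#' @param min_ins_support Minimum supporting-read fraction for insertions
#'   (default 0.05).
#' @param min_svlen Minimum variant length in bp (default 20).
#' @return Object of the same type as `x`, restricted to retained records.
#' @export
filter_variants <- function(x, min_qual = 5, min_del_support = 0.20,
                            min_ins_support = 0.05, min_svlen = 20) {
  UseMethod("filter_variants")
}

#' @export
filter_variants.data.frame <- function(x, min_qual = 5, min_del_support = 0.20,
                                       min_ins_support = 0.05, min_svlen = 20) {
  stopifnot_cols(x, c("svtype", "svlen", "qual", "support_fraction"))
  keep <- filter_keep(x, min_qual, min_del_support, min_ins_support, min_svlen)
  x[keep, , drop = FALSE]
}

#' @export
filter_variants.sv_callset <- function(x, min_qual = 5, min_del_support = 0.20,
                                       min_ins_support = 0.05, min_svlen = 20) {
  keep <- filter_keep(x$variants, min_qual, min_del_support, min_ins_support,
                      min_svlen)
  new_sv_callset(x$variants[keep, , drop = FALSE], x$samples,
                 x$gt[keep, , drop = FALSE])
}

filter_keep <- function(v, min_qual, min_del_support, min_ins_support,
                        min_svlen) {
  support_ok <- !is.na(v$support_fraction) &
    if_else(v$svtype == "DEL",
            v$support_fraction >= min_del_support,
            v$support_fraction >= min_ins_support)
  ok <- !is.na(v$qual) & v$qual >= min_qual & support_ok &
    v$svlen >= min_svlen
  ok & !is.na(ok)
}

#' Size class of a variant
#'
#' Large indels span 20-49 bp; structural variants are 50 bp and above.
#'
#' @param svlen Integer vector of variant lengths.
#' @return Character vector, `"large_indel"` or `"SV"` (`NA` below 20 bp).
#' @export
size_class <- function(svlen) {
  dplyr::case_when(svlen >= 50 ~ "SV",
                   svlen >= 20 ~ "large_indel",
                   TRUE ~ NA_character_)
}

new_sv_genotypes <- function(dosage, samples) {
  presence <- (dosage >= 1L)
  presence[is.na(presence)] <- FALSE  # missing counts as absence
  storage.mode(presence) <- "integer"
  structure(list(variant_ids = rownames(dosage), samples = samples,
                 presence = presence, dosage = dosage),
            class = "sv_genotypes")
}

#' Build a binary presence / dosage matrix from genotypes
#'
#' Converts per-sample genotype strings into a variants x samples matrix.
#' Presence is 1 for genotypes `0/1` and `1/1` and 0 for `0/0`; missing
#' genotypes (`./.`) count as absence in the presence matrix but are kept as
#' `NA` in the dosage matrix so allele-count statistics (e.g. FST) can
#' exclude them.
#'
#' @param x An `sv_callset` (or a character genotype matrix with variant ids
#'   as rownames).
#' @param samples Sample metadata tibble; taken from the callset when `x` is
#'   an `sv_callset`.
#' @return An `sv_genotypes` object: `variant_ids`, `samples`, integer
#'   `presence` and `dosage` (0/1/2/`NA`) matrices.
#' @export
build_genotype_matrix <- function(x, samples = NULL) {
  if (inherits(x, "sv_callset")) {
    gt <- x$gt
    samples <- x$samples
  } else {
    gt <- x
  }
  if (anyDuplicated(rownames(gt))) abort("duplicate variant ids")
  alleles1 <- substr(gt, 1, 1)
  alleles2 <- substr(gt, 3, 3)
  dos <- (alleles1 == "1") + (alleles2 == "1")
  dos[alleles1 == "." | alleles2 == "."] <- NA_integer_
  dosage <- matrix(as.integer(dos), nrow = nrow(gt),
                   dimnames = dimnames(gt))
  new_sv_genotypes(dosage, samples)
}

#' @export
print.sv_genotypes <- function(x, ...) {
  cat(sprintf("<sv_genotypes> %d variants x %d samples (%d missing calls)\n",
              nrow(x$presence), ncol(x$presence), sum(is.na(x$dosage))))
  invisible(x)
}

#' @export
tidy.sv_genotypes <- function(x, ...) {
  long <- tibble(
    variant_id = rep(x$variant_ids, times = ncol(x$presence)),
    sample_id = rep(colnames(x$presence), each = nrow(x$presence)),
    presence = as.vector(x$presence),
    dosage = as.vector(x$dosage)
  )
  left_join(long, x$samples, by = "sample_id")
}

# subset an sv_genotypes by variant ids (or logical/integer index)
subset_genotypes <- function(geno, i) {
  dosage <- geno$dosage[i, , drop = FALSE]
  new_sv_genotypes(dosage, geno$samples)
}

#' Intersect variants with genomic intervals
#'
#' Deletions intersect via their deleted reference interval; insertions via
#' their single-base anchor point. Coordinates are 0-based half-open
#' throughout.
#'
#' @param variants Variants tibble with `variant_id`, `chrom`, `start`,
#'   `end`, `svtype` columns.
#' @param intervals Tibble of intervals (`chrom`, `start`, `end`; additional
#'   columns are carried through).
#' @return A tibble of hits: one row per (variant, interval) overlap with
#'   `variant_id`, `overlap_bp` and all interval columns. Variants on
#'   chromosomes absent from `intervals` simply produce no rows.
#' @export
intersect_variants <- function(variants, intervals) {
  stopifnot_cols(variants, c("variant_id", "chrom", "start", "end"))
  stopifnot_cols(intervals, c("chrom", "start", "end"))
  if (nrow(variants) == 0 || nrow(intervals) == 0) {
    return(tibble(variant_id = character(0), overlap_bp = integer(0)))
  }
  res <- vector("list", length(unique(variants$chrom)))
  chroms <- unique(variants$chrom)
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    v <- variants[variants$chrom == ch, , drop = FALSE]
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    q <- IRanges::IRanges(start = v$start + 1L, end = pmax(v$end, v$start + 1L))
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    inter <- IRanges::pintersect(q[qh], s[sh])
    hit <- iv[sh, , drop = FALSE]
    hit$variant_id <- v$variant_id[qh]
    hit$overlap_bp <- IRanges::width(inter)
    res[[k]] <- hit
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(variant_id = character(0), overlap_bp = integer(0)))
  }
  select(out, "variant_id", "overlap_bp", dplyr::everything())
}
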