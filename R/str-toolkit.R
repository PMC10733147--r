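# STR analyses: canonical motifs, expansion criteria, frequency tables.

#' Canonical (redundancy-collapsed) STR motif
#'
#' All rotations of a motif on both strands describe the same repeat array
#' (e.g. CAG, AGC, GCA, TGC, GCT and CTG form a single redundant triplet).
#' The canonical representative is the lexicographic minimum over all
#' rotations of the motif and of its reverse complement.
#'
#' @param motif Character vector of motifs over A/C/G/T (length 2-12).
#' @return Character vector of canonical motifs.
#' @export
#' @examples
#' canonical_motif("CAG")  # "AGC"
canonical_motif <- function(motif) {
  if (any(grepl("[^ACGT]", motif))) abort("motif must be over A/C/G/T")
  vapply(motif, function(m) min(motif_members(m)), character(1),
         USE.NAMES = FALSE)
}

#' @rdname canonical_motif
#' @return `motif_members()`: the full member set (all rotations, both
#'   strands) of one motif.
#' @export
motif_members <- function(motif) {
  stopifnot(length(motif) == 1)
  rot <- function(m) {
    n <- nchar(m)
    unique(substring(strrep(m, 2), 1:n, n:(2 * n - 1)))
  }
  unique(c(rot(motif), rot(revcomp(motif))))
}

#' Significant STR expansion criteria
#'
#' An expansion at an STR site is significant when all four criteria hold:
#' period >= 3 bp; expanded by at least 10 repeat units; expanded by at
#' least 50% of the reference element size; and reference element size
#' under 1 kb.
#'
#' @param period Repeat period in bp (vector; must be >= 2).
#' @param reference_length Reference STR element length in bp.
#' @param expansion_bp Total expansion size in bp.
#' @param min_period,min_units,min_frac,max_ref_bp The four thresholds.
#' @return Logical vector.
#' @export
is_significant_expansion <- function(period, reference_length, expansion_bp,
                                     min_period = 3L, min_units = 10,
                                     min_frac = 0.5, max_ref_bp = 1000L) {
  if (any(period < 2)) abort("period must be >= 2 for STR analyses")
  period >= min_period &
    expansion_bp / period >= min_units &
    expansion_bp >= min_frac * reference_length &
    reference_length < max_ref_bp
}

#' Reference STR element length at a variant site
#'
#' Scans the reference sequence around an STR variant for the local tandem
#' array with the variant's period and reports its length (bp). Used to
#' apply the significant-expansion criteria to classified STR insertions.
#'
#' @param variant One-row variants tibble (`chrom`, `pos`).
#' @param reference Named character vector of chromosome sequences or an
#'   `sv_reference`.
#' @param period Expected period (from classification).
#' @param window Search window around the site in bp (default 1200).
#' @return Reference element length in bp (0 when no array found).
#' @export
str_reference_length <- function(variant, reference, period,
                                 window = 1200L) {
  if (inherits(reference, "sv_reference")) reference <- reference$sequences
  chrom_seq <- reference[[variant$chrom]]
  L <- nchar(chrom_seq)
  ws <- max(0L, variant$pos - window)
  we <- min(L, variant$pos + window)
  local <- substr(chrom_seq, ws + 1L, we)
  ann <- find_tandem_repeats(local, max_period = min(500L, 3L * period))
  ann <- ann[ann$period == period, , drop = FALSE]
  if (nrow(ann) == 0) return(0L)
  # array overlapping (or nearest to) the variant position
  p0 <- variant$pos - ws
  dist <- pmax(0, pmax(ann$start - p0, p0 - ann$end))
  best <- which.min(dist)
  as.integer(ann$end[best] - ann$start[best])
}

#' Period and motif frequency tables for STR variants
#'
#' Summarizes classified STR expansions/contractions: counts per period,
#' the relative frequency of each period among CDS variants, the genomic
#' context composition per period, and counts per canonical motif.
#'
#' @param str_variants Tibble with `variant_id`, `svtype`, `period`,
#'   `motif` and (optionally) `region_class` (from [partition_hits()]).
#' @return A list of tibbles: `period_counts` (`period`, `n`, `n_cds`,
#'   `cds_rel_freq`), `period_context` (proportions of
#'   CDS/NONCDS/INTERGENIC per period), `motif_counts` (`period`,
#'   `canonical`, `n`).
#' @export
motif_and_period_tables <- function(str_variants) {
  v <- str_variants
  has_ctx <- "region_class" %in% names(v)
  if (!has_ctx) v$region_class <- NA_character_
  period_counts <- v |> count(.data$period, name = "n") |>
    left_join(v |> filter(.data$region_class == "CDS") |>
                count(.data$period, name = "n_cds"),
              by = "period") |>
    mutate(n_cds = dplyr::coalesce(.data$n_cds, 0L),
           cds_rel_freq = if (sum(.data$n_cds) > 0) {
             .data$n_cds / sum(.data$n_cds)
           } else NA_real_)
  period_context <- v |>
    count(.data$period, .data$region_class, name = "n") |>
    group_by(.data$period) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup()
  motif_counts <- v |>
    filter(!is.na(.data$motif)) |>
    mutate(canonical = canonical_motif(.data$motif)) |>
    count(.data$period, .data$canonical, name = "n") |>
    arrange(.data$period, desc(.data$n))
  list(period_counts = period_counts, period_context = period_context,
       motif_counts = motif_counts)
}
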