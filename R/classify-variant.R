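# Extended local alleles and the repeat-classification decision rule.

#' Build the extended local allele for a variant
#'
#' The extended allele embeds the variant in reference flanks of twice the
#' variant size on each side, giving a sequence five times the variant size
#' whose central 20% is the variant region. For an insertion the allele is
#' left flank + consensus insertion + right flank; for a deletion it is the
#' contiguous reference slice covering the deleted interval plus both
#' flanks. Flanks are clipped (and flagged) at contig edges.
#'
#' @param variant One-row list/tibble with `chrom`, `start`, `svtype`,
#'   `svlen` and, for insertions, `seq`.
#' @param reference Named character vector of chromosome sequences (or an
#'   `sv_reference`).
#' @return A list: `sequence`, `variant_start`/`variant_end` (0-based
#'   half-open indices of the variant region within `sequence`), `clipped`.
#' @export
build_extended_allele <- function(variant, reference) {
  if (inherits(reference, "sv_reference")) reference <- reference$sequences
  chrom_seq <- reference[[variant$chrom]]
  if (is.null(chrom_seq) || is.na(chrom_seq)) {
    abort(sprintf("chromosome %s not in reference", variant$chrom))
  }
  L <- nchar(chrom_seq)
  svlen <- variant$svlen
  flank <- 2L * svlen
  s0 <- variant$start
  left_len <- min(flank, s0)
  if (variant$svtype == "INS") {
    right_len <- min(flank, L - s0)
    left <- substr(chrom_seq, s0 - left_len + 1L, s0)
    right <- substr(chrom_seq, s0 + 1L, s0 + right_len)
    seq <- paste0(left, variant$seq, right)
  } else {
    right_len <- min(flank, L - (s0 + svlen))
    seq <- substr(chrom_seq, s0 - left_len + 1L, s0 + svlen + right_len)
  }
  list(sequence = seq,
       variant_start = left_len,
       variant_end = left_len + svlen,
       clipped = left_len < flank || right_len < flank)
}

TANDEM_LABELS <- c("HOMO", "STR", "TR")
FAMILY_LABELS <- c(SINE = "SINE", LINE = "LINE", DNA = "DNA", LTR = "LTR",
                   Retroposon = "RETROPOSON", Other = "OTHER_ME")

#' Classify one variant from its annotations
#'
#' Applies the coverage rule: the variant region (central 20% of the
#' extended allele) must be covered at >= `min_coverage` by annotations of
#' a single type. Tandem classes are evaluated first (ties between tandem
#' classes resolve toward the larger period class, since a p-periodic array
#' is also np-periodic); otherwise mobile-element families are evaluated,
#' with the completeness call made per the fraction-of-whole-element rule;
#' otherwise the variant is non-repetitive (`NONREP`).
#'
#' @param allele Extended allele from [build_extended_allele()].
#' @param tandem Tandem annotations from [find_tandem_repeats()] on
#'   `allele$sequence`.
#' @param elements Element hits from [find_mobile_elements()] on the same
#'   sequence.
#' @param min_coverage Coverage threshold for classification (default 0.75).
#' @param complete_threshold Fraction of a whole canonical element the
#'   variant must contain to be a `complete` transposition (default 0.75).
#' @return One-row tibble: `label`, `me_completeness` (`complete`,
#'   `fragment` or `n/a`), `coverage`, `period`, `motif`, `element_name`.
#' @export
classify_variant <- function(allele, tandem, elements, min_coverage = 0.75,
                             complete_threshold = 0.75) {
  vs <- allele$variant_start
  ve <- allele$variant_end
  res <- function(label, completeness = "n/a", coverage = 0,
                  period = NA_integer_, motif = NA_character_,
                  element_name = NA_character_) {
    tibble(label = label, me_completeness = completeness,
           coverage = coverage, period = period, motif = motif,
           element_name = element_name)
  }

  if (nrow(tandem) > 0) {
    tandem$class <- classify_period(tandem$period)
    cov <- vapply(TANDEM_LABELS, function(cl) {
      a <- tandem[tandem$class == cl, , drop = FALSE]
      if (nrow(a) == 0) 0 else coverage_fraction(vs, ve, a$start, a$end)
    }, numeric(1))
    if (any(cov >= min_coverage)) {
      # ties toward larger period class: HOMO < STR < TR
      winner <- TANDEM_LABELS[max(which(cov == max(cov)))]
      a <- tandem[tandem$class == winner, , drop = FALSE]
      ov <- map_dbl(seq_len(nrow(a)),
                    function(i) overlap_bp(vs, ve, a$start[i], a$end[i]))
      best <- which.max(ov)
      return(res(winner, "n/a", unname(cov[winner]),
                 period = a$period[best], motif = a$motif[best]))
    }
  }

  if (nrow(elements) > 0) {
    fams <- unique(elements$family)
    cov <- vapply(fams, function(f) {
      h <- elements[elements$family == f, , drop = FALSE]
      coverage_fraction(vs, ve, h$start, h$end)
    }, numeric(1))
    if (any(cov >= min_coverage)) {
      fam <- fams[which.max(cov)]
      h <- elements[elements$family == fam, , drop = FALSE]
      # complete transposition: the variant contains >= 75% of at least one
      # whole canonical element
      in_variant <- map_dbl(seq_len(nrow(h)), function(i) {
        overlap_bp(vs, ve, h$start[i], h$end[i]) / h$consensus_length[i]
      })
      completeness <- if (any(in_variant >= complete_threshold)) {
        "complete"
      } else "fragment"
      best <- which.max(in_variant)
      lab <- FAMILY_LABELS[[fam]] %||% "OTHER_ME"
      return(res(lab, completeness, unname(cov[which.max(cov)]),
                 element_name = h$element_name[best]))
    }
  }

  max_cov <- 0
  if (nrow(tandem) > 0) {
    max_cov <- max(max_cov, coverage_fraction(vs, ve, tandem$start,
                                              tandem$end))
  }
  res("NONREP", "n/a", max_cov)
}

#' Classify every variant in a callset by repeat context
#'
#' Drives the full algorithm: extended-allele construction, tandem and
#' mobile-element scanning, and the coverage decision rule, for each
#' variant.
#'
#' @param variants Variants tibble (`variant_id`, `chrom`, `start`,
#'   `svtype`, `svlen`, `seq`).
#' @param reference Named character vector of chromosome sequences or an
#'   `sv_reference`.
#' @param library Repeat library for the element matcher.
#' @param min_coverage,complete_threshold See [classify_variant()].
#' @param max_period Largest tandem period scanned.
#' @param tandem_annotations,element_annotations Optional externally parsed
#'   annotations (from [parse_trf_dat()] / [parse_repeatmasker_out()]),
#'   keyed by `variant_id`; when supplied they replace the built-in
#'   detectors for those variants.
#' @return A tibble: `variant_id`, `label`, `me_completeness`, `coverage`,
#'   `period`, `motif`, `element_name`, `clipped`.
#' @export
classify_variants <- function(variants, reference,
                              library = default_repeat_library(),
                              min_coverage = 0.75,
                              complete_threshold = 0.75, max_period = 500L,
                              tandem_annotations = NULL,
                              element_annotations = NULL) {
  if (inherits(reference, "sv_reference")) reference <- reference$sequences
  rows <- map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    allele <- build_extended_allele(v, reference)
    tandem <- if (!is.null(tandem_annotations)) {
      filter(tandem_annotations, .data$variant_id == v$variant_id)
    } else {
      find_tandem_repeats(allele$sequence, max_period = max_period)
    }
    hits <- if (!is.null(element_annotations)) {
      filter(element_annotations, .data$variant_id == v$variant_id)
    } else {
      find_mobile_elements(allele$sequence, library)
    }
    cls <- classify_variant(allele, tandem, hits,
                            min_coverage = min_coverage,
                            complete_threshold = complete_threshold)
    mutate(cls, variant_id = v$variant_id, clipped = allele$clipped)
  })
  select(bind_rows(rows), "variant_id", dplyr::everything())
}

#' Flag homopolymeric variants for exclusion
#'
#' Homopolymer indels are enriched for sequencing artefacts and are
#' excluded from downstream analyses by default.
#'
#' @param classified Classification tibble from [classify_variants()].
#' @param exclude When `TRUE` (default) mark `HOMO` variants as excluded.
#' @return The tibble with an added logical `excluded` column.
#' @export
flag_homopolymers <- function(classified, exclude = TRUE) {
  mutate(classified, excluded = exclude & .data$label == "HOMO")
}
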