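# Built-in repeat detectors: tandem-array scanner and mobile-element matcher.
#
# These replace external annotation binaries with simplified, deterministic
# detectors: substitution-tolerant (>= 80% identity) but not indel-tolerant.
# Adapters for the external tools' native output formats are in
# classify-adapters.R.

#' Scan a sequence for tandem repeats
#'
#' For every candidate period `p` (1 to `max_period`) positions matching
#' their `p`-lag neighbour are found and merged into maximal arrays whose
#' purity (fraction of matching positions) stays at or above `min_purity`
#' and whose score (`match_weight * matches - mismatch_penalty * mismatches`)
#' reaches `min_score`. A `p`-periodic array is trivially also
#' `np`-periodic, so calls that are >= 80% covered by a smaller-period call
#' are suppressed and each region is reported at its smallest qualifying
#' period. Scoring parameters default to the classic tandem-repeat-finder
#' recommendation (2, 7, 80%, score 50, periods to 500).
#'
#' @param sequence A single DNA string (A/C/G/T; other characters never
#'   match).
#' @param max_period Largest period scanned.
#' @param min_score Minimum array score.
#' @param min_purity Minimum fraction of matching positions.
#' @param match_weight,mismatch_penalty Scoring weights.
#' @return A tibble of arrays: `start`, `end` (0-based half-open within
#'   `sequence`), `period`, `motif` (modal unit), `copy_number`, `purity`,
#'   `score`.
#' @export
find_tandem_repeats <- function(sequence, max_period = 500L, min_score = 50,
                                min_purity = 0.8, match_weight = 2,
                                mismatch_penalty = 7) {
  empty <- tibble(start = integer(0), end = integer(0), period = integer(0),
                  motif = character(0), copy_number = numeric(0),
                  purity = numeric(0), score = numeric(0))
  if (is.na(sequence) || nchar(sequence) == 0) return(empty)
  codes <- encode_dna(sequence)
  raw <- tandem_scan_cpp(codes, as.integer(max_period), match_weight,
                         mismatch_penalty, min_score, min_purity)
  if (nrow(raw) == 0) return(empty)
  raw <- raw[order(raw$period, -raw$score), , drop = FALSE]

  # harmonic suppression: drop a call mostly covered by smaller-period calls
  kept <- logical(nrow(raw))
  covered <- logical(nchar(sequence))
  for (i in seq_len(nrow(raw))) {
    span <- (raw$start[i] + 1L):raw$end[i]
    if (mean(covered[span]) < 0.8) {
      kept[i] <- TRUE
      covered[span] <- TRUE
    }
  }
  out <- raw[kept, , drop = FALSE]

  motif_of <- function(start, end, p) {
    k <- (end - start) %/% p
    units <- substring(sequence, start + 1L + (seq_len(k) - 1L) * p,
                       start + seq_len(k) * p)
    names(sort(table(units), decreasing = TRUE))[1]
  }
  tibble(
    start = out$start, end = out$end, period = out$period,
    motif = map_chr(seq_len(nrow(out)),
                    function(i) motif_of(out$start[i], out$end[i],
                                         out$period[i])),
    copy_number = (out$end - out$start) / out$period,
    purity = out$matches / out$span,
    score = out$score
  )
}

#' Classify a tandem-repeat period
#'
#' Period 1 is a homopolymer (`HOMO`), periods 2-12 are short tandem
#' repeats (`STR`) and periods above 12 are tandem repeats (`TR`).
#'
#' @param period Integer vector of periods (all >= 1).
#' @return Character vector of class labels.
#' @export
classify_period <- function(period) {
  if (any(is.na(period)) || any(period < 1)) abort("period must be >= 1")
  dplyr::case_when(period == 1 ~ "HOMO",
                   period <= 12 ~ "STR",
                   TRUE ~ "TR")
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

#' Scan a sequence for interspersed mobile elements
#'
#' Exact `k`-mer seeds shared with a library consensus (both orientations)
#' are chained along a common alignment diagonal when coverage gaps do not
#' exceed `max_gap` bp; a chain is reported as a hit when its ungapped
#' identity is at least `min_identity`. The matcher tolerates substitutions
#' but not indels.
#'
#' @param sequence A single DNA string.
#' @param library A repeat library (see [default_repeat_library()]); only
#'   `library$elements` is used.
#' @param k Seed length.
#' @param max_gap Maximum unseeded gap chained across, in bp.
#' @param min_identity Minimum ungapped identity of a reported chain.
#' @return A tibble of hits: `start`, `end` (0-based half-open in
#'   `sequence`), `element_name`, `family`, `orientation` (`+`/`-`),
#'   `identity`, `consensus_fraction` (covered consensus bp / consensus
#'   length) and `consensus_length`.
#' @export
find_mobile_elements <- function(sequence, library, k = 15L, max_gap = 50L,
                                 min_identity = 0.8) {
  empty <- tibble(start = integer(0), end = integer(0),
                  element_name = character(0), family = character(0),
                  orientation = character(0), identity = numeric(0),
                  consensus_fraction = numeric(0),
                  consensus_length = integer(0))
  if (is.na(sequence) || nchar(sequence) < k) return(empty)
  if (nrow(library$elements) == 0) abort("empty consensus library")
  qk <- kmer_set(sequence, k)
  qchars <- strsplit(sequence, "", fixed = TRUE)[[1]]

  hits <- list()
  for (e in seq_len(nrow(library$elements))) {
    cons_fwd <- library$elements$consensus[e]
    L <- nchar(cons_fwd)
    for (ori in c("+", "-")) {
      cons <- if (ori == "+") cons_fwd else revcomp(cons_fwd)
      ck <- kmer_set(cons, k)
      m <- match(qk, ck)
      qpos <- which(!is.na(m))
      if (length(qpos) == 0) next
      cpos <- m[qpos]
      diag <- qpos - cpos
      cchars <- strsplit(cons, "", fixed = TRUE)[[1]]
      for (d in unique(diag)) {
        qs <- sort(qpos[diag == d])
        brk <- c(0L, which(diff(qs) > max_gap + k), length(qs))
        for (b in seq_len(length(brk) - 1L)) {
          chain <- qs[(brk[b] + 1L):brk[b + 1L]]
          q1 <- chain[1]; q2 <- chain[length(chain)] + k - 1L
          c1 <- q1 - d; c2 <- q2 - d
          ident <- mean(qchars[q1:q2] == cchars[c1:c2])
          if (ident >= min_identity) {
            hits[[length(hits) + 1L]] <- tibble(
              start = q1 - 1L, end = q2,
              element_name = library$elements$name[e],
              family = library$elements$family[e],
              orientation = ori, identity = ident,
              consensus_fraction = (c2 - c1 + 1L) / L,
              consensus_length = L)
          }
        }
      }
    }
  }
  if (length(hits) == 0) return(empty)
  bind_rows(hits)
}

#' Fraction of a variant region covered by annotations
#'
#' The union of the annotation intervals is intersected with the variant
#' region; the result is the covered fraction in `[0, 1]`.
#'
#' @param variant_start,variant_end Variant region within the allele
#'   (0-based half-open); must be non-empty.
#' @param ann_start,ann_end Annotation intervals (vectors, 0-based
#'   half-open).
#' @return A number in `[0, 1]`.
#' @export
coverage_fraction <- function(variant_start, variant_end, ann_start,
                              ann_end) {
  if (variant_end <= variant_start) abort("zero-length variant region")
  overlap_bp(variant_start, variant_end, ann_start, ann_end) /
    (variant_end - variant_start)
}
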