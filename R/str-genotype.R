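# Diploid STR genotyping from haplotype-resolved local variants, and
# cross-community variability statistics.

# apply phased variants to a reference window [ws, we) (0-based half-open);
# insertions sit at 0-based boundaries, deletions remove [pos, pos+svlen)
apply_haplotype <- function(chrom_seq, ws, we, variants) {
  if (is.null(variants) || nrow(variants) == 0) {
    return(substr(chrom_seq, ws + 1L, we))
  }
  v <- arrange(variants, .data$pos)
  # conflict check: effective intervals must not overlap within a haplotype
  s <- v$pos
  e <- if_else(v$svtype == "DEL", v$pos + v$svlen, v$pos)
  if (nrow(v) > 1 && any(s[-1] < e[-nrow(v)] |
                         (s[-1] == s[-nrow(v)]))) {
    abort("conflicting variants at the same position within one haplotype")
  }
  out <- character(0)
  cur <- ws
  for (i in seq_len(nrow(v))) {
    if (v$pos[i] < ws || v$pos[i] >= we) next
    out <- c(out, substr(chrom_seq, cur + 1L, v$pos[i]))
    if (v$svtype[i] == "INS") {
      out <- c(out, v$seq[i])
      cur <- v$pos[i]
    } else {
      cur <- min(v$pos[i] + v$svlen[i], we)
    }
  }
  out <- c(out, substr(chrom_seq, cur + 1L, we))
  paste(out, collapse = "")
}

#' Genotype an STR site from phased local variants
#'
#' Applies each haplotype's variants to the local reference, extracts the
#' site padded by `flank` bp each side, measures the two allele lengths and
#' determines period/motif with the tandem detector. The longer allele is
#' designated allele A.
#'
#' @param reference Named character vector of chromosome sequences or an
#'   `sv_reference`.
#' @param site A list/one-row tibble with `chrom`, `start`, `end` (0-based
#'   half-open STR element interval).
#' @param hap1_variants,hap2_variants Tibbles of phased variants (`pos`
#'   0-based, `svtype`, `svlen`, `seq`) local to the site; `NULL` or empty
#'   for a reference haplotype.
#' @param flank Window pad in bp (default 50).
#' @return One-row tibble: `len_a`, `len_b` (allele lengths in bp,
#'   `len_a >= len_b`), `seq_a`, `seq_b`, `period`, `motif`.
#' @export
genotype_str_site <- function(reference, site, hap1_variants = NULL,
                              hap2_variants = NULL, flank = 50L) {
  if (inherits(reference, "sv_reference")) reference <- reference$sequences
  chrom_seq <- reference[[site$chrom]]
  L <- nchar(chrom_seq)
  ws <- max(0L, site$start - flank)
  we <- min(L, site$end + flank)
  alleles <- list(
    apply_haplotype(chrom_seq, ws, we, hap1_variants),
    apply_haplotype(chrom_seq, ws, we, hap2_variants))
  lens <- nchar(alleles)
  a <- which.max(lens)
  b <- setdiff(1:2, a)
  ann <- find_tandem_repeats(alleles[[a]])
  ann <- ann[ann$period >= 2, , drop = FALSE]
  if (nrow(ann) > 0) {
    best <- which.max(ann$end - ann$start)
    period <- ann$period[best]
    motif <- ann$motif[best]
  } else {
    period <- NA_integer_
    motif <- NA_character_
  }
  tibble(len_a = lens[a], len_b = lens[b],
         seq_a = alleles[[a]], seq_b = alleles[[b]],
         period = period, motif = motif)
}

# closed-form one-way ANOVA from group sums of squares
oneway_anova <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g)
  N <- length(values)
  gm <- mean(values)
  means <- vapply(g, mean, numeric(1))
  ns <- vapply(g, length, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw == 0 && ssb == 0) return(list(f = 0, p = 1))
  if (ssw == 0) return(list(f = Inf, p = 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Cross-community variability of STR allele lengths
#'
#' For each site, computes the mean and standard deviation of allele
#' lengths within each community, a one-way ANOVA for differences in
#' allelic composition between communities (both alleles of an individual
#' enter as observations, mirroring the genotyping procedure), and the
#' per-community standard deviation min-max normalized to `[0, 1]` across
#' communities (all zero when communities are equally variable).
#'
#' @param allele_lengths Tibble with `site`, `community`, `length` (one row
#'   per allele).
#' @return A tibble with one row per site: `site`, `f_statistic`,
#'   `p_value`, `significant` (p < 0.05) and a `by_community` list-column
#'   (`community`, `n`, `mean`, `sd`, `norm_sd`).
#' @export
site_variability <- function(allele_lengths) {
  stopifnot_cols(allele_lengths, c("site", "community", "length"))
  sites <- split(allele_lengths, allele_lengths$site)
  rows <- map(sites, function(d) {
    counts <- table(d$community)
    if (length(counts) < 2 || any(counts < 2)) {
      abort("each site needs >= 2 communities with >= 2 alleles each")
    }
    av <- oneway_anova(d$length, d$community)
    st <- d |> group_by(.data$community) |>
      summarise(n = dplyr::n(), mean = mean(.data$length),
                sd = sd(.data$length), .groups = "drop")
    rng <- range(st$sd)
    st$norm_sd <- if (diff(rng) == 0) 0 else (st$sd - rng[1]) / diff(rng)
    tibble(site = d$site[1], f_statistic = av$f, p_value = av$p,
           significant = av$p < 0.05, by_community = list(st))
  })
  bind_rows(rows)
}

#' Normalized-SD matrix for heatmap input
#'
#' Wide matrix (sites x communities) of min-max normalized allele-length
#' standard deviations, restricted to significantly variable sites; rows
#' are in `[0, 1]`. Suitable input for hierarchical clustering (average
#' linkage on Euclidean distances) and heatmap display.
#'
#' @param variability Output of [site_variability()].
#' @param significant_only Keep only sites with ANOVA p < 0.05.
#' @return A numeric matrix with site rownames and community colnames.
#' @export
variability_matrix <- function(variability, significant_only = TRUE) {
  v <- if (significant_only) {
    filter(variability, .data$significant)
  } else variability
  long <- v |> select("site", "by_community") |>
    tidyr::unnest("by_community")
  wide <- tidyr::pivot_wider(long, id_cols = "site",
                             names_from = "community",
                             values_from = "norm_sd")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$site
  m
}
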