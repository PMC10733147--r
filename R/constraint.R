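# Size-normalized variant densities across LOEUF deciles.

gene_region_tables <- function(genes, pad = 2000L) {
  cds <- bind_rows(map(seq_len(nrow(genes)), function(i) {
    mutate(as_tibble(genes$cds[[i]]), chrom = genes$chrom[i],
           gene_id = genes$gene_id[i], decile = genes$loeuf_decile[i])
  }))
  span <- tibble(chrom = genes$chrom,
                 start = pmax(0L, genes$start - pad),
                 end = genes$end + pad,
                 gene_id = genes$gene_id, decile = genes$loeuf_decile)
  list(cds = cds, span = span)
}

#' Assign variants to CDS / non-CDS / intergenic context
#'
#' A variant touching any CDS base is `CDS`; otherwise a variant inside a
#' gene span padded by `pad` bp each side (introns, UTRs, proximal
#' regulatory regions) is `NONCDS`; otherwise `INTERGENIC`. Deletions
#' intersect through their deleted interval, insertions through their
#' anchor point. A variant hitting genes in several deciles is counted once
#' and assigned the lowest (most constrained) decile.
#'
#' @param variants Variants tibble.
#' @param genes Gene-model tibble with `cds` list-column and
#'   `loeuf_decile`.
#' @param pad Flanking pad in bp (default 2000).
#' @return A tibble: `variant_id`, `region_class`, `decile` (`NA` for
#'   intergenic), `gene_id`.
#' @export
partition_hits <- function(variants, genes, pad = 2000L) {
  reg <- gene_region_tables(genes, pad = pad)
  cds_hits <- intersect_variants(variants, reg$cds)
  span_hits <- intersect_variants(variants, reg$span)
  pick <- function(hits) {
    if (nrow(hits) == 0) {
      return(tibble(variant_id = character(0), decile = integer(0),
                    gene_id = character(0)))
    }
    hits |> group_by(.data$variant_id) |>
      arrange(.data$decile, .data$gene_id) |>
      summarise(decile = first(.data$decile),
                gene_id = first(.data$gene_id), .groups = "drop")
  }
  best_cds <- pick(cds_hits)
  best_span <- pick(span_hits)
  out <- tibble(variant_id = variants$variant_id)
  out <- left_join(out, rename(best_cds, cds_decile = "decile",
                               cds_gene = "gene_id"), by = "variant_id")
  out <- left_join(out, rename(best_span, span_decile = "decile",
                               span_gene = "gene_id"), by = "variant_id")
  mutate(out,
    region_class = dplyr::case_when(
      !is.na(.data$cds_decile) ~ "CDS",
      !is.na(.data$span_decile) ~ "NONCDS",
      TRUE ~ "INTERGENIC"),
    decile = dplyr::coalesce(.data$cds_decile, .data$span_decile),
    gene_id = dplyr::coalesce(.data$cds_gene, .data$span_gene)) |>
    select("variant_id", "region_class", "decile", "gene_id")
}

decile_region_bp <- function(genes, pad = 2000L) {
  reg <- gene_region_tables(genes, pad = pad)
  out <- map(1:10, function(d) {
    cds_d <- reg$cds[reg$cds$decile == d, , drop = FALSE]
    span_d <- reg$span[reg$span$decile == d, , drop = FALSE]
    cds_bp <- 0L
    noncds_bp <- 0L
    for (ch in unique(span_d$chrom)) {
      cds_ch <- cds_d[cds_d$chrom == ch, , drop = FALSE]
      span_ch <- span_d[span_d$chrom == ch, , drop = FALSE]
      cds_r <- IRanges::reduce(IRanges::IRanges(cds_ch$start + 1L,
                                                cds_ch$end))
      span_r <- IRanges::reduce(IRanges::IRanges(span_ch$start + 1L,
                                                 span_ch$end))
      cds_bp <- cds_bp + sum(IRanges::width(cds_r))
      noncds_bp <- noncds_bp +
        sum(IRanges::width(IRanges::setdiff(span_r, cds_r)))
    }
    tibble(decile = d,
           region_class = c("CDS", "NONCDS"),
           region_bp = c(cds_bp, noncds_bp))
  })
  bind_rows(out)
}

#' Size-normalized variant density per LOEUF decile
#'
#' Counts variants assigned to CDS and non-CDS regions per decile and
#' divides by the merged (non-overlapping) region size of that decile.
#' When `types` is supplied, densities are additionally split by variant
#' type and normalized to the decile-10 value of each type.
#'
#' @param assignments Output of [partition_hits()].
#' @param genes Gene-model tibble.
#' @param pad Flanking pad used for non-CDS regions (default 2000 bp).
#' @param types Optional tibble (`variant_id`, `type`) used to split
#'   densities by variant type.
#' @return A tibble: (`type`,) `decile`, `region_class`, `count`,
#'   `region_bp`, `density`, `norm_density` (density / decile-10 density of
#'   the same type and region class).
#' @export
decile_density <- function(assignments, genes, pad = 2000L, types = NULL) {
  bp <- decile_region_bp(genes, pad = pad)
  hits <- filter(assignments, .data$region_class %in% c("CDS", "NONCDS"))
  if (!is.null(types)) {
    hits <- left_join(hits, types, by = "variant_id")
  } else {
    hits$type <- "all"
  }
  grid <- tidyr::expand_grid(type = unique(hits$type), bp)
  counts <- count(hits, .data$type, .data$decile, .data$region_class,
                  name = "count")
  out <- left_join(grid, counts, by = c("type", "decile", "region_class")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L),
           density = ifelse(.data$region_bp > 0,
                            .data$count / .data$region_bp, NA_real_))
  out <- out |> group_by(.data$type, .data$region_class) |>
    mutate(norm_density = .data$density /
             .data$density[.data$decile == 10]) |>
    ungroup()
  if (is.null(types)) out <- select(out, -"type")
  out
}

#' Fold difference between two densities
#'
#' Ratio of the less-constrained (higher) density to the more-constrained
#' (lower) one.
#'
#' @param density_low_decile Density in the constrained decile.
#' @param density_high_decile Density in the unconstrained decile.
#' @return `density_high_decile / density_low_decile` (`NA` if the
#'   denominator is zero).
#' @export
#' @examples
#' fold_difference(1.29e-5, 1.60e-4)  # ~12.4
fold_difference <- function(density_low_decile, density_high_decile) {
  ifelse(density_low_decile > 0,
         density_high_decile / density_low_decile, NA_real_)
}

#' Plot decile densities
#'
#' @param densities Output of [decile_density()].
#' @param normalized Plot `norm_density` instead of raw density.
#' @return A ggplot object.
#' @export
plot_decile_density <- function(densities, normalized = FALSE) {
  y <- if (normalized) "norm_density" else "density"
  ggplot2::ggplot(densities,
                  ggplot2::aes(x = factor(.data$decile), y = .data[[y]],
                               fill = .data$region_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "LOEUF decile (1 = most constrained)",
                  y = if (normalized) "density / decile-10 density"
                      else "variants per bp") +
    ggplot2::theme_minimal()
}
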