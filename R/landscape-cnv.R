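# Large copy-number variant regions: filtering, merging, classification.

#' Merge per-sample CNV calls into regions of variable copy number
#'
#' Calls with `p_value` above `p_max` are excluded; remaining calls linked
#' by more than `min_ro` reciprocal overlap are clustered
#' (single-linkage) into merged regions spanning the union of their
#' members. Regions are classified by the number of distinct carrier
#' individuals (`SINGLETON`: 1; `POLYMORPHIC`: more than one and < 50%;
#' `MAJOR`: >= 50% but not all; `SHARED`: all) and by geography
#' (`FOCAL_ONLY` / `FOCAL_ABSENT` / `GLOBAL`). Genes are reported only when
#' fully contained in the region.
#'
#' @param cnv_calls Tibble of per-sample calls: `sample_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `cnv_type`
#'   (`deletion`/`duplication`), `p_value`.
#' @param samples Sample metadata tibble.
#' @param p_max Maximum p-value retained (default 1e-4; a call with
#'   p = 2e-4 is excluded).
#' @param min_ro Reciprocal overlap threshold, strict (default 0.5).
#' @param genes Optional gene-model tibble; contained genes are listed per
#'   region.
#' @return A tibble of regions: `region_id`, `chrom`, `start`, `end`,
#'   `n_calls`, `n_carriers`, `cnv_types`, `sharedness`, `geo`,
#'   `contained_genes` (list-column).
#' @export
merge_cnv_regions <- function(cnv_calls, samples, p_max = 1e-4,
                              min_ro = 0.5, genes = NULL) {
  stopifnot_cols(cnv_calls, c("sample_id", "chrom", "start", "end",
                              "cnv_type", "p_value"))
  calls <- filter(cnv_calls, .data$p_value <= p_max)
  if (nrow(calls) == 0) {
    return(tibble(region_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  n_calls = integer(0), n_carriers = integer(0),
                  cnv_types = character(0), sharedness = character(0),
                  geo = character(0), contained_genes = list()))
  }
  calls$.row <- seq_len(nrow(calls))
  edges <- list()
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    if (length(idx) < 2) next
    c2 <- calls[idx, ]
    r <- IRanges::IRanges(c2$start + 1L, c2$end)
    ov <- IRanges::findOverlaps(r, r)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- qh < sh
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh) == 0) next
    shared <- pmin(c2$end[qh], c2$end[sh]) - pmax(c2$start[qh], c2$start[sh])
    ro <- shared / pmax(c2$end[qh] - c2$start[qh],
                        c2$end[sh] - c2$start[sh])
    pass <- ro > min_ro
    if (any(pass)) {
      edges[[length(edges) + 1L]] <- cbind(idx[qh[pass]], idx[sh[pass]])
    }
  }
  em <- if (length(edges) > 0) do.call(rbind, edges) else {
    matrix(integer(0), ncol = 2)
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(calls) - igraph::vcount(g)))
  calls$cluster <- igraph::components(g)$membership

  n_samples <- nrow(samples)
  regions <- calls |> group_by(.data$cluster) |>
    summarise(chrom = first(.data$chrom),
              start = min(.data$start), end = max(.data$end),
              n_calls = dplyr::n(),
              carriers = list(unique(.data$sample_id)),
              cnv_types = paste(sort(unique(.data$cnv_type)),
                                collapse = ","),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = sprintf("cnvr%03d", row_number()),
           n_carriers = map_int(.data$carriers, length),
           sharedness = dplyr::case_when(
             .data$n_carriers == 1 ~ "SINGLETON",
             .data$n_carriers == n_samples ~ "SHARED",
             .data$n_carriers / n_samples < 0.5 ~ "POLYMORPHIC",
             TRUE ~ "MAJOR"),
           geo = map_chr(.data$carriers, geographic_label,
                         samples = samples))

  regions$contained_genes <- map(seq_len(nrow(regions)), function(i) {
    if (is.null(genes)) return(character(0))
    hit <- genes$chrom == regions$chrom[i] &
      genes$start >= regions$start[i] & genes$end <= regions$end[i]
    genes$gene_id[hit]
  })
  select(regions, "region_id", "chrom", "start", "end", "n_calls",
         "n_carriers", "cnv_types", "sharedness", "geo", "contained_genes")
}
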