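# Reciprocal overlap, novelty labelling, callset merging, benchmarking.

#' Reciprocal overlap between two variants
#'
#' For two deletions on the same chromosome the reciprocal overlap is the
#' shared interval length divided by the larger variant length (equivalent
#' to the minimum of the two per-variant overlap fractions). Point-like
#' insertions have no footprint, so their "overlap" is defined as the size
#' ratio `min(svlen) / max(svlen)` gated on breakpoints being within
#' `window` bp; otherwise 0. Different chromosomes or types give 0.
#'
#' Vectorized over rows: `a` and `b` are tibbles of equal height (or one of
#' them has a single row).
#'
#' @param a,b Variant tibbles with `chrom`, `svtype`, `pos`, `start`,
#'   `end`, `svlen`.
#' @param window Breakpoint proximity gate for insertions, in bp.
#' @return Numeric vector of reciprocal-overlap fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b, window = 200L) {
  n <- max(nrow(a), nrow(b))
  ix <- function(x, col) rep_len(x[[col]], n)
  same <- ix(a, "chrom") == ix(b, "chrom") &
    ix(a, "svtype") == ix(b, "svtype")
  la <- ix(a, "svlen"); lb <- ix(b, "svlen")
  out <- numeric(n)
  del <- same & ix(a, "svtype") == "DEL"
  if (any(del)) {
    shared <- pmax(0, pmin(ix(a, "end"), ix(b, "end"))[del] -
                      pmax(ix(a, "start"), ix(b, "start"))[del])
    out[del] <- shared / pmax(la, lb)[del]
  }
  ins <- same & ix(a, "svtype") == "INS"
  if (any(ins)) {
    near <- abs(ix(a, "pos") - ix(b, "pos"))[ins] <= window
    out[ins] <- ifelse(near,
                       pmin(la, lb)[ins] / pmax(la, lb)[ins], 0)
  }
  out
}

# best single-annotation reciprocal overlap per variant
best_overlap <- function(variants, annotations, window = 200L) {
  out <- tibble(variant_id = variants$variant_id,
                best_overlap = 0, best_annotation = NA_character_)
  if (nrow(annotations) == 0 || nrow(variants) == 0) return(out)
  ann_id <- if ("annotation_id" %in% names(annotations)) {
    annotations$annotation_id
  } else annotations$variant_id
  for (ch in unique(variants$chrom)) {
    for (tp in c("INS", "DEL")) {
      vi <- which(variants$chrom == ch & variants$svtype == tp)
      ai <- which(annotations$chrom == ch & annotations$svtype == tp)
      if (length(vi) == 0 || length(ai) == 0) next
      v <- variants[vi, ]; a <- annotations[ai, ]
      pad <- if (tp == "INS") window else 0L
      q <- IRanges::IRanges(v$start + 1L - pad, pmax(v$end, v$start + 1L) + pad)
      s <- IRanges::IRanges(a$start + 1L, pmax(a$end, a$start + 1L))
      ov <- IRanges::findOverlaps(q, s)
      if (length(ov) == 0) next
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      ro <- reciprocal_overlap(v[qh, ], a[sh, ], window = window)
      cand <- tibble(vi = vi[qh], ai = ai[sh], ro = ro)
      best <- cand |> group_by(.data$vi) |>
        slice(which.max(.data$ro)) |> ungroup()
      upd <- best$ro > out$best_overlap[best$vi]
      out$best_overlap[best$vi[upd]] <- best$ro[upd]
      out$best_annotation[best$vi[upd]] <- ann_id[best$ai[upd]]
    }
  }
  out
}

#' Grade variant novelty against an annotation set
#'
#' Each variant gets the best reciprocal overlap against any single
#' annotated variant and a graded label: `HIGH` (> 0.80), `MODERATE`
#' (0.50 to 0.80), `LOW` ((0, 0.50)), `NONE` (0). Variants absent from the
#' coordinate `mapping` (a lift-over surrogate) are `UNMAPPED`. `HIGH` and
#' `MODERATE` count as annotated; the rest are potentially novel.
#'
#' @param variants Variants tibble.
#' @param annotations Annotation tibble (same columns; e.g. from
#'   [make_annotation_set()]).
#' @param mapping Optional character vector (or tibble with `variant_id`)
#'   of variant ids that can be mapped into the annotation coordinate
#'   space; `NULL` means all variants are mappable.
#' @param window Breakpoint gate for insertion overlap, in bp.
#' @return A tibble: `variant_id`, `best_overlap`, `best_annotation`,
#'   `novelty`, `annotated`.
#' @export
novelty_label <- function(variants, annotations, mapping = NULL,
                          window = 200L) {
  bo <- best_overlap(variants, annotations, window = window)
  mapped <- if (is.null(mapping)) {
    rep(TRUE, nrow(bo))
  } else {
    ids <- if (is.data.frame(mapping)) mapping$variant_id else mapping
    bo$variant_id %in% ids
  }
  mutate(bo,
    novelty = dplyr::case_when(
      !mapped ~ "UNMAPPED",
      .data$best_overlap > 0.80 ~ "HIGH",
      .data$best_overlap >= 0.50 ~ "MODERATE",
      .data$best_overlap > 0 ~ "LOW",
      TRUE ~ "NONE"),
    annotated = .data$novelty %in% c("HIGH", "MODERATE"))
}

match_criteria_ok <- function(a, b, min_ro = 0.5, window = 200L) {
  ro <- reciprocal_overlap(a, b, window = window)
  n <- length(ro)
  bp_ok <- abs(rep_len(a$start, n) - rep_len(b$start, n)) <= window &
    abs(rep_len(a$end, n) - rep_len(b$end, n)) <= window
  list(ro = ro, ok = ro >= min_ro & bp_ok)
}

# candidate same-type pairs between two variant tables, by padded overlap
candidate_pairs <- function(a, b, window = 200L) {
  res <- list()
  for (ch in unique(a$chrom)) {
    for (tp in c("INS", "DEL")) {
      ia <- which(a$chrom == ch & a$svtype == tp)
      ib <- which(b$chrom == ch & b$svtype == tp)
      if (length(ia) == 0 || length(ib) == 0) next
      qa <- IRanges::IRanges(a$start[ia] + 1L - window,
                             pmax(a$end[ia], a$start[ia] + 1L) + window)
      qb <- IRanges::IRanges(b$start[ib] + 1L,
                             pmax(b$end[ib], b$start[ib] + 1L))
      ov <- IRanges::findOverlaps(qa, qb)
      if (length(ov) == 0) next
      res[[length(res) + 1L]] <-
        tibble(i = ia[S4Vectors::queryHits(ov)],
               j = ib[S4Vectors::subjectHits(ov)])
    }
  }
  bind_rows(res)
}

#' Merge per-sample callsets into a joint non-redundant callset
#'
#' A simplified overlap-based merge: records from different samples that
#' match in type, reach the reciprocal-overlap threshold and have
#' breakpoints within `window` bp are linked, and single-linkage clusters
#' become one joint variant whose representative is the highest-QUAL
#' member. Per-sample presence is recorded.
#'
#' @param callsets Named list of per-sample variant tibbles (names are
#'   sample ids), each with the usual variant columns plus `qual`.
#' @param min_ro Minimum reciprocal overlap (default 0.5).
#' @param window Maximum breakpoint shift in bp (default 200).
#' @return A list with `variants` (representatives plus `n_members`) and
#'   `presence` (variants x samples 0/1 matrix).
#' @export
merge_callsets <- function(callsets, min_ro = 0.5, window = 200L) {
  stopifnot(length(names(callsets)) == length(callsets))
  pooled <- bind_rows(purrr::imap(callsets,
                                  function(df, nm) mutate(df, .sample = nm)))
  pooled$.row <- seq_len(nrow(pooled))
  pairs <- candidate_pairs(pooled, pooled, window = window)
  pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  if (nrow(pairs) > 0) {
    chk <- match_criteria_ok(pooled[pairs$i, ], pooled[pairs$j, ],
                             min_ro = min_ro, window = window)
    pairs <- pairs[chk$ok, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(
    cbind(pairs$i, pairs$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(pooled) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  pooled$cluster <- comp[pooled$.row]

  reps <- pooled |> group_by(.data$cluster) |>
    arrange(desc(.data$qual)) |>
    summarise(rep = first(.data$.row),
              n_members = dplyr::n(),
              samples = list(unique(.data$.sample)), .groups = "drop")
  variants <- pooled[reps$rep, , drop = FALSE] |>
    mutate(n_members = reps$n_members)
  sample_ids <- names(callsets)
  presence <- matrix(0L, nrow = nrow(reps), ncol = length(sample_ids),
                     dimnames = list(NULL, sample_ids))
  for (k in seq_len(nrow(reps))) {
    presence[k, unlist(reps$samples[[k]])] <- 1L
  }
  ord <- order(variants$chrom, variants$pos, variants$variant_id)
  variants <- variants[ord, , drop = FALSE] |>
    select(-".sample", -".row", -"cluster")
  presence <- presence[ord, , drop = FALSE]
  rownames(presence) <- variants$variant_id
  list(variants = variants, presence = presence)
}

#' Benchmark a callset against a truth set
#'
#' Calls are matched one-to-one to truth records greedily by descending
#' reciprocal overlap among pairs that match in type, reach `min_ro` and
#' have breakpoints within `window` bp. Precision is `TP / (TP + FP)`,
#' recall is `TP / (TP + FN)` (NA for an empty truth set).
#'
#' @param calls,truth Variant tibbles.
#' @param min_ro Minimum reciprocal overlap (default 0.5).
#' @param window Maximum breakpoint distance in bp (default 200).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
benchmark_callset <- function(calls, truth, min_ro = 0.5, window = 200L) {
  if (nrow(truth) == 0) {
    return(tibble(tp = 0L, fp = nrow(calls), fn = 0L,
                  precision = ifelse(nrow(calls) > 0, 0, NA_real_),
                  recall = NA_real_))
  }
  pairs <- candidate_pairs(calls, truth, window = window)
  tp <- 0L
  if (nrow(pairs) > 0) {
    chk <- match_criteria_ok(calls[pairs$i, ], truth[pairs$j, ],
                             min_ro = min_ro, window = window)
    pairs$ro <- chk$ro
    pairs <- pairs[chk$ok, , drop = FALSE]
    pairs <- pairs[order(-pairs$ro), , drop = FALSE]
    used_call <- logical(nrow(calls)); used_truth <- logical(nrow(truth))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!used_call[i] && !used_truth[j]) {
        used_call[i] <- TRUE; used_truth[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(calls) - tp
  fn <- nrow(truth) - tp
  tibble(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = tp / (tp + fn))
}
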