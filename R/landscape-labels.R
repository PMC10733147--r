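# Sharedness, geography and community-spread labels.

#' Sharedness label from carrier count
#'
#' A variant seen in one individual is `PRIVATE`; in more than one but less
#' than 50% of individuals, `POLYMORPHIC`; in at least 50% but not all,
#' `MAJOR`; in all individuals, `SHARED`. `PRIVATE` takes precedence for
#' tiny cohorts where one individual is half the cohort.
#'
#' @param carrier_count Integer vector of carrier counts (each >= 1).
#' @param n_samples Cohort size (scalar or vector).
#' @return Character vector of labels.
#' @export
#' @examples
#' sharedness(c(1, 3, 80, 141), 141)
sharedness <- function(carrier_count, n_samples) {
  if (any(carrier_count < 1)) abort("carrier_count must be >= 1 (observed variant)")
  if (any(carrier_count > n_samples)) abort("carrier_count exceeds cohort size")
  dplyr::case_when(
    carrier_count == 1 ~ "PRIVATE",
    carrier_count == n_samples ~ "SHARED",
    carrier_count / n_samples < 0.5 ~ "POLYMORPHIC",
    TRUE ~ "MAJOR")
}

#' Geographic label of one variant
#'
#' `FOCAL_ONLY` when every carrier is in the focal set, `FOCAL_ABSENT` when
#' every carrier is in the outgroup, `GLOBAL` otherwise.
#'
#' @param carriers Character vector of carrier sample ids (non-empty).
#' @param samples Sample metadata tibble (`sample_id`, `community`,
#'   `in_focal_set`).
#' @return A single label.
#' @export
geographic_label <- function(carriers, samples) {
  if (length(carriers) == 0) abort("empty carrier set")
  focal <- samples$in_focal_set[match(carriers, samples$sample_id)]
  if (any(is.na(focal))) abort("carrier not present in sample metadata")
  if (all(focal)) "FOCAL_ONLY" else if (all(!focal)) "FOCAL_ABSENT" else "GLOBAL"
}

#' Community spread of a focal-only variant
#'
#' Defined over the focal-community partition: `PRIVATE` (one individual),
#' `COMMUNITY_SPECIFIC` (more than one individual, all in one community),
#' `WIDESPREAD` (more than one community but not all) and `SHARED_ALL`
#' (present in every focal community).
#'
#' @param carriers Character vector of carrier sample ids (non-empty; all
#'   focal).
#' @param samples Sample metadata tibble.
#' @return A single label.
#' @export
community_spread <- function(carriers, samples) {
  if (length(carriers) == 0) abort("empty carrier set")
  idx <- match(carriers, samples$sample_id)
  if (any(is.na(idx))) abort("carrier not present in sample metadata")
  if (!all(samples$in_focal_set[idx])) {
    abort("community spread is defined for focal-only variants")
  }
  n_comm <- length(unique(samples$community[samples$in_focal_set]))
  comms <- unique(samples$community[idx])
  if (length(carriers) == 1) {
    "PRIVATE"
  } else if (length(comms) == 1) {
    "COMMUNITY_SPECIFIC"
  } else if (length(comms) == n_comm) {
    "SHARED_ALL"
  } else {
    "WIDESPREAD"
  }
}

#' Label every variant in a genotype matrix
#'
#' Convenience driver computing carrier counts, sharedness, geographic and
#' (for focal-only variants) community-spread labels from a presence
#' matrix.
#'
#' @param geno An `sv_genotypes` object.
#' @return A tibble: `variant_id`, `carrier_count`, `sharedness`, `geo`,
#'   `spread` (`NA` unless `geo == "FOCAL_ONLY"`).
#' @export
label_variants <- function(geno) {
  pres <- geno$presence
  samples <- geno$samples
  n <- ncol(pres)
  cc <- rowSums(pres)
  keep <- cc >= 1
  focal <- samples$in_focal_set
  focal_cc <- rowSums(pres[, focal, drop = FALSE])
  geo <- dplyr::case_when(
    focal_cc == cc ~ "FOCAL_ONLY",
    focal_cc == 0 ~ "FOCAL_ABSENT",
    TRUE ~ "GLOBAL")
  comm <- samples$community
  focal_comms <- unique(comm[focal])
  comm_counts <- vapply(focal_comms, function(cm) {
    rowSums(pres[, comm == cm, drop = FALSE])
  }, numeric(nrow(pres)))
  if (is.null(dim(comm_counts))) {
    comm_counts <- matrix(comm_counts, nrow = nrow(pres))
  }
  n_comm_present <- rowSums(comm_counts > 0)
  spread <- dplyr::case_when(
    geo != "FOCAL_ONLY" ~ NA_character_,
    cc == 1 ~ "PRIVATE",
    n_comm_present == 1 ~ "COMMUNITY_SPECIFIC",
    n_comm_present == length(focal_comms) ~ "SHARED_ALL",
    TRUE ~ "WIDESPREAD")
  out <- tibble(variant_id = geno$variant_ids,
                carrier_count = as.integer(cc),
                sharedness = ifelse(keep, sharedness(pmax(cc, 1), n),
                                    NA_character_),
                geo = ifelse(keep, geo, NA_character_),
                spread = ifelse(keep, spread, NA_character_))
  out
}
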