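# Population structure: Bray-Curtis dissimilarity, principal coordinate
# analysis, and the Weir-Cockerham fixation index.

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on the binary presence matrix:
#' `BC(i, j) = 1 - 2 |shared| / (|vars_i| + |vars_j|)`. Samples carrying no
#' variants are maximally dissimilar (1) to every other sample and flagged
#' with a warning.
#'
#' @param geno An `sv_genotypes` object (or 0/1 presence matrix, variants x
#'   samples).
#' @return A symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(geno) {
  pres <- if (inherits(geno, "sv_genotypes")) geno$presence else geno
  empty <- colSums(pres) == 0
  d <- as.matrix(vegan::vegdist(t(pres), method = "bray"))
  if (any(empty)) {
    warn(sprintf("%d sample(s) carry no variants; dissimilarity set to 1",
                 sum(empty)))
    d[empty, ] <- 1
    d[, empty] <- 1
  }
  diag(d) <- 0
  d
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical scaling: the doubly centred matrix `B = -1/2 J D^2 J` is
#' eigen-decomposed; coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues. The percent variance of each axis is
#' its eigenvalue divided by the sum of positive eigenvalues times 100
#' (negative eigenvalues, which a semi-metric like Bray-Curtis can
#' produce, are excluded from the denominator).
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param samples Optional sample metadata tibble joined into `tidy()` and
#'   `autoplot()` output.
#' @return An `sv_pcoa` object: `coordinates` (samples x axes matrix),
#'   `eigenvalues`, `percent_variance`, `samples`.
#' @export
sv_pcoa <- function(d, samples = NULL) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d)))) abort("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  if (length(pos) == 0) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "PCoA1"))
    return(structure(list(coordinates = coords, eigenvalues = eig$values,
                          percent_variance = rep(0, length(eig$values)),
                          samples = samples), class = "sv_pcoa"))
  }
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(d), paste0("PCoA", seq_along(pos)))
  pct <- eig$values / sum(eig$values[pos]) * 100
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 percent_variance = pct, samples = samples),
            class = "sv_pcoa")
}

#' @export
print.sv_pcoa <- function(x, ...) {
  cat(sprintf("<sv_pcoa> %d samples, %d positive axes; PCoA1 %.1f%%, PCoA2 %.1f%%\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$percent_variance[1],
              ifelse(length(x$percent_variance) > 1,
                     x$percent_variance[2], NA)))
  invisible(x)
}

#' @export
tidy.sv_pcoa <- function(x, n_axes = 2, ...) {
  n_axes <- min(n_axes, ncol(x$coordinates))
  out <- tibble(sample_id = rownames(x$coordinates))
  for (k in seq_len(n_axes)) {
    out[[paste0("axis", k)]] <- x$coordinates[, k]
  }
  if (!is.null(x$samples)) out <- left_join(out, x$samples, by = "sample_id")
  out
}

#' @export
glance.sv_pcoa <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates),
         n_positive_axes = ncol(x$coordinates),
         pct_axis1 = x$percent_variance[1],
         pct_axis2 = ifelse(length(x$percent_variance) > 1,
                            x$percent_variance[2], NA_real_))
}

#' @export
autoplot.sv_pcoa <- function(object, ...) {
  df <- tidy(object)
  pct <- object$percent_variance
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2))
  if ("community" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$community))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = sprintf("PCoA1 (%.1f%%)", pct[1]),
                    y = sprintf("PCoA2 (%.1f%%)", pct[2])) +
    ggplot2::theme_minimal()
}

#' Random subset of common variants
#'
#' Uniformly samples (without replacement) up to `n` loci whose carrier
#' frequency is strictly above `min_freq`; when fewer qualify, all
#' qualifying loci are returned with a warning.
#'
#' @param geno An `sv_genotypes` object.
#' @param min_freq Frequency threshold (strict; default 0.10).
#' @param n Subset size (default 10000).
#' @param seed Integer seed.
#' @return Character vector of variant ids.
#' @export
subset_common_svs <- function(geno, min_freq = 0.10, n = 10000L, seed = 1L) {
  freq <- rowMeans(geno$presence)
  qual <- which(freq > min_freq)
  if (length(qual) <= n) {
    if (length(qual) < n) {
      warn(sprintf("only %d loci exceed frequency %.2f (requested %d)",
                   length(qual), min_freq, n))
    }
    return(geno$variant_ids[qual])
  }
  with_seed(seed, geno$variant_ids[sort(sample(qual, n))])
}

# per-locus Weir-Cockerham variance components for two groups of diploids
wc_components_pair <- function(dos1, dos2) {
  n1 <- rowSums(!is.na(dos1)); n2 <- rowSums(!is.na(dos2))
  p1 <- rowMeans(dos1, na.rm = TRUE) / 2
  p2 <- rowMeans(dos2, na.rm = TRUE) / 2
  h1 <- rowMeans(dos1 == 1L, na.rm = TRUE)
  h2 <- rowMeans(dos2 == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  ok <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1  # drop monomorphic loci
  list(a = a, b = b, c = cc, ok = ok)
}

# haploid analogue (presence/absence treated as one allele per sample)
wc_components_haploid <- function(x1, x2) {
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  p1 <- rowMeans(x1, na.rm = TRUE)
  p2 <- rowMeans(x2, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - r)
  a <- (msp - msg) / nc
  ok <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1
  list(a = a, b = msg * 0, c = msg, ok = ok)
}

#' Pairwise Weir-Cockerham fixation index
#'
#' Estimates theta (FST) for every pair of groups as the ratio of sums of
#' per-locus variance components: among-population (a), among individuals
#' within populations (b) and within individuals (c), following the 1984
#' Weir & Cockerham estimator for diploid genotypes. Missing genotypes are
#' excluded per locus; loci monomorphic across a pair are skipped. A
#' haploid-like mode treating the presence matrix as one allele per sample
#' is available and flagged in the output.
#'
#' @param geno An `sv_genotypes` object.
#' @param loci Optional variant-id subset (e.g. from
#'   [subset_common_svs()]).
#' @param mode `"diploid"` (dosage-based; default) or `"haploid"`
#'   (presence-based fallback).
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `theta`, `n_loci`, `mode`.
#' @export
wc_fst <- function(geno, loci = NULL, mode = c("diploid", "haploid")) {
  mode <- match.arg(mode)
  mat <- if (mode == "diploid") geno$dosage else geno$presence
  if (!is.null(loci)) mat <- mat[match(loci, geno$variant_ids), ,
                                 drop = FALSE]
  groups <- sort(unique(geno$samples$community))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- map(pairs, function(pr) {
    i1 <- geno$samples$community == pr[1]
    i2 <- geno$samples$community == pr[2]
    if (sum(i1) < 2 || sum(i2) < 2) {
      abort("each group needs at least 2 samples")
    }
    m1 <- mat[, i1, drop = FALSE]; m2 <- mat[, i2, drop = FALSE]
    comp <- if (mode == "diploid") wc_components_pair(m1, m2) else
      wc_components_haploid(m1, m2)
    ok <- comp$ok & !is.na(comp$a)
    theta <- sum(comp$a[ok]) /
      sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
    tibble(group1 = pr[1], group2 = pr[2], theta = theta,
           n_loci = sum(ok), mode = mode)
  })
  bind_rows(rows)
}
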