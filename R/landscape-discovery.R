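# Discovery curves: cumulative non-redundant variant counts and log fit.

#' Variant discovery curve
#'
#' Starting from a single individual, counts the cumulative number of
#' distinct variants as individuals are added one at a time. The addition
#' order is randomized; the mean curve over `n_permutations` random orders
#' is reported, together with a least-squares fit of
#' `count = a + b * ln(n)`.
#'
#' @param geno An `sv_genotypes` object (or 0/1 presence matrix, variants x
#'   samples).
#' @param n_permutations Number of random addition orders (default 10).
#' @param seed Integer seed for the permutations.
#' @return An `sv_discovery` object with `curve` (tibble: `n_samples`,
#'   `mean_count`, `sd_count`), `fit` (the `lm` object), `n_permutations`
#'   and `seed`. `tidy()` returns the curve, `glance()` the coefficients.
#' @export
discovery_curve <- function(geno, n_permutations = 10L, seed = 1L) {
  pres <- if (inherits(geno, "sv_genotypes")) geno$presence else geno
  n <- ncol(pres)
  if (n < 2) abort("need at least 2 samples")
  counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      ord <- sample.int(n)
      seen <- logical(nrow(pres))
      out <- integer(n)
      for (i in seq_len(n)) {
        seen <- seen | (pres[, ord[i]] > 0)
        out[i] <- sum(seen)
      }
      out
    }, integer(n))
  })
  curve <- tibble(
    n_samples = seq_len(n),
    mean_count = rowMeans(counts),
    sd_count = apply(counts, 1, sd))
  fit <- lm(mean_count ~ log(n_samples), data = curve)
  structure(list(curve = curve, fit = fit,
                 n_permutations = n_permutations,
                 seed = as.integer(seed)),
            class = "sv_discovery")
}

#' @export
print.sv_discovery <- function(x, ...) {
  co <- coef(x$fit)
  cat(sprintf(
    "<sv_discovery> %d samples, final count %.0f; fit: count = %.1f + %.1f ln(n)\n",
    nrow(x$curve), x$curve$mean_count[nrow(x$curve)], co[1], co[2]))
  invisible(x)
}

#' @export
tidy.sv_discovery <- function(x, ...) x$curve

#' @export
glance.sv_discovery <- function(x, ...) {
  co <- coef(x$fit)
  tibble(a = unname(co[1]), b = unname(co[2]),
         r_squared = summary(x$fit)$r.squared,
         final_count = x$curve$mean_count[nrow(x$curve)],
         n_samples = nrow(x$curve))
}

#' @export
autoplot.sv_discovery <- function(object, ...) {
  co <- coef(object$fit)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$n_samples, y = .data$mean_count)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_count - .data$sd_count,
      ymax = .data$mean_count + .data$sd_count), alpha = 0.2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::stat_function(fun = function(x) co[1] + co[2] * log(x),
                           colour = "steelblue") +
    ggplot2::labs(x = "individuals sampled",
                  y = "non-redundant variants") +
    ggplot2::theme_minimal()
}

#' Variant density by distance to the nearest telomere
#'
#' Each variant's distance to the nearest chromosome end is binned into
#' fixed windows; per-bin counts are averaged across chromosomes to give a
#' generic-chromosome density profile, optionally split by a grouping
#' column and smoothed with a local-linear (tricube-weighted) fit on
#' log-transformed counts.
#'
#' @param variants Variants tibble (`chrom`, `pos`), optionally with a
#'   grouping column named by `by` (e.g. classification label).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param bin Window size in bp (default 500 kb).
#' @param by Optional name of a grouping column in `variants`.
#' @param smooth Add a `smoothed` column (default TRUE when enough bins).
#' @param span Smoother span (default 0.75).
#' @return A tibble: (`group`,) `bin`, `distance` (bin midpoint bp),
#'   `mean_count` and optionally `smoothed`.
#' @export
telomere_density <- function(variants, chrom_lengths, bin = 500000L,
                             by = NULL, smooth = TRUE, span = 0.75) {
  v <- variants
  L <- chrom_lengths[v$chrom]
  d <- pmin(v$pos, L - v$pos)
  v$bin <- floor(d / bin)
  v$group <- if (is.null(by)) "all" else as.character(v[[by]])
  # number of chromosomes contributing each bin
  max_bin <- floor((chrom_lengths / 2) / bin)
  n_chrom_with_bin <- vapply(0:max(max_bin),
                             function(b) sum(max_bin >= b), numeric(1))
  grid <- tidyr::expand_grid(group = unique(v$group), bin = 0:max(max_bin))
  counts <- v |> count(.data$group, .data$bin, .data$chrom) |>
    group_by(.data$group, .data$bin) |>
    summarise(total = sum(.data$n), .groups = "drop")
  out <- left_join(grid, counts, by = c("group", "bin")) |>
    mutate(total = dplyr::coalesce(.data$total, 0L),
           mean_count = .data$total / n_chrom_with_bin[.data$bin + 1],
           distance = (.data$bin + 0.5) * bin) |>
    select("group", "bin", "distance", "mean_count")
  if (smooth && length(unique(out$bin)) >= 8) {
    out <- out |> group_by(.data$group) |>
      mutate(smoothed = exp(predict(loess(
        log(.data$mean_count + 1) ~ .data$distance, span = span,
        degree = 1))) - 1) |>
      ungroup()
  }
  out
}

#' @rdname telomere_density
#' @param density Output of `telomere_density()`.
#' @export
plot_telomere_density <- function(density) {
  p <- ggplot2::ggplot(density,
                       ggplot2::aes(x = .data$distance / 1e6,
                                    y = .data$mean_count,
                                    colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "distance to nearest telomere (Mb)",
                  y = "mean variants per bin") +
    ggplot2::theme_minimal()
  if ("smoothed" %in% names(density)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smoothed))
  }
  p
}
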