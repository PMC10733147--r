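# Sharedness/geography labels, overlap machinery, merging, benchmarking,
# discovery curves, telomere density, CNV regions.

test_that("sharedness follows the caption rules and hand enumeration", {
  expect_equal(sharedness(1, 141), "PRIVATE")
  expect_equal(sharedness(141, 141), "SHARED")
  expect_equal(sharedness(70, 141), "POLYMORPHIC")  # 70/141 < 0.5
  expect_equal(sharedness(71, 141), "MAJOR")
  expect_error(sharedness(0, 10), "carrier_count")

  for (n in 2:8) {
    for (c in 1:n) {
      want <- if (c == 1) "PRIVATE"
        else if (c == n) "SHARED"
        else if (c / n < 0.5) "POLYMORPHIC"
        else "MAJOR"
      expect_equal(sharedness(c, n), want)
    }
  }
})

make_label_samples <- function() {
  tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    community = c("P1", "P1", "P2", "P2", "P3", "P3", "OUT", "OUT"),
    in_focal_set = c(rep(TRUE, 6), FALSE, FALSE))
}

test_that("geographic and spread labels follow the caption rules", {
  samples <- make_label_samples()
  expect_equal(geographic_label(c("s1", "s2", "s3"), samples), "FOCAL_ONLY")
  expect_equal(geographic_label(c("s7", "s8"), samples), "FOCAL_ABSENT")
  expect_equal(geographic_label(c("s1", "s7"), samples), "GLOBAL")
  expect_error(geographic_label(character(0), samples), "empty")

  expect_equal(community_spread("s1", samples), "PRIVATE")
  expect_equal(community_spread(c("s1", "s2"), samples),
               "COMMUNITY_SPECIFIC")
  expect_equal(community_spread(c("s1", "s3"), samples), "WIDESPREAD")
  expect_equal(community_spread(c("s1", "s3", "s5"), samples), "SHARED_ALL")
  expect_error(community_spread(c("s1", "s7"), samples), "focal-only")
})

test_that("label driver partitions all variants consistently", {
  coh <- tiny_cohort()
  geno <- build_genotype_matrix(coh$callset)
  lab <- label_variants(geno)
  expect_false(any(is.na(lab$sharedness)))
  expect_false(any(is.na(lab$geo)))
  expect_true(all(is.na(lab$spread) == (lab$geo != "FOCAL_ONLY")))
  # each scheme is a partition: one label per variant
  expect_equal(nrow(lab), nrow(coh$callset$variants))
})

test_that("reciprocal overlap matches brute force on random pairs", {
  a <- tibble::tibble(variant_id = "a", chrom = "chrA", pos = 0L,
                      start = 0L, end = 100L, svtype = "DEL", svlen = 100L)
  expect_equal(reciprocal_overlap(a, a), 1)
  b <- dplyr::mutate(a, pos = 50L, start = 50L, end = 150L)
  expect_equal(reciprocal_overlap(a, b), 0.5)

  set.seed(23)
  x <- random_variants(1000)
  y <- x[sample.int(1000), ]
  got <- reciprocal_overlap(x, y)
  for (i in sample.int(1000, 120)) {
    expect_equal(got[i], bf_reciprocal_overlap(x[i, ], y[i, ]))
  }
})

test_that("novelty bands follow the graded reciprocal-overlap rules", {
  v <- tibble::tibble(variant_id = c("v1", "v2", "v3"), chrom = "chrA",
                      pos = c(1000L, 5000L, 9000L),
                      start = c(1000L, 5000L, 9000L),
                      end = c(1001L, 5001L, 9001L),
                      svtype = "INS", svlen = c(100L, 100L, 100L))
  ann <- tibble::tibble(annotation_id = c("a1", "a2"), chrom = "chrA",
                        pos = c(1000L, 5000L), start = c(1000L, 5000L),
                        end = c(1001L, 5001L), svtype = "INS",
                        svlen = c(100L, 60L))
  nl <- novelty_label(v, ann)
  expect_equal(nl$novelty, c("HIGH", "MODERATE", "NONE"))
  expect_equal(nl$best_overlap, c(1, 0.6, 0))
  expect_equal(nl$annotated, c(TRUE, TRUE, FALSE))

  nl2 <- novelty_label(v, ann, mapping = c("v1", "v3"))
  expect_equal(nl2$novelty, c("HIGH", "UNMAPPED", "NONE"))
})

test_that("novelty labels equal brute-force best overlap on the fixture", {
  coh <- tiny_cohort()
  v <- coh$callset$variants[seq_len(120), ]
  ann <- make_annotation_set(coh$callset$variants, keep_fraction = 0.6,
                             jitter_bp = 30, size_noise = 0.3, seed = 5)
  nl <- novelty_label(v, ann)
  for (i in sample.int(nrow(v), 40)) {
    ro <- vapply(seq_len(nrow(ann)), function(j) {
      bf_reciprocal_overlap(v[i, ], ann[j, ])
    }, numeric(1))
    expect_equal(nl$best_overlap[i], max(ro, 0))
  }
})

test_that("callset merging collapses jittered duplicates to truth count", {
  set.seed(41)
  # well-separated truth records so only jittered copies can match
  pos <- seq(5000L, by = 5000L, length.out = 60)
  svlen <- sample(400:2000, 60, replace = TRUE)
  truth <- tibble::tibble(
    variant_id = sprintf("t%02d", 1:60),
    chrom = rep(c("chrA", "chrB"), length.out = 60),
    pos = pos, start = pos, end = pos + svlen,
    svtype = "DEL", svlen = svlen,
    qual = round(runif(60, 5, 60), 2))
  jitter_copy <- function(df) {
    j <- sample(-50:50, nrow(df), replace = TRUE)
    dplyr::mutate(df, pos = pos + j, start = start + j, end = end + j,
                  qual = round(runif(nrow(df), 5, 60), 2))
  }
  callsets <- list(s1 = jitter_copy(truth), s2 = jitter_copy(truth),
                   s3 = jitter_copy(truth))
  merged <- merge_callsets(callsets)
  expect_equal(nrow(merged$variants), nrow(truth))
  expect_true(all(merged$presence == 1L))

  ident <- merge_callsets(list(s1 = truth, s2 = truth))
  expect_equal(nrow(ident$variants), nrow(truth))

  far <- dplyr::mutate(truth, chrom = "chrC")
  disjoint <- merge_callsets(list(s1 = truth, s2 = far))
  expect_equal(nrow(disjoint$variants), 2 * nrow(truth))
})

test_that("benchmarking applies the matching criteria and formulas", {
  set.seed(13)
  x <- random_variants(40)
  self <- benchmark_callset(x, x)
  expect_equal(self$tp, 40L)
  expect_equal(self$fp, 0L)
  expect_equal(self$fn, 0L)
  expect_equal(self$precision, 1)
  expect_equal(self$recall, 1)

  part <- benchmark_callset(x[1:8, ], x[1:10, ])
  expect_equal(part$recall, 0.8)
  expect_equal(part$precision, 1)

  ins <- tibble::tibble(variant_id = "i", chrom = "chrA", pos = 1000L,
                        start = 1000L, end = 1001L, svtype = "INS",
                        svlen = 100L, qual = 30)
  near <- dplyr::mutate(ins, pos = 1190L, start = 1190L, end = 1191L)
  farr <- dplyr::mutate(ins, pos = 1250L, start = 1250L, end = 1251L)
  expect_equal(benchmark_callset(near, ins)$tp, 1L)
  expect_equal(benchmark_callset(farr, ins)$tp, 0L)

  empty <- benchmark_callset(x[1:3, ], x[0, ])
  expect_true(is.na(empty$recall))
})

test_that("discovery curves are monotone and fit log growth exactly", {
  # all samples identical: flat after the first individual
  pres <- matrix(1L, nrow = 30, ncol = 6,
                 dimnames = list(sprintf("v%d", 1:30), sprintf("s%d", 1:6)))
  dc <- discovery_curve(pres, n_permutations = 4, seed = 1)
  expect_true(all(diff(dc$curve$mean_count) == 0))
  expect_equal(dc$curve$mean_count[1], 30)

  # all variants private: curve is the cumulative sum of per-sample counts
  pres2 <- kronecker(diag(6), matrix(1L, 5, 1))
  rownames(pres2) <- sprintf("v%d", 1:30)
  colnames(pres2) <- sprintf("s%d", 1:6)
  dc2 <- discovery_curve(pres2, n_permutations = 3, seed = 2)
  expect_equal(dc2$curve$mean_count, seq(5, 30, by = 5))
  expect_true(all(diff(dc2$curve$mean_count) >= 0))

  # final value is permutation invariant
  expect_equal(dc2$curve$mean_count[6], sum(rowSums(pres2) > 0))

  # exact recovery of (a, b) from data generated as a + b ln(n)
  n <- 1:40
  fake <- structure(list(curve = tibble::tibble(
    n_samples = n, mean_count = 100 + 35 * log(n), sd_count = 0)),
    class = "sv_discovery")
  fake$fit <- stats::lm(mean_count ~ log(n_samples), data = fake$curve)
  g <- suppressWarnings(glance(fake))  # perfect fit: summary() grumbles
  expect_equal(g$a, 100, tolerance = 0.05 * 100)
  expect_equal(g$b, 35, tolerance = 0.05 * 35)
})

test_that("telomere distance binning averages across chromosomes", {
  lens <- c(c1 = 100000L, c2 = 60000L)
  v <- tibble::tibble(chrom = c("c1", "c1", "c2"),
                      pos = c(0L, 99999L, 30000L))
  td <- telomere_density(v, lens, bin = 10000L, smooth = FALSE)
  expect_equal(td$mean_count[td$bin == 0], 2 / 2)  # both chroms have bin 0
  expect_equal(td$mean_count[td$bin == 3], 1 / 2)  # averaged over 2 chroms

  lens2 <- c(c1 = 100000L, c2 = 100000L)
  set.seed(55)
  u <- tibble::tibble(chrom = sample(c("c1", "c2"), 4000, replace = TRUE),
                      pos = sample.int(100000L, 4000, replace = TRUE))
  tu <- telomere_density(u, lens2, bin = 5000L, smooth = FALSE)
  # uniform variants: flat interior profile (chi-square not rejected);
  # the central bin is a boundary sliver and is excluded
  counts <- tu$mean_count[tu$bin < 10] * 2
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("telomere-enriched TR variants concentrate near chromosome ends", {
  coh <- tiny_cohort()
  ref <- tiny_reference()
  truth <- coh$truth
  v <- dplyr::left_join(coh$callset$variants,
                        truth[, c("variant_id", "class")], by = "variant_id")
  lens <- ref$chrom_lengths
  d <- pmin(v$pos, lens[v$chrom] - v$pos)
  tel <- ref$telomere_region_bp
  frac_tr <- mean(d[v$class == "TR"] < tel)
  frac_non <- mean(d[v$class == "NONREP"] < tel)
  expect_gt(frac_tr, 2 * frac_non)
})

test_that("CNV region merging filters, clusters and contains genes", {
  samples <- make_label_samples()
  calls <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s7"),
    chrom = c("c1", "c1", "c1", "c1"),
    start = c(100000L, 140000L, 500000L, 101000L),
    end = c(200000L, 220000L, 560000L, 201000L),
    cnv_type = c("deletion", "deletion", "duplication", "deletion"),
    p_value = c(1e-5, 1e-5, 1e-6, 1e-5))
  genes <- tibble::tibble(gene_id = c("gIn", "gEdge"), chrom = "c1",
                          start = c(120000L, 190000L),
                          end = c(150000L, 230000L),
                          loeuf_decile = c(1L, 2L))
  reg <- merge_cnv_regions(calls, samples, genes = genes)
  expect_equal(nrow(reg), 2)
  big <- reg[reg$start == 100000L, ]
  expect_equal(big$n_carriers, 3L)
  expect_equal(big$geo, "GLOBAL")
  expect_equal(big$contained_genes[[1]], "gIn")  # boundary gene excluded

  # p-value boundary: 2e-4 excluded
  weak <- dplyr::mutate(calls, p_value = 2e-4)
  expect_equal(nrow(merge_cnv_regions(weak, samples)), 0)

  # two calls with RO 0.6 collapse into one region spanning the union
  two <- calls[1:2, ]
  r2 <- merge_cnv_regions(two, samples)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(100000L, 220000L))
})
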