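# Canonical motifs, expansion criteria, diploid genotyping, variability.

test_that("canonical motif collapses rotations and strands", {
  expect_equal(canonical_motif("CAG"), "AGC")
  expect_setequal(motif_members("CAG"),
                  c("CAG", "AGC", "GCA", "TGC", "GCT", "CTG"))
  expect_equal(canonical_motif("AT"), "AT")
  expect_error(canonical_motif("CAN"), "A/C/G/T")

  # class consistency over all dimers/trimers/tetramers and sampled 5/6-mers
  bases <- c("A", "C", "G", "T")
  all_motifs <- function(k) {
    apply(expand.grid(rep(list(bases), k)), 1, paste, collapse = "")
  }
  set.seed(19)
  motifs <- c(all_motifs(2), all_motifs(3), all_motifs(4),
              sample(all_motifs(5), 60), sample(all_motifs(6), 60))
  for (m in motifs) {
    canon <- canonical_motif(m)
    members <- motif_members(m)
    expect_true(all(canonical_motif(members) == canon))
    expect_true(canon %in% members)
    # idempotent
    expect_equal(canonical_motif(canon), canon)
  }
})

test_that("significant-expansion criteria are conjunctive", {
  # the 130 bp trinucleotide expansion at a 90 bp reference element
  expect_true(is_significant_expansion(3, 90, 130))
  # period below 3 never qualifies
  expect_false(is_significant_expansion(2, 50, 5000))
  # reference element at/above 1 kb never qualifies
  expect_false(is_significant_expansion(5, 2000, 3000))
  # fewer than 10 units
  expect_false(is_significant_expansion(6, 100, 54))
  # less than 50% of reference size
  expect_false(is_significant_expansion(3, 900, 60))
  expect_error(is_significant_expansion(1, 10, 100), "period")
})

test_that("diploid STR genotyping recovers planted allele lengths", {
  ref <- tiny_reference()
  arr <- ref$str_arrays[ref$str_arrays$period == 3, ][1, ]
  site <- list(chrom = arr$chrom, start = arr$start, end = arr$end)

  hom <- genotype_str_site(ref, site)
  expect_equal(hom$len_a, hom$len_b)
  expect_equal(hom$len_a, (arr$end - arr$start) + 100)
  expect_equal(hom$period, 3L)

  ins <- tibble::tibble(pos = arr$start + 6L, svtype = "INS", svlen = 130L,
                        seq = substr(strrep(arr$motif, 44), 1, 130))
  het <- genotype_str_site(ref, site, hap1_variants = ins)
  expect_equal(het$len_a - het$len_b, 130)
  expect_equal(het$period, 3L)
  expect_equal(canonical_motif(het$motif), canonical_motif(arr$motif))

  confl <- dplyr::bind_rows(ins, ins)
  expect_error(genotype_str_site(ref, site, hap1_variants = confl),
               "conflicting")
})

test_that("simulated diploid sites are recovered within 2 bp", {
  ref <- tiny_reference()
  set.seed(123)
  arrays <- ref$str_arrays[sample.int(nrow(ref$str_arrays), 40), ]
  err <- c()
  for (i in seq_len(nrow(arrays))) {
    a <- arrays[i, ]
    site <- list(chrom = a$chrom, start = a$start, end = a$end)
    k1 <- sample(0:30, 1); k2 <- sample(0:30, 1)
    hap <- function(k) {
      if (k == 0) return(NULL)
      tibble::tibble(pos = a$start + a$period, svtype = "INS",
                     svlen = k * a$period, seq = strrep(a$motif, k))
    }
    g <- genotype_str_site(ref, site, hap(k1), hap(k2))
    ref_len <- (a$end - a$start) + 100
    want <- sort(c(ref_len + k1 * a$period, ref_len + k2 * a$period),
                 decreasing = TRUE)
    err <- c(err, abs(g$len_a - want[1]), abs(g$len_b - want[2]))
  }
  expect_gte(mean(err <= 2), 0.95)
})

test_that("ANOVA variability matches closed-form sums of squares", {
  # constant alleles: no variability
  d0 <- tibble::tibble(site = "s", community = rep(c("P1", "P2"), each = 4),
                       length = 10)
  v0 <- site_variability(d0)
  expect_equal(v0$f_statistic, 0)
  expect_equal(v0$p_value, 1)

  # two clearly separated groups; F checked against hand-computed sums
  x1 <- c(10, 12, 11, 13); x2 <- c(30, 31, 29, 32)
  d <- tibble::tibble(site = "s", community = rep(c("P1", "P2"), each = 4),
                      length = c(x1, x2))
  v <- site_variability(d)
  gm <- mean(c(x1, x2))
  ssb <- 4 * (mean(x1) - gm)^2 + 4 * (mean(x2) - gm)^2
  ssw <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  f_hand <- (ssb / 1) / (ssw / 6)
  expect_equal(v$f_statistic, f_hand)
  expect_lt(v$p_value, 0.05)
  # agrees with the stats implementation
  ow <- stats::oneway.test(length ~ community, data = d, var.equal = TRUE)
  expect_equal(v$f_statistic, unname(ow$statistic))
  expect_equal(v$p_value, unname(ow$p.value))

  expect_error(site_variability(
    tibble::tibble(site = "s", community = "P1", length = c(1, 2))),
    ">= 2 communities")
})

test_that("ANOVA p-values agree with a permutation oracle", {
  set.seed(99)
  perm_p <- function(values, groups, n_perm = 4000) {
    f_obs <- svscape:::oneway_anova(values, groups)$f
    f_perm <- replicate(n_perm, {
      svscape:::oneway_anova(values, sample(groups))$f
    })
    mean(f_perm >= f_obs)
  }
  for (rep in 1:3) {
    values <- rnorm(24, sd = 2) + rep(c(0, 0.5, 1), each = 8)
    groups <- rep(c("P1", "P2", "P3"), each = 8)
    p_anova <- svscape:::oneway_anova(values, groups)$p
    p_perm <- perm_p(values, groups)
    expect_lt(abs(p_anova - p_perm), 0.03)
  }
})

test_that("normalized SD rows span [0, 1] and feed the heatmap matrix", {
  set.seed(7)
  d <- tidyr::expand_grid(site = sprintf("site%d", 1:6),
                          community = c("P1", "P2", "P3"),
                          rep = 1:6) |>
    dplyr::mutate(length = rnorm(dplyr::n(),
                                 sd = 1 + 3 * (community == "P2")))
  v <- site_variability(d[, c("site", "community", "length")])
  m <- variability_matrix(v, significant_only = FALSE)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(apply(m, 1, min) == 0))
  expect_true(all(apply(m, 1, max) == 1))
})

test_that("motif and period tables conserve counts and collapse motifs", {
  v <- tibble::tibble(
    variant_id = sprintf("v%d", 1:18),
    svtype = "INS",
    period = c(rep(3L, 15), rep(5L, 3)),
    motif = c(rep("CAG", 10), rep("CTG", 5), rep("AAGGG", 3)),
    region_class = c(rep("CDS", 2), rep("INTERGENIC", 16)))
  tabs <- motif_and_period_tables(v)
  expect_equal(sum(tabs$period_counts$n), 18)
  trip <- tabs$motif_counts[tabs$motif_counts$period == 3, ]
  expect_equal(nrow(trip), 1)  # CAG and CTG share one canonical motif
  expect_equal(trip$n, 15)
  expect_equal(trip$canonical, "AGC")
  ctx <- tabs$period_context
  sums <- ctx |> dplyr::group_by(period) |>
    dplyr::summarise(s = sum(proportion))
  expect_true(all(abs(sums$s - 1) < 1e-12))

  all_inter <- motif_and_period_tables(
    dplyr::mutate(v, region_class = "INTERGENIC"))
  expect_true(all(all_inter$period_context$region_class == "INTERGENIC"))
})
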