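# Bray-Curtis, PCOA and Weir-Cockerham FST.

test_that("Bray-Curtis matches the brute-force pairwise formula", {
  pres <- matrix(c(1, 1, 0, 0,
                   1, 1, 0, 0,
                   0, 0, 1, 1), nrow = 4,
                 dimnames = list(sprintf("v%d", 1:4), c("a", "b", "c")))
  d <- bray_curtis(pres)
  expect_equal(d["a", "b"], 0)         # identical samples
  expect_equal(d["a", "c"], 1)         # disjoint variant sets
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  set.seed(2)
  pres2 <- matrix(rbinom(300, 1, 0.4), nrow = 30,
                  dimnames = list(sprintf("v%d", 1:30),
                                  sprintf("s%d", 1:10)))
  d2 <- bray_curtis(pres2)
  for (i in 1:9) for (j in (i + 1):10) {
    shared <- sum(pres2[, i] & pres2[, j])
    bc <- 1 - 2 * shared / (sum(pres2[, i]) + sum(pres2[, j]))
    expect_equal(d2[i, j], bc)
    expect_equal(d2[j, i], bc)
  }
  expect_true(all(d2 >= 0 & d2 <= 1))

  pres3 <- cbind(pres2, empty = 0L)
  w <- capture_warnings(d3 <- bray_curtis(pres3))
  expect_true(any(grepl("no variants", w)))
  expect_true(all(d3["empty", -11] == 1))
})

test_that("PCOA matches an independent dense solver to 1e-8", {
  set.seed(5)
  x <- matrix(rnorm(25), 5, 5)
  d <- as.matrix(dist(x))[1:5, 1:5]
  dimnames(d) <- list(letters[1:5], letters[1:5])
  p <- sv_pcoa(d)

  ind <- ape::pcoa(as.dist(d))
  k <- min(ncol(p$coordinates), ncol(ind$vectors))
  for (ax in 1:k) {
    a <- p$coordinates[, ax]; b <- ind$vectors[, ax]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  rel <- ind$values$Relative_eig[1:k] * 100
  expect_equal(p$percent_variance[1:k], rel, tolerance = 1e-8)
})

test_that("PCOA separates two tight clusters on axis 1", {
  n <- 10
  d <- matrix(0.9, n, n)
  d[1:5, 1:5] <- 0.05
  d[6:10, 6:10] <- 0.05
  diag(d) <- 0
  dimnames(d) <- list(sprintf("s%d", 1:n), sprintf("s%d", 1:n))
  p <- sv_pcoa(d)
  ax1 <- p$coordinates[, 1]
  expect_true(all(sign(ax1[1:5]) == sign(ax1[1])))
  expect_true(all(sign(ax1[6:10]) == -sign(ax1[1])))
})

test_that("three equidistant samples give two equal positive eigenvalues", {
  d <- matrix(0.5, 3, 3); diag(d) <- 0
  dimnames(d) <- list(letters[1:3], letters[1:3])
  p <- sv_pcoa(d)
  ev <- p$eigenvalues[p$eigenvalues > 1e-12]
  expect_equal(length(ev), 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
})

test_that("common-SV subsetting uses a strict frequency threshold", {
  pres <- rbind(
    matrix(1L, nrow = 5, ncol = 10),               # freq 1
    matrix(rep(c(1L, 0L), c(1, 9)), 5, 10, byrow = TRUE),  # freq 0.1
    matrix(0L, nrow = 2, ncol = 10))
  pres[12, ] <- 0L
  rownames(pres) <- sprintf("v%02d", 1:12)
  colnames(pres) <- sprintf("s%d", 1:10)
  g <- svscape:::new_sv_genotypes(pres, tibble::tibble(
    sample_id = colnames(pres), community = "P1", in_focal_set = TRUE))
  got <- suppressWarnings(subset_common_svs(g, min_freq = 0.10, n = 100))
  # frequency exactly 0.10 is excluded ("higher than 10%")
  expect_setequal(got, sprintf("v%02d", 1:5))
  # nothing above the threshold: empty subset with a warning
  rare <- svscape:::new_sv_genotypes(pres[6:12, , drop = FALSE], g$samples)
  expect_warning(empty <- subset_common_svs(rare, min_freq = 0.10, n = 10),
                 "only 0 loci")
  expect_length(empty, 0)
  # reproducible subsetting under a fixed seed
  big <- matrix(1L, nrow = 50, ncol = 10,
                dimnames = list(sprintf("b%02d", 1:50), colnames(pres)))
  gb <- svscape:::new_sv_genotypes(big, g$samples)
  s1 <- subset_common_svs(gb, n = 20L, seed = 4)
  s2 <- subset_common_svs(gb, n = 20L, seed = 4)
  expect_identical(s1, s2)
  expect_equal(length(s1), 20)
})

make_two_group_geno <- function(dosage) {
  n <- ncol(dosage) / 2
  samples <- tibble::tibble(
    sample_id = colnames(dosage),
    community = rep(c("G1", "G2"), each = n),
    in_focal_set = TRUE)
  svscape:::new_sv_genotypes(dosage, samples)
}

test_that("FST is ~0 under panmixia and 1 at reciprocal fixation", {
  set.seed(21)
  n_loci <- 8000; n <- 30
  p <- runif(n_loci, 0.1, 0.9)
  dos <- matrix(rbinom(n_loci * 2 * n, 2, rep(p, 2 * n)), nrow = n_loci,
                dimnames = list(sprintf("L%d", 1:n_loci),
                                sprintf("s%d", 1:(2 * n))))
  g <- make_two_group_geno(dos)
  fst <- wc_fst(g)
  expect_lt(abs(fst$theta), 0.01)

  fixed <- cbind(matrix(2L, 500, n), matrix(0L, 500, n))
  rownames(fixed) <- sprintf("F%d", 1:500)
  colnames(fixed) <- sprintf("s%d", 1:(2 * n))
  gf <- make_two_group_geno(fixed)
  expect_equal(wc_fst(gf)$theta, 1)
})

test_that("FST recovers the Balding-Nichols divergence parameter", {
  set.seed(10)
  n_loci <- 10000; n <- 30; theta <- 0.10
  p <- runif(n_loci, 0.05, 0.95)
  draw_group <- function() {
    pk <- rbeta(n_loci, p * (1 - theta) / theta,
                (1 - p) * (1 - theta) / theta)
    matrix(rbinom(n_loci * n, 2, rep(pk, n)), nrow = n_loci)
  }
  dos <- cbind(draw_group(), draw_group())
  dimnames(dos) <- list(sprintf("L%d", 1:n_loci), sprintf("s%d", 1:(2 * n)))
  g <- make_two_group_geno(dos)
  est <- wc_fst(g)$theta
  expect_gte(est, 0.08)
  expect_lte(est, 0.12)

  # rank ordering across divergence levels
  est_at <- function(th) {
    pk1 <- if (th == 0) p else rbeta(n_loci, p * (1 - th) / th,
                                     (1 - p) * (1 - th) / th)
    pk2 <- if (th == 0) p else rbeta(n_loci, p * (1 - th) / th,
                                     (1 - p) * (1 - th) / th)
    d <- cbind(matrix(rbinom(n_loci * n, 2, rep(pk1, n)), nrow = n_loci),
               matrix(rbinom(n_loci * n, 2, rep(pk2, n)), nrow = n_loci))
    dimnames(d) <- dimnames(dos)
    wc_fst(make_two_group_geno(d))$theta
  }
  ests <- vapply(c(0, 0.05, 0.1, 0.2), est_at, numeric(1))
  expect_true(all(diff(ests) > 0))
})

test_that("haploid mode runs on the presence matrix and is flagged", {
  set.seed(3)
  pres <- matrix(rbinom(2000, 1, 0.3), nrow = 100,
                 dimnames = list(sprintf("v%d", 1:100),
                                 sprintf("s%d", 1:20)))
  g <- make_two_group_geno(pres)
  f <- wc_fst(g, mode = "haploid")
  expect_equal(f$mode, "haploid")
  expect_true(is.finite(f$theta))
  expect_lt(abs(f$theta), 0.08)
})

test_that("missing genotypes are excluded from FST but not presence", {
  set.seed(14)
  dos <- matrix(rbinom(400, 2, 0.5), nrow = 20,
                dimnames = list(sprintf("v%d", 1:20), sprintf("s%d", 1:20)))
  dos[1, 1:3] <- NA
  g <- make_two_group_geno(dos)
  expect_equal(g$presence[1, 1:3], c(s1 = 0L, s2 = 0L, s3 = 0L))
  f <- wc_fst(g)
  expect_true(is.finite(f$theta))
})

test_that("sample-order permutation leaves results invariant", {
  set.seed(8)
  dos <- matrix(rbinom(3000, 2, 0.4), nrow = 100,
                dimnames = list(sprintf("v%d", 1:100),
                                sprintf("s%d", 1:30)))
  samples <- tibble::tibble(sample_id = colnames(dos),
                            community = rep(c("G1", "G2", "G3"), each = 10),
                            in_focal_set = TRUE)
  g1 <- svscape:::new_sv_genotypes(dos, samples)
  perm <- sample(30)
  g2 <- svscape:::new_sv_genotypes(dos[, perm], samples[perm, ])
  expect_equal(wc_fst(g1), wc_fst(g2))
  d1 <- bray_curtis(g1); d2 <- bray_curtis(g2)
  expect_equal(d1, d2[colnames(d1), colnames(d1)])
})
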