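# Multi-community diploid cohort simulator with Balding-Nichols structure.

#' Simulation configuration
#'
#' Collects the knobs of the cohort simulator with defaults emulating a
#' small multi-community study: four focal communities plus an outgroup,
#' Balding-Nichols divergence theta = 0.10, and a mixture of planted variant
#' classes. All counts refer to variants that pass the default quality
#' filters; a `frac_weak` share of extra records is emitted with low QUAL or
#' low read support to exercise filtering.
#'
#' @param n_communities Number of focal communities.
#' @param samples_per_community Diploid individuals per focal community.
#' @param outgroup_size Diploid individuals in the outgroup.
#' @param theta Balding-Nichols divergence parameter in `[0, 1)`; `0` means
#'   no drift (all groups share the ancestral frequency).
#' @param n_variants_per_class Named integer vector of planted counts per
#'   class. Recognised classes: `STR`, `TR`, `SINE_complete`,
#'   `SINE_fragment`, `LINE_complete`, `LINE_fragment`, `RETRO_complete`,
#'   `LTR_complete`, `DNA_complete`, `NONREP`, `HOMO`.
#' @param frac_private,frac_focal_only,frac_outgroup_only,frac_community_private
#'   Fractions of variants constrained to the respective geography classes;
#'   the remainder is unconstrained ("global" candidates).
#' @param telomere_enrichment When `TRUE`, a `telomere_tr_frac` share of TR
#'   variants is drawn from arrays inside the telomere-proximal regions.
#' @param telomere_tr_frac See above.
#' @param mut_rate Per-base substitution rate applied to planted repeat
#'   sequences (default 0: pure repeats, so the built-in detectors are exact
#'   oracles). Must be <= 0.05.
#' @param frac_weak Fraction of additional low-evidence records.
#' @param seed Integer seed.
#' @return A `sv_sim_config` list.
#' @export
sv_sim_config <- function(n_communities = 4L, samples_per_community = 10L,
                          outgroup_size = 10L, theta = 0.10,
                          n_variants_per_class = c(
                            STR = 250L, TR = 150L, SINE_complete = 80L,
                            SINE_fragment = 60L, LINE_complete = 30L,
                            LINE_fragment = 40L, RETRO_complete = 40L,
                            LTR_complete = 20L, DNA_complete = 20L,
                            NONREP = 200L, HOMO = 30L),
                          frac_private = 0.10, frac_focal_only = 0.25,
                          frac_outgroup_only = 0.05,
                          frac_community_private = 0.10,
                          telomere_enrichment = TRUE,
                          telomere_tr_frac = 0.7,
                          mut_rate = 0, frac_weak = 0.05, seed = 1L) {
  if (theta < 0 || theta >= 1) abort("theta must be in [0, 1)")
  if (mut_rate > 0.05) abort("mut_rate must be <= 0.05")
  if (any(n_variants_per_class < 0)) abort("variant counts must be >= 0")
  structure(as.list(environment()), class = "sv_sim_config")
}

#' Balding-Nichols per-population allele frequencies
#'
#' Draws one frequency per population around ancestral frequency `p`:
#' `Beta(p (1 - theta) / theta, (1 - p)(1 - theta) / theta)`, whose mean is
#' `p` and variance `theta p (1 - p)`. With `theta = 0` all populations
#' share `p` exactly.
#'
#' @param p Ancestral allele frequency (scalar).
#' @param theta Divergence parameter in `[0, 1)`.
#' @param n_pops Number of populations.
#' @return Numeric vector of length `n_pops`.
#' @export
bn_frequencies <- function(p, theta, n_pops) {
  if (theta == 0) return(rep(p, n_pops))
  rbeta(n_pops, p * (1 - theta) / theta, (1 - p) * (1 - theta) / theta)
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  vapply(seq, function(s) {
    n <- nchar(s)
    k <- rbinom(1, n, rate)
    if (k == 0) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(DNA_BASES, b), 1),
                      character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# build (pos, svtype, svlen, seq, truth fields) for every planted variant
build_planted_variants <- function(reference, config) {
  lib <- reference$library
  cons <- setNames(lib$elements$consensus, lib$elements$name)
  fam <- setNames(lib$elements$family, lib$elements$name)
  counts <- config$n_variants_per_class
  cnt <- function(cl) if (cl %in% names(counts)) as.integer(counts[[cl]]) else 0L
  sample_idx <- function(x, n) x[sample.int(length(x), n)]
  sample_one <- function(lo, hi) {
    if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
  }
  out <- list()

  tandem_variants <- function(arrays, n, class) {
    if (n == 0) return(NULL)
    if (class == "TR" && config$telomere_enrichment) {
      tel <- reference$telomere_region_bp
      L <- reference$chrom_lengths[arrays$chrom]
      near <- arrays$start < tel | arrays$end > L - tel
      n_tel <- min(round(config$telomere_tr_frac * n), sum(near))
      idx <- c(sample_idx(which(near), n_tel),
               sample_idx(which(!near), min(n - n_tel, sum(!near))))
    } else {
      idx <- sample.int(nrow(arrays), min(n, nrow(arrays)))
    }
    if (length(idx) < n) {
      abort(sprintf("not enough planted %s arrays (%d) for %d variants",
                    class, nrow(arrays), n))
    }
    a <- arrays[idx, , drop = FALSE]
    res <- map(seq_len(nrow(a)), function(i) {
      p <- a$period[i]; copies <- a$copies[i]
      kmin <- ceiling(20 / p)
      kmax_del <- copies - 2L
      svtype <- if (kmax_del >= kmin && runif(1) < 0.5) "DEL" else "INS"
      if (svtype == "INS") {
        k <- sample_one(kmin, kmin + 30L)
        j <- sample.int(copies, 1) - 1L        # insert at a unit boundary
        pos <- a$start[i] + j * p
        seq <- strrep(a$motif[i], k)
      } else {
        k <- sample_one(kmin, kmax_del)
        j <- sample.int(copies - k, 1) - 1L
        pos <- a$start[i] + j * p
        seq <- strrep(a$motif[i], k)
      }
      tibble(chrom = a$chrom[i], pos = as.integer(pos), svtype = svtype,
             svlen = k * p, seq = seq, class = class,
             period = p, motif = a$motif[i], element_name = NA_character_)
    })
    bind_rows(res)
  }

  out$STR <- tandem_variants(reference$str_arrays, cnt("STR"), "STR")
  out$TR <- tandem_variants(reference$tr_arrays, cnt("TR"), "TR")

  # positions for inserted sequences: random backbone spots away from
  # planted features
  free_positions <- function(n, pad = 100L) {
    occ <- bind_rows(
      select(reference$str_arrays, "chrom", "start", "end"),
      select(reference$tr_arrays, "chrom", "start", "end"),
      select(reference$elements, "chrom", "start", "end"))
    res <- tibble(chrom = character(0), pos = integer(0))
    while (nrow(res) < n) {
      chrom <- sample(names(reference$chrom_lengths), n, replace = TRUE)
      pos <- floor(runif(n, 1000, reference$chrom_lengths[chrom] - 1000))
      cand <- tibble(chrom = chrom, pos = as.integer(pos))
      ok <- map_int(seq_len(nrow(cand)), function(i) {
        o <- occ[occ$chrom == cand$chrom[i], ]
        as.integer(!any(o$start - pad < cand$pos[i] & o$end + pad > cand$pos[i]))
      })
      res <- bind_rows(res, cand[ok == 1L, ])
    }
    res[seq_len(n), ]
  }

  element_variants <- function(class, n) {
    if (n == 0) return(NULL)
    base <- sub("_(complete|fragment)$", "", class)
    el_name <- switch(base, SINE = "SINE1_syn", LINE = "LINE1_syn",
                      RETRO = "RETRO1_syn", LTR = "LTR1_syn",
                      DNA = "DNA1_syn")
    full <- cons[[el_name]]
    pos <- free_positions(n)
    seqs <- if (grepl("fragment", class)) {
      L <- nchar(full)
      frac <- runif(n, 0.15, 0.55)
      w <- pmax(30L, as.integer(round(frac * L)))
      st <- floor(runif(n, 0, L - w)) + 1L
      substring(full, st, st + w - 1L)
    } else {
      rep(full, n)
    }
    tibble(chrom = pos$chrom, pos = pos$pos, svtype = "INS",
           svlen = nchar(seqs), seq = seqs, class = class,
           period = NA_integer_, motif = NA_character_,
           element_name = el_name)
  }
  for (cl in c("SINE_complete", "SINE_fragment", "LINE_complete",
               "LINE_fragment", "RETRO_complete", "LTR_complete",
               "DNA_complete")) {
    out[[cl]] <- element_variants(cl, cnt(cl))
  }

  if (cnt("NONREP") > 0) {
    n <- cnt("NONREP")
    pos <- free_positions(n)
    svlen <- as.integer(round(exp(runif(n, log(20), log(600)))))
    out$NONREP <- tibble(chrom = pos$chrom, pos = pos$pos, svtype = "INS",
                         svlen = svlen,
                         seq = vapply(svlen, random_dna, character(1)),
                         class = "NONREP", period = NA_integer_,
                         motif = NA_character_,
                         element_name = NA_character_)
  }
  if (cnt("HOMO") > 0) {
    n <- cnt("HOMO")
    pos <- free_positions(n)
    # score >= 50 at match weight 2 needs >= 26 matching positions, so
    # detectable homopolymer arrays are >= ~27 bp; plant 30-45 bp
    svlen <- sample(30:45, n, replace = TRUE)
    base <- sample(DNA_BASES, n, replace = TRUE)
    out$HOMO <- tibble(chrom = pos$chrom, pos = pos$pos, svtype = "INS",
                       svlen = svlen, seq = strrep(base, svlen),
                       class = "HOMO", period = 1L, motif = base,
                       element_name = NA_character_)
  }
  v <- bind_rows(out)
  if (config$mut_rate > 0) {
    tandem <- v$class %in% c("STR", "TR", "HOMO")
    v$seq[tandem] <- mutate_seq(v$seq[tandem], config$mut_rate)
  }
  v
}

#' Simulate a multi-community diploid cohort
#'
#' Plants variants of known repeat class on a synthetic reference (see
#' [make_reference()]), draws per-community allele frequencies under the
#' Balding-Nichols model and diploid genotypes binomially, applies geography
#' constraints (private / focal-only / outgroup-only / community-private),
#' and returns the joint callset with a one-row-per-variant truth table.
#'
#' @param reference An `sv_reference`.
#' @param config An [sv_sim_config()].
#' @return An `sv_cohort`: list with `callset` (an `sv_callset`), `truth`
#'   (tibble: planted class, period/motif or element name, geography class,
#'   per-community frequencies, carrier list, `weak` flag), `samples`,
#'   `config`.
#' @export
simulate_cohort <- function(reference, config = sv_sim_config()) {
  with_seed(config$seed, {
    communities <- paste0("P", seq_len(config$n_communities))
    samples <- bind_rows(
      tibble(sample_id = sprintf("%s_s%02d",
                                 rep(communities,
                                     each = config$samples_per_community),
                                 sequence(rep(config$samples_per_community,
                                              config$n_communities))),
             community = rep(communities,
                             each = config$samples_per_community),
             in_focal_set = TRUE),
      tibble(sample_id = sprintf("OUT_s%02d",
                                 seq_len(config$outgroup_size)),
             community = "OUTGROUP", in_focal_set = FALSE))
    n_samp <- nrow(samples)
    groups <- c(communities, "OUTGROUP")

    v <- build_planted_variants(reference, config)
    nv <- nrow(v)
    # geography classes
    geo_pool <- c(
      rep("private", round(config$frac_private * nv)),
      rep("focal_only", round(config$frac_focal_only * nv)),
      rep("outgroup_only", round(config$frac_outgroup_only * nv)),
      rep("community_private", round(config$frac_community_private * nv)))
    geo <- sample(c(geo_pool, rep("global", max(0, nv - length(geo_pool)))),
                  nv)[seq_len(nv)]
    v$geography <- geo
    v$ancestral_p <- runif(nv, 0.05, 0.95)

    freq <- t(vapply(v$ancestral_p,
                     function(p) bn_frequencies(p, config$theta,
                                                length(groups)),
                     numeric(length(groups))))
    colnames(freq) <- groups

    grp_of <- samples$community
    dosage <- matrix(0L, nrow = nv, ncol = n_samp)
    for (g in groups) {
      cols <- which(grp_of == g)
      dosage[, cols] <- matrix(
        rbinom(nv * length(cols), 2L, rep(freq[, g], length(cols))),
        nrow = nv)
    }
    focal_cols <- which(samples$in_focal_set)
    out_cols <- which(!samples$in_focal_set)
    v$private_community <- NA_character_
    for (i in seq_len(nv)) {
      gcl <- v$geography[i]
      if (gcl == "private") {
        dosage[i, ] <- 0L
        dosage[i, sample(focal_cols, 1)] <- 1L
      } else if (gcl == "focal_only") {
        dosage[i, out_cols] <- 0L
        if (sum(dosage[i, ]) == 0) dosage[i, sample(focal_cols, 1)] <- 1L
      } else if (gcl == "outgroup_only") {
        dosage[i, focal_cols] <- 0L
        if (sum(dosage[i, ]) == 0) dosage[i, sample(out_cols, 1)] <- 1L
      } else if (gcl == "community_private") {
        com <- sample(communities, 1)
        v$private_community[i] <- com
        keep <- which(grp_of == com)
        dosage[i, setdiff(seq_len(n_samp), keep)] <- 0L
        while (sum(dosage[i, keep] > 0) < 2) {
          dosage[i, sample(keep, 1)] <- 1L
        }
      } else if (sum(dosage[i, ]) == 0) {
        dosage[i, sample.int(n_samp, 1)] <- 1L
      }
    }

    # quality / support; a frac_weak share of extra weak records
    n_weak <- round(config$frac_weak * nv)
    weak_idx <- if (n_weak > 0) sample.int(nv, n_weak) else integer(0)
    # weak rows are duplicated as additional low-evidence records
    v$weak <- FALSE
    v$qual <- runif(nv, 20, 60)
    v$support_fraction <- if_else(v$svtype == "DEL",
                                  runif(nv, 0.3, 0.95),
                                  runif(nv, 0.2, 0.95))
    if (n_weak > 0) {
      wv <- v[weak_idx, , drop = FALSE]
      wv$weak <- TRUE
      fail_qual <- runif(n_weak) < 0.5
      wv$qual <- if_else(fail_qual, runif(n_weak, 0, 4.99), wv$qual)
      wv$support_fraction <- if_else(!fail_qual,
                                     if_else(wv$svtype == "DEL",
                                             runif(n_weak, 0.01, 0.19),
                                             runif(n_weak, 0.001, 0.049)),
                                     wv$support_fraction)
      wd <- dosage[weak_idx, , drop = FALSE]
      v <- bind_rows(v, wv)
      dosage <- rbind(dosage, wd)
      freq <- rbind(freq, freq[weak_idx, , drop = FALSE])
    }

    ord <- order(v$chrom, v$pos)
    v <- v[ord, , drop = FALSE]
    dosage <- dosage[ord, , drop = FALSE]
    v$variant_id <- sprintf("sv%05d", seq_len(nrow(v)))
    v$start <- v$pos
    v$end <- if_else(v$svtype == "DEL", v$pos + v$svlen, v$pos + 1L)

    gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], nrow = nrow(v),
                 dimnames = list(v$variant_id, samples$sample_id))

    variants <- select(v, "variant_id", "chrom", "pos", "start", "end",
                       "svtype", "svlen", "seq", "qual", "support_fraction")
    truth <- bind_cols(
      select(v, "variant_id", "class", "svtype", "svlen", "period", "motif",
             "element_name", "geography", "private_community",
             "ancestral_p", "weak"),
      as_tibble(freq[ord, , drop = FALSE]))
    truth$carriers <- map(seq_len(nrow(v)),
                          function(i) samples$sample_id[dosage[i, ] > 0])

    structure(list(
      callset = new_sv_callset(variants, samples, gt),
      truth = truth, samples = samples, config = config
    ), class = "sv_cohort")
  })
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("<sv_cohort> %d variants, %d samples, theta = %.2f\n",
              nrow(x$callset$variants), nrow(x$samples), x$config$theta))
  print(count(x$truth, .data$class))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf`, `metadata.tsv`, `truth.tsv` and `truth.json` into
#' `dir`.
#'
#' @param cohort An `sv_cohort`.
#' @param dir Output directory.
#' @param reference Optional `sv_reference` for anchor bases in the VCF.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- if (!is.null(reference)) reference$sequences else NULL
  write_sv_vcf(cohort$callset, file.path(dir, "cohort.vcf"),
               reference = seqs, seed = cohort$config$seed)
  write_sv_tsv(cohort$samples, file.path(dir, "metadata.tsv"),
               seed = cohort$config$seed)
  write_sv_tsv(cohort$truth, file.path(dir, "truth.tsv"),
               seed = cohort$config$seed)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Derive a jittered annotation set from planted truth
#'
#' Copies a fraction of the cohort's variants with breakpoint jitter and
#' multiplicative size noise; the remainder is omitted and is the expected
#' "unannotated" set for novelty labelling.
#'
#' @param variants Variants tibble (e.g. `cohort$callset$variants`).
#' @param keep_fraction Fraction of variants copied into the annotation set.
#' @param jitter_bp Maximum absolute breakpoint shift in bp.
#' @param size_noise Maximum relative size change (e.g. 0.3 for +/-30%).
#' @param seed Integer seed.
#' @return A tibble of annotation records (`annotation_id`, `source_id`,
#'   `chrom`, `pos`, `start`, `end`, `svtype`, `svlen`).
#' @export
make_annotation_set <- function(variants, keep_fraction = 1, jitter_bp = 0,
                                size_noise = 0, seed = 1L) {
  if (keep_fraction < 0 || keep_fraction > 1) {
    abort("keep_fraction must be in [0, 1]")
  }
  with_seed(seed, {
    n_keep <- round(keep_fraction * nrow(variants))
    if (n_keep == 0) {
      return(tibble(annotation_id = character(0), source_id = character(0),
                    chrom = character(0), pos = integer(0),
                    start = integer(0), end = integer(0),
                    svtype = character(0), svlen = integer(0)))
    }
    keep <- sort(sample.int(nrow(variants), n_keep))
    a <- variants[keep, , drop = FALSE]
    jit <- if (jitter_bp > 0) {
      as.integer(round(runif(n_keep, -jitter_bp, jitter_bp)))
    } else 0L
    scale <- if (size_noise > 0) {
      1 + runif(n_keep, -size_noise, size_noise)
    } else 1
    pos <- pmax(1L, a$pos + jit)
    svlen <- pmax(1L, as.integer(round(a$svlen * scale)))
    tibble(
      annotation_id = sprintf("ann%05d", seq_len(n_keep)),
      source_id = a$variant_id, chrom = a$chrom, pos = pos,
      start = pos, end = if_else(a$svtype == "DEL", pos + svlen, pos + 1L),
      svtype = a$svtype, svlen = svlen)
  })
}
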