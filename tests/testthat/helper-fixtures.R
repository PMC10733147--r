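# Shared fixtures (built once per test run) and brute-force oracles.

.fixture_env <- new.env(parent = emptyenv())

tiny_reference <- function() {
  if (is.null(.fixture_env$ref)) {
    .fixture_env$ref <- make_reference(
      chrom_lengths = c(chrA = 250000L, chrB = 250000L),
      n_str_arrays = 60L, n_tr_arrays = 40L, genes_per_decile = 4L,
      seed = 42L)
  }
  .fixture_env$ref
}

tiny_cohort <- function() {
  if (is.null(.fixture_env$coh)) {
    cfg <- sv_sim_config(
      samples_per_community = 6L, outgroup_size = 6L,
      n_variants_per_class = c(STR = 40L, TR = 25L, SINE_complete = 15L,
                               SINE_fragment = 10L, LINE_complete = 4L,
                               RETRO_complete = 8L, NONREP = 40L,
                               HOMO = 8L),
      seed = 42L)
    .fixture_env$coh <- simulate_cohort(tiny_reference(), cfg)
  }
  .fixture_env$coh
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force smallest period whose self-match fraction over a window
# reaches the purity threshold (oracle for the tandem detector's period)
bf_smallest_period <- function(seq, max_period = 20, min_purity = 0.8) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  for (p in seq_len(min(max_period, n - 1))) {
    m <- ch[(p + 1):n] == ch[1:(n - p)]
    if (mean(m) >= min_purity && n >= 2 * p) return(p)
  }
  NA_integer_
}

# brute-force reciprocal overlap of two variant rows
bf_reciprocal_overlap <- function(a, b, window = 200) {
  if (a$chrom != b$chrom || a$svtype != b$svtype) return(0)
  if (a$svtype == "DEL") {
    shared <- max(0, min(a$end, b$end) - max(a$start, b$start))
    return(min(shared / a$svlen, shared / b$svlen))
  }
  if (abs(a$pos - b$pos) <= window) {
    return(min(a$svlen, b$svlen) / max(a$svlen, b$svlen))
  }
  0
}

# brute-force interval intersection total per variant
bf_overlap_total <- function(v, intervals) {
  vs <- if (v$svtype == "DEL") v$start else v$start
  ve <- if (v$svtype == "DEL") v$end else v$start + 1
  tot <- 0L
  for (i in seq_len(nrow(intervals))) {
    if (intervals$chrom[i] != v$chrom) next
    tot <- tot + max(0, min(ve, intervals$end[i]) -
                       max(vs, intervals$start[i]))
  }
  tot
}

# random variants tibble on a toy genome
random_variants <- function(n, chroms = c(chrA = 100000L, chrB = 100000L),
                            types = c("INS", "DEL")) {
  chrom <- sample(names(chroms), n, replace = TRUE)
  svtype <- sample(types, n, replace = TRUE)
  svlen <- sample(20:2000, n, replace = TRUE)
  pos <- vapply(seq_len(n), function(i) {
    sample.int(chroms[[chrom[i]]] - svlen[i] - 100L, 1)
  }, integer(1))
  tibble::tibble(
    variant_id = sprintf("rv%04d", seq_len(n)), chrom = chrom,
    pos = pos, start = pos,
    end = ifelse(svtype == "DEL", pos + svlen, pos + 1L),
    svtype = svtype, svlen = svlen,
    qual = round(runif(n, 5, 60), 2))
}

# fold a planted-class label to the classifier's label vocabulary
coarse_class <- function(cl) {
  dplyr::case_when(
    cl %in% c("STR", "TR", "HOMO", "NONREP") ~ cl,
    grepl("^SINE", cl) ~ "SINE",
    grepl("^LINE", cl) ~ "LINE",
    grepl("^RETRO", cl) ~ "RETROPOSON",
    grepl("^LTR", cl) ~ "LTR",
    grepl("^DNA", cl) ~ "DNA",
    TRUE ~ cl)
}
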