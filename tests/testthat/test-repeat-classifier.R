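# Extended alleles, built-in detectors, classification rule, adapters.

test_that("extended alleles are 5x the variant with the variant central", {
  ref <- list(chrZ = random_dna_str(5000))
  names(ref) <- "chrZ"
  set.seed(1)
  ins <- list(chrom = "chrZ", start = 2000L, svtype = "INS", svlen = 100L,
              seq = random_dna_str(100))
  al <- build_extended_allele(ins, ref)
  expect_equal(nchar(al$sequence), 500L)
  expect_equal(c(al$variant_start, al$variant_end), c(200L, 300L))
  expect_false(al$clipped)
  expect_equal(substr(al$sequence, 201, 300), ins$seq)

  del <- list(chrom = "chrZ", start = 1000L, svtype = "DEL", svlen = 50L)
  al <- build_extended_allele(del, ref)
  expect_equal(al$sequence, substr(ref$chrZ, 1000 - 100 + 1, 1000 + 50 + 100))
  expect_equal(c(al$variant_start, al$variant_end), c(100L, 150L))

  edge <- list(chrom = "chrZ", start = 10L, svtype = "INS", svlen = 100L,
               seq = random_dna_str(100))
  al <- build_extended_allele(edge, ref)
  expect_true(al$clipped)
  expect_equal(al$variant_start, 10L)
  expect_equal(al$variant_end, 110L)
})

test_that("tandem detector finds planted arrays with the right period", {
  a <- find_tandem_repeats(strrep("A", 40))
  expect_equal(nrow(a), 1)
  expect_equal(a$period, 1L)
  expect_equal(a$copy_number, 40)

  cag <- find_tandem_repeats(strrep("CAG", 40))
  expect_equal(cag$period, 3L)
  expect_equal(cag$motif, "CAG")
  expect_equal(cag$purity, 1)

  unit <- "ACGTGTACCTTGA"  # 13-mer: TR range
  tr <- find_tandem_repeats(strrep(unit, 10))
  expect_equal(tr$period, 13L)
  expect_equal(bf_smallest_period(strrep(unit, 10)), 13L)

  expect_equal(nrow(find_tandem_repeats("")), 0)
})

test_that("detector period agrees with brute-force smallest period", {
  set.seed(17)
  for (rep in 1:25) {
    p <- sample(1:20, 1)
    unit <- random_dna_str(p)
    copies <- ceiling(60 / p) + 2
    s <- strrep(unit, copies)
    ann <- find_tandem_repeats(s)
    expect_gt(nrow(ann), 0)
    main <- ann[which.max(ann$end - ann$start), ]
    expect_equal(main$period, bf_smallest_period(s, max_period = 20))
  }
})

test_that("period classes split at the documented boundaries", {
  expect_equal(classify_period(c(1, 2, 12, 13, 300)),
               c("HOMO", "STR", "STR", "TR", "TR"))
  expect_error(classify_period(0), "period")
})

test_that("element matcher reports completeness fraction and orientation", {
  lib <- default_repeat_library()
  sine <- lib$elements$consensus[lib$elements$family == "SINE"]
  line <- lib$elements$consensus[lib$elements$family == "LINE"]
  set.seed(4)
  flank <- random_dna_str(150)

  full <- find_mobile_elements(paste0(flank, sine, flank), lib)
  expect_equal(nrow(full), 1)
  expect_gte(full$consensus_fraction, 0.99)
  expect_equal(full$orientation, "+")
  expect_equal(full$family, "SINE")

  L <- nchar(line)
  mid <- substr(line, round(0.3 * L), round(0.7 * L) - 1)
  frag <- find_mobile_elements(paste0(flank, mid, flank), lib)
  frag <- frag[frag$family == "LINE", ]
  expect_equal(nrow(frag), 1)
  expect_equal(frag$consensus_fraction, 0.4, tolerance = 0.02)

  rc <- find_mobile_elements(paste0(flank, revcomp(sine), flank), lib)
  expect_equal(rc$orientation, "-")
  expect_gte(rc$consensus_fraction, 0.99)
})

test_that("coverage fraction is union arithmetic on the variant region", {
  expect_equal(coverage_fraction(0, 100, integer(0), integer(0)), 0)
  expect_equal(coverage_fraction(0, 100, 0, 100), 1)
  expect_equal(coverage_fraction(0, 100, c(0, 20), c(30, 60)), 0.6)
  expect_error(coverage_fraction(50, 50, 0, 10), "zero-length")
})

test_that("classification rule follows coverage and completeness", {
  lib <- default_repeat_library()
  ref <- list(chrZ = random_dna_str(20000))
  set.seed(6)

  v_str <- list(chrom = "chrZ", start = 5000L, svtype = "INS",
                svlen = 150L, seq = strrep("CAG", 50))
  al <- build_extended_allele(v_str, ref)
  cls <- classify_variant(al, find_tandem_repeats(al$sequence),
                          find_mobile_elements(al$sequence, lib))
  expect_equal(cls$label, "STR")
  expect_equal(cls$coverage, 1)
  expect_equal(cls$me_completeness, "n/a")

  sine <- lib$elements$consensus[lib$elements$family == "SINE"]
  v_sine <- list(chrom = "chrZ", start = 9000L, svtype = "INS",
                 svlen = nchar(sine) + 20L,
                 seq = paste0(random_dna_str(10), sine, random_dna_str(10)))
  al <- build_extended_allele(v_sine, ref)
  cls <- classify_variant(al, find_tandem_repeats(al$sequence),
                          find_mobile_elements(al$sequence, lib))
  expect_equal(cls$label, "SINE")
  expect_equal(cls$me_completeness, "complete")

  v_non <- list(chrom = "chrZ", start = 12000L, svtype = "INS",
                svlen = 200L, seq = random_dna_str(200))
  al <- build_extended_allele(v_non, ref)
  cls <- classify_variant(al, find_tandem_repeats(al$sequence),
                          find_mobile_elements(al$sequence, lib))
  expect_equal(cls$label, "NONREP")
})

test_that("classification is strand symmetric for insertions", {
  lib <- default_repeat_library()
  ref <- list(chrZ = random_dna_str(20000))
  set.seed(8)
  seqs <- list(strrep("CAG", 40),
               lib$elements$consensus[2],
               random_dna_str(150))
  for (s in seqs) {
    for (variant_seq in c(s, revcomp(s))) {
      v <- list(chrom = "chrZ", start = 8000L, svtype = "INS",
                svlen = nchar(variant_seq), seq = variant_seq)
      al <- build_extended_allele(v, ref)
      cls <- classify_variant(al, find_tandem_repeats(al$sequence),
                              find_mobile_elements(al$sequence, lib))
      if (variant_seq == s) fwd <- cls$label else {
        expect_equal(cls$label, fwd)
      }
    }
  }
})

test_that("homopolymer flagging excludes HOMO and keeps the rest", {
  cls <- tibble::tibble(variant_id = sprintf("v%d", 1:10),
                        label = c(rep("HOMO", 3), rep("STR", 4),
                                  rep("NONREP", 3)))
  fl <- flag_homopolymers(cls)
  expect_equal(sum(fl$excluded), 3)
  expect_equal(sum(!fl$excluded), 10 - 3)
  expect_true(all(!fl$excluded[fl$label == "STR"]))
})

test_that("TRF .dat adapter maps fields and skips malformed lines", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "Tandem Repeats Finder Program",
    "",
    "Sequence: var001",
    "Parameters: 2 7 7 80 10 50 500",
    "",
    "1 120 3 40.0 3 95 0 160 20 30 25 25 1.97 CAG CAGCAGCAG",
    "oops not a data line",
    "5 64 garbage 2 2 2 2 2 2 2 2 2 2 X Y"
  ), path)
  expect_warning(ann <- parse_trf_dat(path), "malformed")
  expect_equal(nrow(ann), 1)
  expect_equal(ann$sequence_name, "var001")
  expect_equal(ann$start, 0L)
  expect_equal(ann$end, 120L)
  expect_equal(ann$period, 3L)
  expect_equal(ann$motif, "CAG")
  expect_equal(ann$purity, 0.95)

  empty <- withr::local_tempfile(fileext = ".dat")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_trf_dat(empty)), 0)
})

test_that("RepeatMasker .out adapter maps families and strands", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat      position in repeat",
    "score  div. del. ins.  sequence  begin end   (left)   repeat   class/family  begin end (left)  ID",
    "",
    " 1500  10.0  0.1  0.2  var002     101  380  (120)  +  AluY     SINE/Alu        1  280  (0)    1",
    " 1200  12.0  0.1  0.2  var003      51  200  (300)  C  L1MA     LINE/L1      (5800) 150    1    2",
    "  800  12.0  0.1  0.2  var004      10  100  (400)  +  Oddball  Weird/Thing     1   91  (10)   3"
  ), path)
  ann <- parse_repeatmasker_out(path)
  expect_equal(nrow(ann), 3)
  expect_equal(ann$family, c("SINE", "LINE", "Other"))
  expect_equal(ann$orientation, c("+", "-", "+"))
  expect_equal(ann$start[1], 100L)
  expect_equal(ann$end[1], 380L)
  expect_equal(ann$consensus_fraction[1], 1)
  expect_equal(ann$consensus_length[2], 5950L)

  empty <- withr::local_tempfile(fileext = ".out")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_repeatmasker_out(empty)), 0)
})

test_that("externally parsed annotations can replace built-in detectors", {
  ref <- list(chrZ = random_dna_str(5000))
  v <- tibble::tibble(variant_id = "v1", chrom = "chrZ", pos = 2000L,
                      start = 2000L, end = 2001L, svtype = "INS",
                      svlen = 90L, seq = strrep("CAG", 30))
  tand <- tibble::tibble(variant_id = "v1", start = 150L, end = 300L,
                         period = 3L, motif = "CAG", copy_number = 50,
                         purity = 1, score = 300)
  cls <- classify_variants(v, ref, tandem_annotations = tand,
                           element_annotations = tibble::tibble(
                             variant_id = character(0), start = integer(0),
                             end = integer(0), element_name = character(0),
                             family = character(0),
                             orientation = character(0),
                             identity = numeric(0),
                             consensus_fraction = numeric(0),
                             consensus_length = integer(0)))
  expect_equal(cls$label, "STR")
})
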