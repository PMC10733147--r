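# Synthetic reference genome with planted repeat features and gene models.
#
# The generator emulates the statistical structure the downstream analyses
# assume: a random-base backbone carrying pure tandem-repeat arrays (STR and
# TR), full mobile-element consensus copies, and protein-coding gene models
# spread over ten LOEUF deciles. Planted repeats are mismatch-free by
# default so the built-in detectors act as exact oracles.

# evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Default mobile-element and tandem-repeat library
#'
#' A fixed synthetic library whose element lengths track the canonical human
#' families: a SINE-like element of 280 bp (the Alu length scale), a
#' LINE-like element of 6 kb (L1 scale), a retroposon-like element of 2 kb
#' (SVA scale), plus LTR-like and DNA-transposon-like elements. STR motifs
#' cover periods 2-6 and TR units periods 13-48. Content is deterministic
#' (internally seeded) and independent of the caller's RNG.
#'
#' @return A list with `elements` (tibble: `name`, `family`, `consensus`),
#'   `str_motifs` and `tr_units` (character vectors).
#' @export
default_repeat_library <- function() {
  with_seed(8675309L, {
    elements <- tibble(
      name = c("SINE1_syn", "LINE1_syn", "RETRO1_syn", "LTR1_syn", "DNA1_syn"),
      family = c("SINE", "LINE", "Retroposon", "LTR", "DNA"),
      length = c(280L, 6000L, 2000L, 500L, 800L)
    )
    elements$consensus <- vapply(elements$length, random_dna, character(1))
    tr_units <- vapply(c(13L, 17L, 22L, 28L, 35L, 48L), random_dna,
                       character(1))
    list(
      elements = select(elements, -"length"),
      str_motifs = c("AC", "AT", "CAG", "GAA", "AGAT", "AATGC", "ACGGTC"),
      tr_units = tr_units
    )
  })
}

place_intervals <- function(chrom_lengths, lengths, occupied, margin = 200L,
                            region = NULL, max_tries = 500L) {
  # sequential rejection sampling of non-overlapping intervals
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(names(chrom_lengths), 1)
      L <- chrom_lengths[[chrom]]
      if (len + 2L * margin >= L) {
        abort(sprintf("planted feature of %d bp exceeds chromosome %s (%d bp)",
                      len, chrom, L))
      }
      if (!is.null(region)) {
        # restrict to the two chromosome-end regions of given width
        w <- min(region, floor((L - len) / 2))
        s <- if (runif(1) < 0.5) sample.int(w, 1) + margin
             else L - w - len - margin + sample.int(w, 1)
      } else {
        s <- sample.int(L - len - 2L * margin, 1) + margin
      }
      e <- s + len
      occ <- occupied[[chrom]]
      clash <- any(occ$start < e + margin & occ$end > s - margin)
      if (!clash) {
        occupied[[chrom]] <- rbind(occ, data.frame(start = s, end = e))
        out[[i]] <- data.frame(chrom = chrom, start = s, end = e)
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not place planted feature; genome too crowded")
  }
  list(intervals = bind_rows(out), occupied = occupied)
}

#' Generate a synthetic reference genome with planted features
#'
#' Builds a random-base backbone, plants pure STR and TR arrays, full
#' mobile-element consensus copies and gene models, and records every
#' planted feature in truth tables. Deterministic for a fixed seed.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (each at
#'   least 200 kb; at least two chromosomes).
#' @param library Repeat library, see [default_repeat_library()].
#' @param n_str_arrays,n_tr_arrays Number of planted tandem arrays.
#' @param str_copies,tr_copies Integer range (length-2) of copy numbers per
#'   array.
#' @param n_element_copies Full consensus copies planted per element.
#' @param genes_per_decile Genes per LOEUF decile (deciles 1-10).
#' @param telomere_frac Fraction of each chromosome end counted as the
#'   telomere-proximal region (scaled analogue of the ~5 Mb window on a
#'   full-size chromosome).
#' @param tr_telomere_frac Fraction of TR arrays placed inside the
#'   telomere-proximal regions, so that telomere-enriched cohorts can draw
#'   TR variants there.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An `sv_reference`: list with `sequences` (named character vector),
#'   `chrom_lengths`, truth tibbles `str_arrays`, `tr_arrays`, `elements`
#'   (all 0-based half-open), `genes`, `telomere_region_bp` and `seed`.
#' @export
make_reference <- function(chrom_lengths = c(chrA = 600000L, chrB = 600000L),
                           library = default_repeat_library(),
                           n_str_arrays = 300L, n_tr_arrays = 200L,
                           str_copies = c(15L, 40L), tr_copies = c(5L, 15L),
                           n_element_copies = 2L, genes_per_decile = 4L,
                           telomere_frac = 0.1, tr_telomere_frac = 0.5,
                           seed = 1L) {
  if (length(chrom_lengths) < 2) abort("need at least 2 chromosomes")
  if (any(chrom_lengths < 200000L)) abort("chromosomes must be >= 200 kb")
  chrom_lengths <- vapply(chrom_lengths, as.integer, integer(1))

  with_seed(seed, {
    seqs <- vapply(chrom_lengths, random_dna, character(1))
    occupied <- lapply(chrom_lengths,
                       function(...) data.frame(start = integer(0),
                                                end = integer(0)))

    # STR arrays
    str_motif <- sample(library$str_motifs, n_str_arrays, replace = TRUE)
    str_n <- sample(seq(str_copies[1], str_copies[2]), n_str_arrays,
                    replace = TRUE)
    pl <- place_intervals(chrom_lengths, nchar(str_motif) * str_n, occupied)
    occupied <- pl$occupied
    str_arrays <- mutate(pl$intervals, motif = str_motif,
                         period = nchar(str_motif), copies = str_n,
                         array_id = sprintf("str%04d", row_number()))

    # TR arrays: a configurable share goes to chromosome-end regions
    tel_bp <- as.integer(round(telomere_frac * min(chrom_lengths)))
    tr_unit <- sample(library$tr_units, n_tr_arrays, replace = TRUE)
    tr_n <- sample(seq(tr_copies[1], tr_copies[2]), n_tr_arrays,
                   replace = TRUE)
    n_tel <- round(tr_telomere_frac * n_tr_arrays)
    tr_lens <- nchar(tr_unit) * tr_n
    pl1 <- place_intervals(chrom_lengths, tr_lens[seq_len(n_tel)], occupied,
                           region = tel_bp)
    pl2 <- place_intervals(chrom_lengths,
                           tr_lens[seq_len(n_tr_arrays) > n_tel],
                           pl1$occupied)
    occupied <- pl2$occupied
    tr_arrays <- mutate(bind_rows(pl1$intervals, pl2$intervals),
                        motif = tr_unit, period = nchar(tr_unit),
                        copies = tr_n,
                        array_id = sprintf("tr%04d", row_number()))

    # full element copies
    el_idx <- rep(seq_len(nrow(library$elements)), each = n_element_copies)
    el_len <- nchar(library$elements$consensus)[el_idx]
    pl <- place_intervals(chrom_lengths, el_len, occupied)
    occupied <- pl$occupied
    elements <- mutate(pl$intervals,
                       name = library$elements$name[el_idx],
                       family = library$elements$family[el_idx])

    # overwrite backbone with planted sequences
    plant <- function(seqs, tab, planted_seq) {
      for (i in seq_len(nrow(tab))) {
        ch <- tab$chrom[i]
        substr(seqs[[ch]], tab$start[i] + 1L, tab$end[i]) <- planted_seq[i]
      }
      seqs
    }
    seqs <- plant(seqs, str_arrays, strrep(str_arrays$motif,
                                           str_arrays$copies))
    seqs <- plant(seqs, tr_arrays, strrep(tr_arrays$motif, tr_arrays$copies))
    cons <- setNames(library$elements$consensus, library$elements$name)
    seqs <- plant(seqs, elements, cons[elements$name])

    # gene models across LOEUF deciles; genes avoid each other (not the
    # repeat arrays: intronic/flanking repeats are realistic)
    n_genes <- 10L * genes_per_decile
    span_len <- sample(3000:8000, n_genes, replace = TRUE)
    gene_occ <- lapply(chrom_lengths,
                       function(...) data.frame(start = integer(0),
                                                end = integer(0)))
    pl <- place_intervals(chrom_lengths, span_len, gene_occ, margin = 2500L)
    genes <- pl$intervals
    genes$gene_id <- sprintf("gene%03d", seq_len(n_genes))
    genes$loeuf_decile <- rep(1:10, each = genes_per_decile)
    genes$cds <- lapply(seq_len(n_genes), function(i) {
      n_ex <- sample(2:5, 1)
      width <- genes$end[i] - genes$start[i]
      # non-overlapping exons of 100-400 bp inside the span
      ex_w <- sample(100:400, n_ex, replace = TRUE)
      gaps <- width - sum(ex_w)
      offs <- sort(sample.int(max(gaps, n_ex), n_ex))
      st <- genes$start[i] + offs + c(0L, cumsum(ex_w))[seq_len(n_ex)]
      data.frame(start = st, end = st + ex_w)
    })
    genes <- select(as_tibble(genes), "gene_id", "chrom", "start", "end",
                    "cds", "loeuf_decile")

    structure(list(
      sequences = seqs, chrom_lengths = chrom_lengths,
      str_arrays = as_tibble(str_arrays), tr_arrays = as_tibble(tr_arrays),
      elements = as_tibble(elements), genes = genes,
      telomere_region_bp = tel_bp, library = library, seed = as.integer(seed)
    ), class = "sv_reference")
  })
}

#' @export
print.sv_reference <- function(x, ...) {
  cat(sprintf(
    "<sv_reference> %d chromosome(s), %s bp; %d STR + %d TR arrays, %d element copies, %d genes\n",
    length(x$sequences), format(sum(x$chrom_lengths), big.mark = ","),
    nrow(x$str_arrays), nrow(x$tr_arrays), nrow(x$elements), nrow(x$genes)))
  invisible(x)
}

#' Write / read a synthetic reference
#'
#' `write_reference()` emits `reference.fa`, truth BED-like TSVs for the
#' planted arrays and elements, and the gene-model TSV into `dir`.
#' `read_reference_fasta()` reads any FASTA into the named-character form
#' the classifier consumes.
#'
#' @param ref An `sv_reference`.
#' @param dir Output directory (created if needed).
#' @return The directory (or named character vector of sequences), invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(ref$sequences)
  Biostrings::writeXStringSet(dna, file.path(dir, "reference.fa"))
  write_sv_tsv(ref$str_arrays, file.path(dir, "str_arrays.tsv"),
               seed = ref$seed)
  write_sv_tsv(ref$tr_arrays, file.path(dir, "tr_arrays.tsv"),
               seed = ref$seed)
  write_sv_tsv(ref$elements, file.path(dir, "elements.tsv"), seed = ref$seed)
  write_gene_models(ref$genes, file.path(dir, "genes.tsv"), seed = ref$seed)
  invisible(dir)
}

#' @rdname write_reference
#' @param path Path to a FASTA file.
#' @export
read_reference_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- as.character(dna)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Simulate variant positions with a constraint gradient across deciles
#'
#' Places insertion variants into the CDS regions of genes so that the
#' size-normalized variant density in each LOEUF decile is proportional to
#' `fold[decile]`. Used to test recovery of planted depletion gradients.
#'
#' @param genes Gene-model tibble (with `cds` list-column and
#'   `loeuf_decile`).
#' @param n Total number of variants to place.
#' @param fold Numeric vector of length 10: relative density per decile
#'   (e.g. `c(1/12, rep(1, 9))` plants a 12-fold depletion in decile 1).
#' @param svlen Length given to each planted insertion.
#' @param seed Integer seed.
#' @return A variants tibble suitable for [partition_hits()].
#' @export
simulate_decile_variants <- function(genes, n = 2000L,
                                     fold = rep(1, 10), svlen = 50L,
                                     seed = 1L) {
  stopifnot(length(fold) == 10)
  with_seed(seed, {
    cds_by_gene <- map2(genes$cds, genes$chrom, function(b, ch) {
      mutate(as_tibble(b), chrom = ch)
    })
    cds <- bind_rows(cds_by_gene)
    cds$decile <- rep(genes$loeuf_decile,
                      vapply(genes$cds, nrow, integer(1)))
    cds$width <- cds$end - cds$start
    cds$weight <- fold[cds$decile] * cds$width
    pick <- sample.int(nrow(cds), n, replace = TRUE,
                       prob = cds$weight / sum(cds$weight))
    pos <- cds$start[pick] + floor(runif(n) * cds$width[pick])
    tibble(
      variant_id = sprintf("cv%05d", seq_len(n)),
      chrom = cds$chrom[pick], pos = as.integer(pos),
      start = as.integer(pos), end = as.integer(pos) + 1L,
      svtype = "INS", svlen = as.integer(svlen)
    )
  })
}
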