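# Standard-format I/O: SV VCFs, sample metadata, gene models, matrices.
#
# Internal coordinate convention is 0-based half-open. A deletion at VCF
# POS p (anchor base) removes reference bases occupying [p, p + svlen); an
# insertion is anchored at the zero-width point after the anchor base and is
# represented by the single-base interval [p, p + 1) for genomic
# intersections. VCF readers/writers convert between the two conventions.

new_sv_callset <- function(variants, samples, gt) {
  structure(list(variants = variants, samples = samples, gt = gt),
            class = "sv_callset")
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("<sv_callset> %d variants x %d samples\n",
              nrow(x$variants), nrow(x$samples)))
  cat(sprintf("  svtype: %s\n",
              paste(sprintf("%s=%d", names(table(x$variants$svtype)),
                            table(x$variants$svtype)), collapse = ", ")))
  invisible(x)
}

#' Read sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `community` and
#' `in_focal_set` (logical; the study-cohort analogue of a focal group
#' versus an outgroup).
#'
#' @param path Path to a tab-separated metadata file.
#' @return A tibble with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- read_sv_tsv(path)
  stopifnot_cols(md, c("sample_id", "community", "in_focal_set"), "metadata")
  md$sample_id <- as.character(md$sample_id)
  md$in_focal_set <- as.logical(md$in_focal_set)
  md
}

#' Read an SV/indel VCF into a callset
#'
#' Parses insertion/deletion records from a VCF 4.2 file. Both
#' sequence-resolved records (`REF`/`ALT` carry the variant sequence) and
#' symbolic records (`<INS>`/`<DEL>` with `SVLEN` and, optionally, a `SEQ`
#' INFO key) are supported. Records without a recoverable `SVLEN` are dropped
#' with a warning.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sample_metadata Optional tibble as returned by
#'   [read_sample_metadata()]. Every genotyped sample in the VCF must appear
#'   in it; unknown sample ids are an error. When `NULL`, samples get
#'   placeholder metadata (community `"unknown"`, not focal).
#' @return An `sv_callset`: a list with `variants` (tibble: `variant_id`,
#'   `chrom`, `pos` (1-based anchor), `start`/`end` (0-based half-open
#'   interval used for intersections), `svtype`, `svlen`, `seq`, `qual`,
#'   `support_fraction`), `samples` (tibble) and `gt` (character matrix of
#'   genotypes, variants x samples).
#' @export
read_sv_vcf <- function(path, sample_metadata = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
                                         stringsAsFactors = FALSE))
  info_get <- function(key) suppressWarnings(
    vcfR::extract.info(vcf, element = key))

  svtype <- info_get("SVTYPE")
  svlen_raw <- suppressWarnings(as.numeric(info_get("SVLEN")))
  seq_info <- info_get("SEQ")
  support <- suppressWarnings(as.numeric(info_get("SUPPORT")))

  ref <- fix$REF
  alt <- fix$ALT
  symbolic <- grepl("^<", alt)
  # infer type from allele lengths when SVTYPE is absent
  inferred <- ifelse(nchar(alt) > nchar(ref), "INS", "DEL")
  svtype <- ifelse(is.na(svtype) | svtype == "",
                   ifelse(symbolic, gsub("[<>]", "", alt), inferred), svtype)
  svlen <- abs(svlen_raw)
  seq_resolved_len <- ifelse(symbolic, NA_real_,
                             abs(nchar(alt) - nchar(ref)))
  svlen <- ifelse(is.na(svlen), seq_resolved_len, svlen)

  seq <- seq_info
  no_seq <- is.na(seq) | seq == ""
  seq[no_seq & !symbolic & svtype == "INS"] <-
    substr(alt[no_seq & !symbolic & svtype == "INS"], 2L, 1e9L)
  seq[no_seq & !symbolic & svtype == "DEL"] <-
    substr(ref[no_seq & !symbolic & svtype == "DEL"], 2L, 1e9L)

  pos <- as.integer(fix$POS)
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  id <- fix$ID
  id[is.na(id) | id == "."] <- sprintf("var%06d", which(is.na(id) | id == "."))

  keep <- !is.na(svlen) & svtype %in% c("INS", "DEL")
  if (any(!keep)) {
    warn(sprintf("dropping %d record(s) without SVLEN or with unsupported type",
                 sum(!keep)))
  }

  variants <- tibble(
    variant_id = id, chrom = fix$CHROM, pos = pos,
    svtype = svtype, svlen = as.integer(round(svlen)), seq = seq,
    qual = qual, support_fraction = support
  )[keep, , drop = FALSE]
  variants <- mutate(variants,
    start = .data$pos,
    end = if_else(.data$svtype == "DEL",
                  .data$pos + .data$svlen, .data$pos + 1L))

  gt <- if (ncol(vcf@gt) >= 2) vcfR::extract.gt(vcf, element = "GT") else NULL
  if (is.null(gt)) {
    gt <- matrix(character(0), nrow = nrow(variants), ncol = 0)
    sample_ids <- character(0)
  } else {
    gt <- gt[keep, , drop = FALSE]
    sample_ids <- colnames(gt)
  }
  rownames(gt) <- variants$variant_id

  if (is.null(sample_metadata)) {
    samples <- tibble(sample_id = sample_ids, community = "unknown",
                      in_focal_set = FALSE)
  } else {
    unknown <- setdiff(sample_ids, sample_metadata$sample_id)
    if (length(unknown) > 0) {
      abort(sprintf("VCF sample(s) missing from metadata: %s",
                    paste(unknown, collapse = ", ")))
    }
    samples <- left_join(tibble(sample_id = sample_ids), sample_metadata,
                         by = "sample_id")
  }
  new_sv_callset(variants, samples, gt)
}

#' Write a callset as a VCF
#'
#' Emits sequence-resolved VCF 4.2 records. The anchor base is taken from
#' `reference` when supplied, otherwise `N` is used. `SVTYPE`, `SVLEN`
#' (negative for deletions), `END` and `SUPPORT` INFO keys are written, plus
#' per-sample `GT`.
#'
#' @param callset An `sv_callset`, or a variants tibble (then `gt` may be
#'   supplied separately).
#' @param path Output path.
#' @param reference Optional named character vector of chromosome sequences.
#' @param seed Optional integer recorded in the header for provenance.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(callset, path, reference = NULL, seed = NULL) {
  v <- callset$variants
  gt <- callset$gt
  samples <- callset$samples$sample_id
  anchor <- rep("N", nrow(v))
  if (!is.null(reference)) {
    anchor <- substr(reference[v$chrom], v$pos, v$pos)
    anchor[is.na(anchor) | anchor == ""] <- "N"
  }
  ref_col <- ifelse(v$svtype == "DEL", paste0(anchor, v$seq), anchor)
  alt_col <- ifelse(v$svtype == "INS", paste0(anchor, v$seq), anchor)
  info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;SUPPORT=%s",
                  v$svtype,
                  ifelse(v$svtype == "DEL", -v$svlen, v$svlen),
                  ifelse(v$svtype == "DEL", v$pos + v$svlen, v$pos),
                  ifelse(is.na(v$support_fraction), ".",
                         format(v$support_fraction, digits = 4)))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=svscape_%s", utils::packageVersion("svscape")),
    if (!is.null(seed)) sprintf("##svscape_seed=%d", as.integer(seed)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Float,Description=\"Fraction of reads supporting ALT\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples) > 0) c("FORMAT", samples)), collapse = "\t")
  )
  body <- cbind(v$chrom, v$pos, v$variant_id, ref_col, alt_col,
                ifelse(is.na(v$qual), ".", format(v$qual, digits = 6)),
                "PASS", info)
  if (length(samples) > 0) body <- cbind(body, "GT", gt)
  lines <- apply(body, 1, paste, collapse = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read/write gene models
#'
#' Gene models are stored one gene per line: `gene_id`, `chrom`, `start`,
#' `end` (gene span, 0-based half-open), `cds_blocks` (comma-separated
#' `start-end` pairs) and `loeuf_decile` (1 = most constrained, 10 = least).
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `cds` list-column of `start`/`end` data frames.
#' @export
read_gene_models <- function(path) {
  g <- read_sv_tsv(path)
  stopifnot_cols(g, c("gene_id", "chrom", "start", "end", "cds_blocks",
                      "loeuf_decile"), "gene models")
  g$cds <- lapply(strsplit(as.character(g$cds_blocks), ",", fixed = TRUE),
                  function(b) {
    parts <- do.call(rbind, strsplit(b, "-", fixed = TRUE))
    data.frame(start = as.integer(parts[, 1]), end = as.integer(parts[, 2]))
  })
  select(g, -"cds_blocks")
}

#' @rdname read_gene_models
#' @param genes Gene-model tibble with a `cds` list-column.
#' @param seed Optional integer recorded in the file header.
#' @export
write_gene_models <- function(genes, path, seed = NULL) {
  out <- mutate(genes, cds_blocks = map_chr(.data$cds, function(b) {
    paste(sprintf("%d-%d", b$start, b$end), collapse = ",")
  }))
  out <- select(out, "gene_id", "chrom", "start", "end", "cds_blocks",
                "loeuf_decile")
  write_sv_tsv(out, path, seed = seed)
}

#' Write/read a genotype matrix as TSV
#'
#' Dosages (0/1/2, `NA` for missing) with variant ids as the first column and
#' one column per sample. The reader reconstructs an `sv_genotypes` object;
#' community metadata can be re-attached via `samples`.
#'
#' @param geno An `sv_genotypes` object.
#' @param path Output path.
#' @param seed Optional integer recorded in the header.
#' @export
write_genotype_tsv <- function(geno, path, seed = NULL) {
  df <- as.data.frame(geno$dosage)
  df <- cbind(variant_id = geno$variant_ids, df)
  write_sv_tsv(tibble::as_tibble(df), path, seed = seed)
}

#' @rdname write_genotype_tsv
#' @param samples Optional sample metadata tibble to re-attach.
#' @export
read_genotype_tsv <- function(path, samples = NULL) {
  df <- read_sv_tsv(path)
  dosage <- as.matrix(df[, -1, drop = FALSE])
  rownames(dosage) <- df$variant_id
  if (is.null(samples)) {
    samples <- tibble(sample_id = colnames(dosage), community = "unknown",
                      in_focal_set = FALSE)
  }
  new_sv_genotypes(dosage, samples)
}
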