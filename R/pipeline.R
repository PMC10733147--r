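# End-to-end pipeline driver: filter -> classify -> landscape -> novelty ->
# constraint -> STR -> popstruct, with provenance-stamped outputs.

#' Pipeline configuration
#'
#' Collects input paths and every analysis threshold with its default:
#' QUAL >= 5, deletion support >= 0.20, insertion support >= 0.05, minimum
#' size 20 bp, classification coverage 0.75, complete-element fraction
#' 0.75, reciprocal-overlap novelty bands 0.5/0.8, breakpoint window 200
#' bp, CNV p-value 1e-4, telomere bin 500 kb, gene pad 2 kb, STR expansion
#' criteria (period >= 3, >= 10 units, >= 50% of reference, reference
#' < 1 kb), FST subset of 10,000 loci above 10% frequency.
#'
#' @param vcf,fasta,genes,metadata Input paths (required).
#' @param annotation Optional annotation VCF for novelty labelling.
#' @param cnv_calls Optional per-sample CNV call TSV.
#' @param out_dir Output directory.
#' @param seed Integer seed used for every stochastic step.
#' @param min_qual,min_del_support,min_ins_support,min_svlen Filter
#'   thresholds.
#' @param min_coverage,complete_threshold Classifier thresholds.
#' @param ro_moderate,ro_high Novelty bands.
#' @param breakpoint_window Breakpoint proximity window (bp).
#' @param cnv_p_max CNV p-value cutoff.
#' @param telomere_bin Telomere-distance bin size (bp).
#' @param gene_pad Non-CDS flanking pad (bp).
#' @param fst_n_loci,fst_min_freq FST locus subset parameters.
#' @param n_permutations Discovery-curve permutations.
#' @return An `sv_pipeline_config` list.
#' @export
sv_pipeline_config <- function(vcf, fasta, genes, metadata,
                               annotation = NULL, cnv_calls = NULL,
                               out_dir = "svscape_out", seed = 1L,
                               min_qual = 5, min_del_support = 0.20,
                               min_ins_support = 0.05, min_svlen = 20L,
                               min_coverage = 0.75,
                               complete_threshold = 0.75,
                               ro_moderate = 0.5, ro_high = 0.8,
                               breakpoint_window = 200L,
                               cnv_p_max = 1e-4, telomere_bin = 500000L,
                               gene_pad = 2000L, fst_n_loci = 10000L,
                               fst_min_freq = 0.10,
                               n_permutations = 10L) {
  structure(as.list(environment()), class = "sv_pipeline_config")
}

#' Run the full pipeline
#'
#' Executes every stage on the configured inputs and writes a per-variant
#' master TSV, a summary JSON, a provenance JSON (the echoed configuration
#' plus its hash) and a plain-text log into `config$out_dir`. Output is
#' deterministic for a fixed seed. On stage failure, partial outputs are
#' removed and an error naming the stage is raised.
#'
#' @param config An [sv_pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_files <- file.path(config$out_dir,
                         c("variants.tsv", "summary.json", "config.json",
                           "pipeline.log"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(paste0("INFO ", fmt), ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(out_files)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  res <- list()
  stage("load", {
    reference <- read_reference_fasta(config$fasta)
    genes <- read_gene_models(config$genes)
    metadata <- read_sample_metadata(config$metadata)
    callset <- read_sv_vcf(config$vcf, metadata)
    say("loaded %d variants, %d samples, %d genes",
        nrow(callset$variants), nrow(callset$samples), nrow(genes))
    res$reference <- reference; res$genes <- genes
    res$callset <- callset
  })

  stage("filter", {
    n0 <- nrow(res$callset$variants)
    res$callset <- filter_variants(
      res$callset, min_qual = config$min_qual,
      min_del_support = config$min_del_support,
      min_ins_support = config$min_ins_support,
      min_svlen = config$min_svlen)
    say("filter retained %d / %d variants", nrow(res$callset$variants), n0)
  })

  stage("classify", {
    res$classification <- classify_variants(
      res$callset$variants, res$reference,
      min_coverage = config$min_coverage,
      complete_threshold = config$complete_threshold) |>
      flag_homopolymers()
    n_homo <- sum(res$classification$excluded)
    say("classified %d variants (%d homopolymers excluded)",
        nrow(res$classification), n_homo)
    keep <- res$classification$variant_id[!res$classification$excluded]
    res$analysis <- filter_variants(res$callset)  # idempotent; keeps shape
    sel <- res$analysis$variants$variant_id %in% keep
    res$analysis <- new_sv_callset(res$analysis$variants[sel, ],
                                   res$analysis$samples,
                                   res$analysis$gt[sel, , drop = FALSE])
  })

  stage("landscape", {
    res$geno <- build_genotype_matrix(res$analysis)
    res$labels <- label_variants(res$geno)
    say("labels: %s", paste(sprintf("%s=%d",
        names(table(res$labels$sharedness)),
        table(res$labels$sharedness)), collapse = ", "))
    res$discovery <- discovery_curve(res$geno,
                                     n_permutations = config$n_permutations,
                                     seed = derive_seed(config$seed, 1L))
    chrom_lengths <- setNames(nchar(res$reference), names(res$reference))
    cls <- left_join(res$analysis$variants,
                     select(res$classification, "variant_id", "label"),
                     by = "variant_id")
    res$telomere <- telomere_density(cls, chrom_lengths,
                                     bin = config$telomere_bin,
                                     by = "label", smooth = FALSE)
  })

  stage("novelty", {
    if (!is.null(config$annotation)) {
      ann <- read_sv_vcf(config$annotation)$variants
      res$novelty <- novelty_label(res$analysis$variants, ann,
                                   window = config$breakpoint_window)
      say("novelty: %d / %d annotated", sum(res$novelty$annotated),
          nrow(res$novelty))
    }
  })

  stage("constraint", {
    res$partition <- partition_hits(res$analysis$variants, res$genes,
                                    pad = config$gene_pad)
    res$densities <- decile_density(res$partition, res$genes,
                                    pad = config$gene_pad)
    say("constraint: %d CDS, %d non-CDS, %d intergenic variants",
        sum(res$partition$region_class == "CDS"),
        sum(res$partition$region_class == "NONCDS"),
        sum(res$partition$region_class == "INTERGENIC"))
  })

  stage("str", {
    str_cls <- filter(res$classification, .data$label == "STR")
    str_v <- res$analysis$variants |>
      filter(.data$variant_id %in% str_cls$variant_id) |>
      left_join(select(str_cls, "variant_id", "period", "motif"),
                by = "variant_id") |>
      left_join(res$partition, by = "variant_id")
    res$str_tables <- motif_and_period_tables(str_v)
    exp_v <- filter(str_v, .data$svtype == "INS", .data$period >= 2)
    if (nrow(exp_v) > 0) {
      ref_len <- map_int(seq_len(nrow(exp_v)), function(i) {
        str_reference_length(exp_v[i, ], res$reference, exp_v$period[i])
      })
      exp_v$reference_length <- ref_len
      exp_v$significant_expansion <- is_significant_expansion(
        exp_v$period, ref_len, exp_v$svlen)
      say("STR expansions: %d significant of %d",
          sum(exp_v$significant_expansion), nrow(exp_v))
    }
    res$str_expansions <- exp_v
  })

  stage("popstruct", {
    d <- bray_curtis(res$geno)
    res$pcoa <- sv_pcoa(d, res$geno$samples)
    loci <- suppressWarnings(subset_common_svs(
      res$geno, min_freq = config$fst_min_freq, n = config$fst_n_loci,
      seed = derive_seed(config$seed, 2L)))
    res$fst <- wc_fst(res$geno, loci = loci)
    say("popstruct: PCoA1 %.1f%%, %d FST pairs on %d loci",
        res$pcoa$percent_variance[1], nrow(res$fst), length(loci))
  })

  stage("cnv", {
    if (!is.null(config$cnv_calls)) {
      calls <- read_sv_tsv(config$cnv_calls)
      res$cnv_regions <- merge_cnv_regions(calls, res$callset$samples,
                                           p_max = config$cnv_p_max,
                                           genes = res$genes)
      say("CNV: %d merged regions", nrow(res$cnv_regions))
    }
  })

  stage("write", {
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, out_files[3], auto_unbox = TRUE,
                         digits = NA, null = "null")
    cfg_hash <- unname(tools::md5sum(out_files[3]))

    master <- res$analysis$variants |>
      left_join(select(res$classification, -"clipped"),
                by = "variant_id") |>
      left_join(res$labels, by = "variant_id") |>
      left_join(res$partition, by = "variant_id")
    if (!is.null(res$novelty)) {
      master <- left_join(master,
                          select(res$novelty, "variant_id", "novelty",
                                 "annotated"), by = "variant_id")
    }
    master <- arrange(master, .data$chrom, .data$pos, .data$variant_id)
    write_sv_tsv(master, out_files[1], seed = config$seed,
                 extra = sprintf("# config_hash: %s", cfg_hash))

    gl <- glance(res$discovery)
    summary <- list(
      seed = config$seed, config_hash = cfg_hash,
      n_input = nrow(res$callset$variants),
      n_analysis = nrow(res$analysis$variants),
      label_counts = as.list(table(master$label)),
      pct_repetitive = round(
        100 * mean(master$label != "NONREP"), 4),
      sharedness_counts = as.list(table(master$sharedness)),
      geo_counts = as.list(table(master$geo)),
      spread_counts = as.list(table(master$spread)),
      novelty_counts = if (!is.null(res$novelty)) {
        as.list(table(res$novelty$novelty))
      } else NULL,
      discovery = list(a = gl$a, b = gl$b, final_count = gl$final_count),
      pcoa_pct = round(res$pcoa$percent_variance[1:2], 4),
      fst = lapply(seq_len(nrow(res$fst)), function(i) {
        as.list(res$fst[i, c("group1", "group2", "theta", "n_loci")])
      }),
      n_significant_str = if (nrow(res$str_expansions) > 0) {
        sum(res$str_expansions$significant_expansion)
      } else 0L,
      cds_fold_1_vs_10 = {
        dd <- res$densities
        lo <- dd$density[dd$decile == 1 & dd$region_class == "CDS"]
        hi <- dd$density[dd$decile == 10 & dd$region_class == "CDS"]
        if (length(lo) == 1 && length(hi) == 1 && !is.na(lo) && lo > 0) {
          round(fold_difference(lo, hi), 6)
        } else NULL
      },
      cnv_regions = if (!is.null(res$cnv_regions)) {
        nrow(res$cnv_regions)
      } else NULL
    )
    jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                         out_files[2], auto_unbox = TRUE, digits = NA)
    writeLines(c(sprintf("# svscape pipeline, seed %d, config %s",
                         config$seed, cfg_hash), log_lines), out_files[4])
  })

  invisible(res)
}
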