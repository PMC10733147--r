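# Adapters for external repeat-annotation outputs, so real Tandem Repeats
# Finder / RepeatMasker runs can replace the built-in detectors.

#' Parse a Tandem Repeats Finder `.dat` file
#'
#' Reads the table layout of TRF's `.dat` output (one `Sequence:` block per
#' scanned sequence; data lines carry start, end, period, copy number,
#' consensus size, percent matches, percent indels, score, base
#' composition, entropy, motif and the array sequence). Coordinates are
#' converted to 0-based half-open. Malformed lines are skipped with a
#' warning.
#'
#' @param path Path to a `.dat` file.
#' @return A tibble with `sequence_name`, `start`, `end`, `period`,
#'   `motif`, `copy_number`, `purity` (percent matches / 100) and `score`,
#'   compatible with [find_tandem_repeats()] output. The `sequence_name`
#'   can be matched to variant ids by the caller.
#' @export
parse_trf_dat <- function(path) {
  lines <- readLines(path)
  out <- list()
  current <- NA_character_
  n_bad <- 0L
  for (ln in lines) {
    if (grepl("^Sequence:", ln)) {
      current <- sub("^Sequence:\\s*", "", ln)
      current <- sub("\\s.*$", "", current)
      next
    }
    if (!grepl("^[0-9]+\\s+[0-9]+\\s", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 14) {
      n_bad <- n_bad + 1L
      next
    }
    num <- suppressWarnings(as.numeric(f[c(1:8)]))
    if (any(is.na(num))) {
      n_bad <- n_bad + 1L
      next
    }
    out[[length(out) + 1L]] <- tibble(
      sequence_name = current,
      start = as.integer(num[1]) - 1L, end = as.integer(num[2]),
      period = as.integer(num[3]), motif = f[14],
      copy_number = num[4], purity = num[6] / 100, score = num[8])
  }
  if (n_bad > 0) warn(sprintf("skipped %d malformed TRF line(s)", n_bad))
  if (length(out) == 0) {
    return(tibble(sequence_name = character(0), start = integer(0),
                  end = integer(0), period = integer(0),
                  motif = character(0), copy_number = numeric(0),
                  purity = numeric(0), score = numeric(0)))
  }
  bind_rows(out)
}

rm_family <- function(class_family) {
  cls <- sub("/.*$", "", class_family)
  known <- c(SINE = "SINE", LINE = "LINE", DNA = "DNA", LTR = "LTR",
             Retroposon = "Retroposon", SVA = "Retroposon")
  unname(known[cls]) %||% NA_character_
}

#' Parse a RepeatMasker `.out` file
#'
#' Reads the standard column layout (three header lines, then one hit per
#' line). Repeat classes are mapped to the six families used by the
#' classifier (`SINE`, `LINE`, `DNA`, `LTR`, `Retroposon`, `Other`);
#' unknown classes map to `Other`. The consensus fraction is computed from
#' the in-repeat begin/end/left coordinates. Malformed lines are skipped
#' with a warning.
#'
#' @param path Path to a `.out` file.
#' @return A tibble with `sequence_name`, `start`, `end` (0-based
#'   half-open in the query), `element_name`, `family`, `orientation`,
#'   `consensus_fraction` and `consensus_length`, compatible with
#'   [find_mobile_elements()] output.
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  lines <- lines[!grepl("^\\s*(SW|score|perc)", lines)]
  out <- list()
  n_bad <- 0L
  strip <- function(x) as.numeric(gsub("[()]", "", x))
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 14) {
      n_bad <- n_bad + 1L
      next
    }
    qbeg <- suppressWarnings(as.integer(f[6]))
    qend <- suppressWarnings(as.integer(f[7]))
    if (is.na(qbeg) || is.na(qend)) {
      n_bad <- n_bad + 1L
      next
    }
    ori <- if (f[9] %in% c("C", "-")) "-" else "+"
    if (ori == "+") {
      rbeg <- strip(f[12]); rend <- strip(f[13]); rleft <- strip(f[14])
    } else {
      rleft <- strip(f[12]); rend <- strip(f[13]); rbeg <- strip(f[14])
    }
    cons_len <- rend + rleft
    fam <- rm_family(f[11])
    out[[length(out) + 1L]] <- tibble(
      sequence_name = f[5], start = qbeg - 1L, end = qend,
      element_name = f[10],
      family = ifelse(is.na(fam), "Other", fam), orientation = ori,
      consensus_fraction = (rend - rbeg + 1) / cons_len,
      consensus_length = as.integer(cons_len))
  }
  if (n_bad > 0) {
    warn(sprintf("skipped %d malformed RepeatMasker line(s)", n_bad))
  }
  if (length(out) == 0) {
    return(tibble(sequence_name = character(0), start = integer(0),
                  end = integer(0), element_name = character(0),
                  family = character(0), orientation = character(0),
                  consensus_fraction = numeric(0),
                  consensus_length = integer(0)))
  }
  bind_rows(out)
}
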