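# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized over `x`. Characters outside ACGT are complemented to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "CAG"))
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# random DNA of length n under the current RNG state
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# encode a DNA string as integers; ambiguous bases get unique negative codes
# so they never self-match in the tandem scanner
encode_dna <- function(seq) {
  codes <- utf8ToInt(toupper(seq))
  known <- codes %in% utf8ToInt("ACGT")
  if (!all(known)) codes[!known] <- -seq_len(sum(!known))
  codes
}

# derive a stream-specific 32-bit seed from a user seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 2654435L + stream * 97L) %% 2147483647L
}

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# union length of a set of half-open intervals given as start/end vectors
union_bp <- function(start, end) {
  if (length(start) == 0) return(0L)
  o <- order(start)
  s <- start[o]; e <- end[o]
  total <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else if (e[i] > cur_e) {
      cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s)
}

# overlap in bp between one half-open interval and a set of half-open intervals
overlap_bp <- function(qstart, qend, start, end) {
  if (length(start) == 0 || qend <= qstart) return(0L)
  s <- pmax(qstart, start)
  e <- pmin(qend, end)
  keep <- e > s
  if (!any(keep)) return(0L)
  union_bp(s[keep], e[keep])
}

# comment header prepended to every TSV the package writes
sv_tsv_header <- function(seed = NULL, extra = character()) {
  h <- c("# svscape output", sprintf("# package_version: %s",
                                     as.character(utils::packageVersion("svscape"))))
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %d", as.integer(seed)))
  c(h, extra)
}

write_sv_tsv <- function(df, path, seed = NULL, extra = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sv_tsv_header(seed, extra), con)
  # flatten list columns for plain-text output
  for (nm in names(df)[vapply(df, is.list, logical(1))]) {
    df[[nm]] <- vapply(df[[nm]],
                       function(v) paste(unlist(v), collapse = ","),
                       character(1))
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_sv_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
}
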