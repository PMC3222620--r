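# Pre-formatting helpers: FASTA cleanup and hit-file splitting.

IUPAC_NT <- "ACGTURYSWKMBDHVN"

#' Strip stray characters from FASTA sequence lines
#'
#' Removes whitespace, digits, and any character outside the IUPAC
#' nucleotide alphabet from sequence lines (case preserved; ambiguity codes
#' like N, R, Y are kept). Headers are untouched. Lines left empty after
#' cleaning, and blank lines, are dropped. A FASTA that is already clean is
#' copied byte-identically.
#'
#' @param infile Input FASTA-like file (must contain `>` headers).
#' @param out Output path.
#' @param keep_gap_chars Also keep `-` characters (pre-aligned input).
#' @return A list with `sequences` (number of entries) and
#'   `characters_removed`.
#' @examples
#' f <- tempfile()
#' writeLines(c(">s1", "1 ACGT ACGT 8"), f)
#' clean_fasta(f, tempfile())
#' @export
clean_fasta <- function(infile, out, keep_gap_chars = FALSE) {
  lines <- readLines(infile, warn = FALSE)
  is_header <- startsWith(lines, ">")
  if (!any(is_header)) {
    abort(paste0("no FASTA headers found in ", infile))
  }
  alphabet <- paste0(IUPAC_NT, tolower(IUPAC_NT), if (keep_gap_chars) "-")
  pattern <- paste0("[^", alphabet, "]")
  cleaned <- lines
  cleaned[!is_header] <- gsub(pattern, "", lines[!is_header])
  removed <- sum(nchar(lines[!is_header])) - sum(nchar(cleaned[!is_header]))
  keep <- is_header | cleaned != ""
  writeLines(cleaned[keep], out)
  list(sequences = sum(is_header), characters_removed = removed)
}

split_key_field <- function(dialect) {
  switch(check_dialect(dialect),
    blast = 1L,
    repeatmasker = 10L,
    epcr = 2L
  )
}

#' Split a hit file into smaller subfiles
#'
#' `by = "query"` writes one subfile per query/element (data lines
#' verbatim, in input order); `by = "chunk_size"` writes consecutive chunks
#' of `chunk_size` data lines. Headers, comments and blank lines are not
#' copied, so concatenating the subfiles reproduces exactly the input's data
#' lines.
#'
#' @param infile Input hit file.
#' @param dialect One of `"blast"`, `"repeatmasker"`, `"epcr"`.
#' @param by `"query"` or `"chunk_size"`.
#' @param outdir Output directory (created if missing).
#' @param chunk_size Lines per subfile when `by = "chunk_size"`.
#' @return Character vector of the subfile paths, in output order.
#' @export
split_hitfile <- function(infile, dialect, by = c("query", "chunk_size"),
                          outdir, chunk_size = NULL) {
  by <- match.arg(by)
  dialect <- check_dialect(dialect)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory ", outdir))
  }
  lines <- readLines(infile, warn = FALSE)
  data <- lines[!vapply(lines, is_skippable_line, logical(1),
    dialect = dialect, USE.NAMES = FALSE
  )]
  stem <- sub("\\.[^.]*$", "", basename(infile))
  if (by == "query") {
    fld <- split_key_field(dialect)
    keys <- vapply(data, function(l) split_fields(l)[fld], character(1),
      USE.NAMES = FALSE
    )
    parts <- split(data, factor(keys, levels = unique(keys)))
    files <- file.path(outdir, paste0(stem, "_", sanitize_key(names(parts)), ".out"))
    purrr::walk2(parts, files, writeLines)
  } else {
    if (is.null(chunk_size) || chunk_size < 1) {
      abort("split_hitfile: chunk_size must be >= 1 when by = 'chunk_size'")
    }
    idx <- ceiling(seq_along(data) / chunk_size)
    parts <- split(data, idx)
    files <- file.path(outdir, sprintf("%s_part%03d.out", stem, seq_along(parts)))
    purrr::walk2(parts, files, writeLines)
  }
  files
}
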