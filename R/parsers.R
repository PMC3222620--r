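# Parsers for the three supported hit-report dialects. Every dialect is
# normalized into the same hit-table model: 1-based inclusive coordinates
# with seq_start <= seq_end and orientation carried by `strand`.

split_fields <- function(line) strsplit(trimws(line), "\\s+")[[1]]

parse_abort <- function(msg, line_number = NA_integer_) {
  abort(
    paste0(
      "parse error", if (!is.na(line_number)) paste0(" at line ", line_number),
      ": ", msg
    ),
    class = "tehits_parse_error", line_number = line_number
  )
}

num_or_abort <- function(x, what, line_number) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) parse_abort(paste0("non-numeric ", what, " '", x, "'"), line_number)
  v
}

# Comment / header / blank line detection, per dialect.
is_skippable_line <- function(line, dialect) {
  t <- trimws(line)
  if (t == "") {
    return(TRUE)
  }
  if (dialect %in% c("blast", "epcr") && startsWith(t, "#")) {
    return(TRUE)
  }
  if (dialect == "repeatmasker") {
    first <- sub("\\s.*$", "", t)
    if (first %in% c("SW", "score") || startsWith(t, "There were no")) {
      return(TRUE)
    }
  }
  FALSE
}

#' Parse one line of BLAST tabular output into a hit
#'
#' Expects the standard 12-column tabular layout (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, q.start, q.end,
#' s.start, s.end, E-value, bit score). Subject coordinates arriving with
#' start > end denote a minus-strand match: they are swapped so that
#' `seq_start <= seq_end` and `strand` is set to `-`. Query coordinates are
#' consumed but not retained; downstream stages work purely in subject space.
#'
#' @param line One data line (comment lines starting with `#` are the
#'   caller's responsibility to skip).
#' @param line_number Optional line number used in error messages.
#' @return A one-row hit tibble.
#' @examples
#' parse_blast_line("TE1\tchr1\t95.00\t200\t5\t2\t1\t200\t1200\t1001\t1e-50\t180.0")
#' @export
parse_blast_line <- function(line, line_number = NA_integer_) {
  f <- split_fields(line)
  if (length(f) != 12) {
    parse_abort(paste0("expected 12 BLAST columns, found ", length(f)), line_number)
  }
  s1 <- num_or_abort(f[9], "subject start", line_number)
  s2 <- num_or_abort(f[10], "subject end", line_number)
  mism <- num_or_abort(f[5], "mismatch count", line_number)
  gaps <- num_or_abort(f[6], "gap count", line_number)
  ev <- num_or_abort(f[11], "E-value", line_number)
  bit <- num_or_abort(f[12], "bit score", line_number)
  strand <- if (s1 > s2) "-" else "+"
  start <- min(s1, s2)
  end <- max(s1, s2)
  new_hit_tbl(
    hit_id = make_hit_id(f[1], f[2], start, end),
    location = f[2], seq_start = start, seq_end = end, strand = strand,
    group_label = f[1], mismatches = mism, gaps = gaps,
    e_value = ev, bit_score = bit, dialect = "blast"
  )
}

#' Parse one line of a RepeatMasker `.out` annotation
#'
#' Expects the standard space-aligned `.out` layout: SW score, percent
#' divergence/deletion/insertion, query sequence name, begin, end, (left),
#' strand (`+` or `C` for complement), repeat name, repeat class/family,
#' repeat begin/end, (left), and optional ID. The group label is
#' `repeatName#class/family`; mismatch, gap, and score fields are absent in
#' this dialect.
#'
#' @inheritParams parse_blast_line
#' @return A one-row hit tibble.
#' @export
parse_repeatmasker_line <- function(line, line_number = NA_integer_) {
  f <- split_fields(line)
  if (length(f) < 13 || length(f) > 16) {
    parse_abort(
      paste0("expected 13-16 RepeatMasker columns, found ", length(f)),
      line_number
    )
  }
  start <- num_or_abort(f[6], "begin coordinate", line_number)
  end <- num_or_abort(f[7], "end coordinate", line_number)
  glyph <- f[9]
  if (!glyph %in% c("+", "C")) {
    parse_abort(paste0("unrecognized strand glyph '", glyph, "'"), line_number)
  }
  label <- paste0(f[10], "#", f[11])
  new_hit_tbl(
    hit_id = make_hit_id(label, f[5], start, end),
    location = f[5], seq_start = start, seq_end = end,
    strand = if (glyph == "C") "-" else "+",
    group_label = label, dialect = "repeatmasker"
  )
}

#' Parse one line of e-PCR tabular output into a hit
#'
#' Uses a five-column dialect: sequence id, marker id, strand (`+`/`-`),
#' start, end. Coordinates are stored ordered (`seq_start <= seq_end`)
#' whatever order the line gives them; the strand column carries orientation.
#'
#' @inheritParams parse_blast_line
#' @return A one-row hit tibble.
#' @export
parse_epcr_line <- function(line, line_number = NA_integer_) {
  f <- split_fields(line)
  if (length(f) != 5) {
    parse_abort(paste0("expected 5 e-PCR columns, found ", length(f)), line_number)
  }
  if (!f[3] %in% c("+", "-")) {
    parse_abort(paste0("unrecognized strand '", f[3], "'"), line_number)
  }
  c1 <- num_or_abort(f[4], "start coordinate", line_number)
  c2 <- num_or_abort(f[5], "end coordinate", line_number)
  new_hit_tbl(
    hit_id = make_hit_id(f[2], f[1], min(c1, c2), max(c1, c2)),
    location = f[1], seq_start = min(c1, c2), seq_end = max(c1, c2),
    strand = f[3], group_label = f[2], dialect = "epcr"
  )
}

line_parser_for <- function(dialect) {
  switch(check_dialect(dialect),
    blast = parse_blast_line,
    repeatmasker = parse_repeatmasker_line,
    epcr = parse_epcr_line
  )
}

#' Read a hit file into a hit table
#'
#' Reads one BLAST-tabular, RepeatMasker `.out`, or e-PCR tabular file,
#' skipping headers, comments and blank lines, and returns hits in file
#' order. Malformed lines abort with the offending line number unless
#' `skip_bad` is set, in which case they are counted (see the `skipped`
#' attribute of the result) and skipped with a warning. Hit ids are made
#' unique across the whole file even when two lines describe identical loci.
#'
#' @param path Path to the hit file.
#' @param dialect One of `"blast"`, `"repeatmasker"`, `"epcr"`.
#' @param skip_bad Skip malformed lines instead of aborting.
#' @return A hit tibble with attributes `dialect` and `skipped`.
#' @export
parse_hit_file <- function(path, dialect, skip_bad = FALSE) {
  dialect <- check_dialect(dialect)
  if (!file.exists(path)) {
    abort(paste0("hit file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  parser <- line_parser_for(dialect)
  keep <- !vapply(lines, is_skippable_line, logical(1),
    dialect = dialect, USE.NAMES = FALSE
  )
  rows <- vector("list", sum(keep))
  n_skipped <- 0L
  j <- 0L
  for (i in which(keep)) {
    row <- if (skip_bad) {
      tryCatch(parser(lines[[i]], line_number = i),
        tehits_parse_error = function(e) {
          warn(conditionMessage(e))
          NULL
        }
      )
    } else {
      parser(lines[[i]], line_number = i)
    }
    if (is.null(row)) {
      n_skipped <- n_skipped + 1L
    } else {
      j <- j + 1L
      rows[[j]] <- row
    }
  }
  hits <- if (j == 0) empty_hit_tbl(dialect) else dplyr::bind_rows(rows[seq_len(j)])
  if (nrow(hits) == 0) {
    warn(paste0("no hits parsed from ", path))
  }
  hits$hit_id <- dedupe_hit_ids(hits$hit_id)
  attr(hits, "dialect") <- dialect
  attr(hits, "skipped") <- n_skipped
  validate_hits(hits)
  hits
}

#' Read several hit files sharing one dialect
#'
#' Concatenates the per-file results in list order. Every path is checked
#' before any parsing starts, and hit-id uniqueness is maintained across
#' files (duplicate loci in different files get suffixed ids).
#'
#' @param paths Character vector of hit-file paths.
#' @inheritParams parse_hit_file
#' @return A hit tibble with attributes `dialect` and `skipped`.
#' @export
parse_hit_files <- function(paths, dialect, skip_bad = FALSE) {
  dialect <- check_dialect(dialect)
  bad <- paths[!file.exists(paths)]
  if (length(bad) > 0) {
    abort(paste0("hit file(s) not found: ", toString(bad)))
  }
  if (length(paths) == 0) {
    return(empty_hit_tbl(dialect))
  }
  parts <- lapply(paths, parse_hit_file, dialect = dialect, skip_bad = skip_bad)
  hits <- dplyr::bind_rows(parts)
  hits$hit_id <- dedupe_hit_ids(
    make_hit_id(hits$group_label, hits$location, hits$seq_start, hits$seq_end)
  )
  attr(hits, "dialect") <- dialect
  attr(hits, "skipped") <- sum(vapply(parts, function(p) attr(p, "skipped") %||% 0L, integer(1)))
  validate_hits(hits)
  hits
}

#' Read a plain-text list of hit-file paths
#'
#' One path per line; blank lines and `#` comments are ignored. Relative
#' paths are resolved against the list file's own directory.
#'
#' @param path Path to the list file.
#' @return Character vector of hit-file paths.
#' @export
read_file_list <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file list not found: ", path))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  ifelse(
    grepl("^(/|~)", lines) | file.exists(lines),
    lines,
    file.path(dirname(path), lines)
  )
}
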