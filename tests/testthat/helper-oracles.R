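# Independent oracles and random-input builders shared by the tests.
# These deliberately avoid the package's own code paths: the merge oracle is
# a pairwise union-to-fixpoint loop, the reverse complement is chartr-based,
# and expected flank sequences are sliced from the raw FASTA text.

# Reverse complement without Biostrings.
rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
      collapse = ""
    )
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force merge: repeatedly union ANY pair satisfying the gap rule until
# no pair does, independent of the package's sorted sweep.
oracle_merge <- function(df, distance, same_group = TRUE, same_strand = TRUE) {
  rows <- df[, c("location", "group_label", "strand", "seq_start", "seq_end")]
  rows$merged_count <- if ("merged_count" %in% names(df)) df$merged_count else 1L
  repeat {
    n <- nrow(rows)
    merged_any <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (rows$location[i] != rows$location[j]) next
        if (same_group && rows$group_label[i] != rows$group_label[j]) next
        if (same_strand && rows$strand[i] != rows$strand[j]) next
        gap <- max(rows$seq_start[i], rows$seq_start[j]) -
          min(rows$seq_end[i], rows$seq_end[j]) - 1
        if (gap <= distance) {
          rows$seq_start[i] <- min(rows$seq_start[i], rows$seq_start[j])
          rows$seq_end[i] <- max(rows$seq_end[i], rows$seq_end[j])
          rows$merged_count[i] <- rows$merged_count[i] + rows$merged_count[j]
          rows <- rows[-j, , drop = FALSE]
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  rows[order(rows$location, rows$seq_start, rows$seq_end), , drop = FALSE]
}

# Per-base coverage set of a hit table, for coverage-conservation checks.
coverage_set <- function(df) {
  unique(unlist(mapply(
    function(l, s, e) paste0(l, ":", s:e),
    df$location, df$seq_start, df$seq_end,
    SIMPLIFY = FALSE
  ), use.names = FALSE))
}

# Random in-memory hit table on a handful of sequences/groups.
random_hits <- function(n, n_locations = 2, n_groups = 2, max_pos = 2000,
                        dialect = "blast") {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(200, n, replace = TRUE)
  mism <- sample.int(20, n, replace = TRUE)
  bit <- round(stats::runif(n, 30, 400), 1)
  blast <- dialect == "blast"
  new_hit_tbl(
    hit_id = paste0("h", seq_len(n)),
    location = sample(paste0("chr", seq_len(n_locations)), n, replace = TRUE),
    seq_start = start, seq_end = start + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    group_label = sample(
      if (dialect == "repeatmasker") {
        paste0("EL", seq_len(n_groups), "#FAM/F", seq_len(n_groups))
      } else {
        paste0("Q", seq_len(n_groups))
      }, n,
      replace = TRUE
    ),
    mismatches = if (blast) mism else NA_integer_,
    gaps = if (blast) sample(0:5, n, replace = TRUE) else NA_integer_,
    e_value = if (blast) 10^(-bit / 10) else NA_real_,
    bit_score = if (blast) bit else NA_real_,
    dialect = dialect
  )
}

# Random dialect files written straight as text (independent of the
# package's writers), for parser round-trip tests.
random_blast_file <- function(n, path = tempfile(fileext = ".out")) {
  len <- sample.int(500, n, replace = TRUE) + 30L
  mism <- sample.int(15, n, replace = TRUE)
  s <- sample.int(5000, n, replace = TRUE)
  e <- s + len - 1L
  minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
  bit <- round(stats::runif(n, 40, 500), 1)
  lines <- paste(
    sample(paste0("TE", 1:3), n, replace = TRUE),
    sample(paste0("chr", 1:2), n, replace = TRUE),
    sprintf("%.2f", 100 * (1 - mism / len)), len, mism,
    sample(0:3, n, replace = TRUE), 1L, len,
    ifelse(minus, e, s), ifelse(minus, s, e),
    sprintf("%.6g", 10^(-bit / 10)), sprintf("%.1f", bit),
    sep = "\t"
  )
  writeLines(lines, path)
  path
}

random_rm_file <- function(n, path = tempfile(fileext = ".out")) {
  s <- sample.int(5000, n, replace = TRUE)
  len <- sample.int(800, n, replace = TRUE) + 50L
  lines <- c(
    "   SW   perc perc perc  query  position in query  matching repeat  position in repeat",
    "score   div. del. ins.  sequence begin end (left) repeat class/family begin end (left) ID",
    "",
    paste(
      sample.int(3000, n, replace = TRUE), "12.3", "0.5", "0.8",
      sample(paste0("scaf", 1:3), n, replace = TRUE), s, s + len - 1L, "(100)",
      sample(c("+", "C"), n, replace = TRUE),
      sample(c("L1X", "AluZ", "HATQ"), n, replace = TRUE),
      sample(c("LINE/L1", "SINE/Alu", "DNA/hAT"), n, replace = TRUE),
      1L, len, "(0)", seq_len(n)
    )
  )
  writeLines(lines, path)
  path
}

# Comparable normalized tuple of a hit table (drops run-specific ids).
hit_tuple <- function(hits, fields = c(
                        "location", "seq_start", "seq_end", "strand",
                        "group_label", "mismatches", "gaps", "e_value",
                        "bit_score"
                      )) {
  df <- as.data.frame(hits[, intersect(fields, names(hits))])
  rownames(df) <- NULL
  df
}

# Small shared FASTA database on disk.
write_test_fasta <- function(seqs, path = tempfile(fileext = ".fas")) {
  writeLines(unlist(lapply(names(seqs), function(nm) {
    wrapped <- sub("\n$", "", gsub("(.{60})", "\\1\n", seqs[[nm]], perl = TRUE))
    c(paste0(">", nm), strsplit(wrapped, "\n", fixed = TRUE)[[1]])
  })), path)
  path
}
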