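# Sequence-extraction stage: faidx-indexed random access into the FASTA
# database, flank buffering clamped to sequence bounds, and FASTA / hit-table
# output. Random access goes through the htslib index, so memory stays
# bounded by one sequence rather than the whole database.

#' Index a FASTA database for random access
#'
#' Builds (or reuses) a faidx index next to the file and returns a
#' lightweight store recording every sequence's name and length. Retrieval
#' through the store is by `(name, start, end)` in 1-based inclusive
#' coordinates. Duplicate sequence names, empty files, and non-FASTA content
#' are fatal.
#'
#' @param fasta Path to an uncompressed FASTA file.
#' @return A `sequence_store` object.
#' @export
build_store <- function(fasta) {
  if (!file.exists(fasta)) {
    abort(paste0("FASTA database not found: ", fasta))
  }
  headers <- scan_fasta_headers(fasta)
  if (length(headers) == 0) {
    abort(paste0("not a FASTA file (no '>' headers): ", fasta))
  }
  nm <- sub("\\s.*$", "", sub("^>", "", headers))
  if (anyDuplicated(nm)) {
    dup <- nm[duplicated(nm)][1]
    abort(paste0(
      "duplicate sequence name in ", fasta, ": '", dup,
      "' (offending header: '", headers[nm == dup][2], "')"
    ))
  }
  fai <- paste0(fasta, ".fai")
  if (!file.exists(fai) || file.mtime(fai) < file.mtime(fasta)) {
    tryCatch(Rsamtools::indexFa(fasta), error = function(e) {
      abort(paste0("failed to index FASTA ", fasta, ": ", conditionMessage(e)))
    })
  }
  idx <- Rsamtools::scanFaIndex(fasta)
  lens <- stats::setNames(
    GenomicRanges::width(idx),
    as.character(GenomicRanges::seqnames(idx))
  )
  structure(
    list(path = normalizePath(fasta), lengths = lens),
    class = "sequence_store"
  )
}

# Stream the file in line chunks, collecting only header lines; validates
# that the first non-blank character is '>'.
scan_fasta_headers <- function(fasta) {
  con <- file(fasta, open = "r")
  on.exit(close(con))
  headers <- character(0)
  first_seen <- FALSE
  repeat {
    chunk <- readLines(con, n = 10000L, warn = FALSE)
    if (length(chunk) == 0) break
    if (!first_seen) {
      nonblank <- chunk[trimws(chunk) != ""]
      if (length(nonblank) > 0) {
        first_seen <- TRUE
        if (!startsWith(nonblank[1], ">")) {
          abort(paste0(
            "not a FASTA file: ", fasta, " (first content line: '",
            substr(nonblank[1], 1, 40), "')"
          ))
        }
      }
    }
    headers <- c(headers, chunk[startsWith(chunk, ">")])
  }
  headers
}

#' @export
print.sequence_store <- function(x, ...) {
  cat("<sequence_store> ", x$path, "\n  ", length(x$lengths),
    " sequence(s), ", format(sum(as.numeric(x$lengths)), big.mark = ","),
    " bases total\n",
    sep = ""
  )
  invisible(x)
}

#' Sequence lengths known to a store
#'
#' @param store A `sequence_store`.
#' @return Named integer vector of sequence lengths.
#' @export
store_lengths <- function(store) {
  stopifnot(inherits(store, "sequence_store"))
  store$lengths
}

#' Fetch subsequences from an indexed FASTA store
#'
#' @param store A `sequence_store`.
#' @param name,start,end Parallel vectors of sequence names and 1-based
#'   inclusive coordinates, all within bounds.
#' @return Character vector of subsequences.
#' @export
fetch_sequence <- function(store, name, start, end) {
  stopifnot(inherits(store, "sequence_store"))
  unknown <- setdiff(unique(name), names(store$lengths))
  if (length(unknown) > 0) {
    abort(paste0("unknown sequence(s) in store: ", toString(unknown)))
  }
  if (any(start < 1L) || any(end > store$lengths[name]) || any(start > end)) {
    abort("fetch_sequence: coordinates out of bounds")
  }
  if (length(name) == 0) {
    return(character(0))
  }
  rng <- GenomicRanges::GRanges(name, IRanges::IRanges(start, end))
  unname(as.character(Rsamtools::scanFa(Rsamtools::FaFile(store$path), param = rng)))
}

#' Buffer hit coordinates with flanks, clamped to sequence bounds
#'
#' Adds `extract_start = max(1, seq_start - buffer)` and
#' `extract_end = min(sequence length, seq_end + buffer)` columns, extending
#' each hit upstream and downstream where sequence is available. Hits on
#' sequences unknown to the store are reported with a warning and dropped;
#' the run continues.
#'
#' @param hits A hit tibble.
#' @param buffer Flank size in bases, >= 0.
#' @param store A `sequence_store` covering the hit locations.
#' @return `hits` with `extract_start` / `extract_end` columns.
#' @export
buffered_coordinates <- function(hits, buffer, store) {
  stopifnot(inherits(store, "sequence_store"))
  if (!is.numeric(buffer) || length(buffer) != 1 || is.na(buffer) || buffer < 0) {
    abort("buffer must be a single number >= 0")
  }
  validate_hits(hits)
  dialect <- hit_dialect(hits)
  known <- hits$location %in% names(store$lengths)
  if (any(!known)) {
    warn(paste0(
      "skipping ", sum(!known), " hit(s) on sequence(s) absent from the database: ",
      toString(unique(hits$location[!known])), " (hit ids: ",
      toString(utils::head(hits$hit_id[!known], 5)), ")"
    ))
    hits <- hits[known, , drop = FALSE]
  }
  lens <- unname(store$lengths[hits$location])
  out <- dplyr::mutate(
    hits,
    extract_start = pmax(1L, .data$seq_start - as.integer(buffer)),
    extract_end = pmin(as.integer(lens), .data$seq_end + as.integer(buffer))
  )
  attr(out, "dialect") <- dialect
  out
}

#' Extract hit sequences from the database
#'
#' Slices the store at each hit's buffered coordinates. By default
#' minus-strand extracts are reverse-complemented so every output sequence
#' reads in query/element orientation (the orientation an aligner comparing
#' hits to their query consensus expects); set `revcomp_minus = FALSE` to
#' keep genomic orientation for flank-analysis workflows. Genomic
#' coordinates and strand are retained on every record either way.
#'
#' @inheritParams buffered_coordinates
#' @param revcomp_minus Reverse-complement minus-strand extracts.
#' @return A tibble of extraction records: the hit columns plus
#'   `extract_start`, `extract_end`, and `sequence`.
#' @export
extract_hits <- function(hits, store, buffer = 0L, revcomp_minus = TRUE) {
  coords <- buffered_coordinates(hits, buffer, store)
  if (nrow(coords) == 0) {
    return(dplyr::mutate(coords, sequence = character(0)))
  }
  seqs <- Biostrings::DNAStringSet(fetch_sequence(
    store, coords$location, coords$extract_start, coords$extract_end
  ))
  minus <- coords$strand == "-"
  if (isTRUE(revcomp_minus) && any(minus)) {
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }
  out <- dplyr::mutate(coords, sequence = as.character(seqs))
  attr(out, "dialect") <- hit_dialect(hits)
  attr(out, "revcomp_minus") <- isTRUE(revcomp_minus)
  out
}

record_headers <- function(records) {
  paste0(
    records$hit_id, " ", records$location, ":", records$extract_start,
    "-", records$extract_end, "(", records$strand, ")"
  )
}

#' Write extraction records to a FASTA file
#'
#' One entry per record, headers
#' `>{hit_id} {location}:{extract_start}-{extract_end}({strand})`, sequence
#' wrapped at 60 columns.
#'
#' @param records Extraction records from [extract_hits()].
#' @param out Output FASTA path.
#' @return Number of records written, invisibly.
#' @export
write_fasta <- function(records, out) {
  if (nrow(records) == 0) {
    file.create(out)
    warn(paste0("no records to write; created empty FASTA ", out))
    return(invisible(0L))
  }
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- record_headers(records)
  Biostrings::writeXStringSet(x, out, width = 60L)
  invisible(nrow(records))
}

sanitize_key <- function(key) gsub("[^A-Za-z0-9._-]", "_", key)

#' Write one FASTA file per hit group
#'
#' Extracts every group with [extract_hits()] and writes one FASTA per group
#' into `outdir`, named from the sanitized group key (`#`, `/` and other
#' non-filename characters become `_`). When a query FASTA is supplied, the
#' query sequence matching each group - by exact header-token equality with
#' the group key, or with the element-name component of RepeatMasker labels -
#' is written first in that group's file; keys with no match get a warning,
#' not an error. The records across all files are exactly the unsplit
#' extraction output.
#'
#' @param groups Named list of hit tibbles from [split_hits()].
#' @param store A `sequence_store`.
#' @param outdir Output directory (created if missing).
#' @param buffer Flank size in bases.
#' @param qseq Optional path to the original query/consensus FASTA.
#' @param revcomp_minus Passed to [extract_hits()].
#' @return A tibble with one row per group: `key`, `file`, `n_records`,
#'   `n_query`.
#' @export
write_split_fasta <- function(groups, store, outdir, buffer = 0L,
                              qseq = NULL, revcomp_minus = TRUE) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory ", outdir))
  }
  qset <- NULL
  if (!is.null(qseq)) {
    qset <- Biostrings::readDNAStringSet(qseq)
    names(qset) <- sub("\\s.*$", "", names(qset))
  }
  rows <- purrr::imap(groups, function(group, key) {
    records <- extract_hits(group, store, buffer = buffer, revcomp_minus = revcomp_minus)
    x <- Biostrings::DNAStringSet(records$sequence)
    names(x) <- record_headers(records)
    n_query <- 0L
    if (!is.null(qset)) {
      candidates <- unique(c(key, element_of(key), element_of(group$group_label)))
      q <- qset[names(qset) %in% candidates]
      if (length(q) == 0) {
        warn(paste0("no query sequence found for group '", key, "'"))
      } else {
        x <- c(q, x)
        n_query <- length(q)
      }
    }
    file <- file.path(outdir, paste0(sanitize_key(key), ".fas"))
    Biostrings::writeXStringSet(x, file, width = 60L)
    tibble(key = key, file = file, n_records = nrow(records), n_query = n_query)
  })
  dplyr::bind_rows(rows)
}

fmt_evalue <- function(x) sprintf("%.6g", x)
fmt_pct <- function(x) sprintf("%.2f", x)

#' Serialize surviving hits back into their input dialect
#'
#' Writes the hit table in the dialect's own column layout so the file can
#' feed any downstream tool that reads that format, and so that re-parsing
#' it reproduces the hit set. BLAST lines re-invert subject coordinates for
#' minus-strand hits and reconstruct query-space columns (q.start 1, q.end =
#' alignment length, percent identity from the stored mismatch count);
#' RepeatMasker lines use `C` for minus strand. Merged hits (merged_count >
#' 1) are preceded by a `#` comment line noting the merge count.
#'
#' @param hits A hit tibble.
#' @param dialect Output dialect; defaults to the table's own.
#' @param out Output path.
#' @return Number of hit lines written, invisibly.
#' @export
write_hit_table <- function(hits, dialect = hit_dialect(hits), out) {
  dialect <- check_dialect(dialect)
  validate_hits(hits)
  n <- nrow(hits)
  lines <- character(0)
  if (n > 0) {
    body <- switch(dialect,
      blast = {
        mism <- ifelse(is.na(hits$mismatches), 0L, hits$mismatches)
        gaps <- ifelse(is.na(hits$gaps), 0L, hits$gaps)
        pid <- fmt_pct(100 * (1 - mism / hits$seq_length))
        minus <- hits$strand == "-"
        s1 <- ifelse(minus, hits$seq_end, hits$seq_start)
        s2 <- ifelse(minus, hits$seq_start, hits$seq_end)
        paste(hits$group_label, hits$location, pid, hits$seq_length,
          mism, gaps, 1L, hits$seq_length, s1, s2,
          fmt_evalue(ifelse(is.na(hits$e_value), 1, hits$e_value)),
          sprintf("%.1f", ifelse(is.na(hits$bit_score), 0, hits$bit_score)),
          sep = "\t"
        )
      },
      repeatmasker = {
        div <- ifelse(is.na(hits$mismatches), 0,
          100 * hits$mismatches / hits$seq_length
        )
        paste(
          0L, sprintf("%.1f", div), "0.0", "0.0",
          hits$location, hits$seq_start, hits$seq_end, "(0)",
          ifelse(hits$strand == "-", "C", "+"),
          element_of(hits$group_label), family_of(hits$group_label),
          1L, hits$seq_length, "(0)", seq_len(n)
        )
      },
      epcr = paste(
        hits$location, hits$group_label, hits$strand,
        hits$seq_start, hits$seq_end
      )
    )
    comment <- ifelse(
      hits$merged_count > 1L,
      paste0("# ", hits$hit_id, " merged_count=", hits$merged_count),
      NA_character_
    )
    lines <- as.vector(rbind(comment, body))
    lines <- lines[!is.na(lines)]
  }
  if (dialect == "repeatmasker") {
    lines <- c(
      "   SW   perc perc perc  query         position in query      matching  repeat           position in repeat",
      "score   div. del. ins.  sequence      begin end      (left)  repeat    class/family   begin  end    (left)  ID",
      "",
      lines
    )
  }
  writeLines(lines, out)
  invisible(n)
}

#' Draw a deterministic random sample of records
#'
#' Samples `k` records without replacement using a seeded generator, leaving
#' the global random state untouched; the original relative order of the
#' selected records is preserved. `k` at or above the record count returns
#' everything.
#'
#' @param records A data frame (or vector/list) of records.
#' @param k Sample size, >= 0.
#' @param seed Integer seed; the same seed always gives the same selection.
#' @return The sampled records.
#' @export
sample_records <- function(records, k, seed = 1L) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0)
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (k >= n) {
    return(records)
  }
  idx <- sort(withr::with_seed(as.integer(seed), sample.int(n, k)))
  if (is.data.frame(records)) records[idx, , drop = FALSE] else records[idx]
}
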