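#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column order of a hit table. Orientation always lives in `strand`;
# seq_start <= seq_end is an invariant, never encodes direction.
HIT_COLUMNS <- c(
  "hit_id", "location", "seq_start", "seq_end", "seq_length", "strand",
  "group_label", "mismatches", "gaps", "e_value", "bit_score", "merged_count"
)

# Which quality fields each input dialect reports.
DIALECTS <- c("blast", "repeatmasker", "epcr")
DIALECT_FIELDS <- list(
  blast        = c("mismatches", "gaps", "e_value", "bit_score"),
  repeatmasker = character(0),
  epcr         = character(0)
)

#' Build a unique identifier for one hit
#'
#' Hit identifiers are `label_location_start_end`; when the same tuple is
#' issued more than once within a run, later copies get a numeric suffix
#' (`_1`, `_2`, ...) so identifiers stay unique even for duplicate loci.
#'
#' @param group_label Query id, repeat element label, or marker id.
#' @param location Name of the database sequence the hit lies on.
#' @param seq_start,seq_end 1-based inclusive coordinates, start <= end.
#' @param disambiguator Non-negative integer; 0 means no suffix.
#' @return A character identifier.
#' @examples
#' make_hit_id("TE1", "chr1", 1001, 1200, 0)
#' make_hit_id("TE1", "chr1", 1001, 1200, 1)
#' @export
make_hit_id <- function(group_label, location, seq_start, seq_end,
                        disambiguator = 0L) {
  stopifnot(all(seq_start <= seq_end), all(disambiguator >= 0))
  base <- paste(group_label, location, seq_start, seq_end, sep = "_")
  k <- rep_len(as.integer(disambiguator), length(base))
  ifelse(k > 0, paste0(base, "_", k), base)
}

# Assign run-unique ids to a whole vector of hits, suffixing collisions in
# order of appearance. `taken` seeds already-issued ids (multi-file input).
dedupe_hit_ids <- function(base, taken = character(0)) {
  if (!anyDuplicated(c(taken, base))) {
    return(base)
  }
  issued <- new.env(parent = emptyenv(), hash = TRUE)
  for (id in taken) assign(id, 0L, envir = issued)
  out <- character(length(base))
  for (i in seq_along(base)) {
    id <- base[[i]]
    k <- 0L
    while (exists(id, envir = issued, inherits = FALSE)) {
      k <- k + 1L
      id <- paste0(base[[i]], "_", k)
    }
    assign(id, 0L, envir = issued)
    out[[i]] <- id
  }
  out
}

#' Assemble a hit table from parallel vectors
#'
#' Low-level constructor for the normalized hit model shared by every
#' pipeline stage: one row per match locus, 1-based inclusive coordinates
#' with `seq_start <= seq_end`, orientation in `strand` (`"+"`/`"-"`), and
#' `NA` in the quality columns a dialect does not report. `seq_length` is
#' computed as `seq_end - seq_start + 1` and all invariants are checked.
#'
#' @param hit_id Unique identifiers (see [make_hit_id()]).
#' @param location Database sequence names.
#' @param seq_start,seq_end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param group_label Query id, `element#class/family` label, or marker id.
#' @param mismatches,gaps,e_value,bit_score Optional quality fields.
#' @param merged_count Raw hits combined into each record (1 when fresh).
#' @param dialect Source dialect recorded as an attribute, or `NULL`.
#' @return A hit tibble.
#' @export
new_hit_tbl <- function(hit_id, location, seq_start, seq_end, strand,
                        group_label, mismatches = NA_integer_,
                        gaps = NA_integer_, e_value = NA_real_,
                        bit_score = NA_real_, merged_count = 1L,
                        dialect = NULL) {
  hits <- tibble(
    hit_id = as.character(hit_id),
    location = as.character(location),
    seq_start = as.integer(seq_start),
    seq_end = as.integer(seq_end),
    seq_length = as.integer(seq_end) - as.integer(seq_start) + 1L,
    strand = as.character(strand),
    group_label = as.character(group_label),
    mismatches = as.integer(mismatches),
    gaps = as.integer(gaps),
    e_value = as.double(e_value),
    bit_score = as.double(bit_score),
    merged_count = as.integer(merged_count)
  )
  attr(hits, "dialect") <- dialect
  validate_hits(hits)
  hits
}

empty_hit_tbl <- function(dialect = NULL) {
  new_hit_tbl(
    hit_id = character(0), location = character(0),
    seq_start = integer(0), seq_end = integer(0), strand = character(0),
    group_label = character(0), dialect = dialect
  )
}

#' Check the structural invariants of a hit table
#'
#' Verifies column presence, `seq_start <= seq_end`, the inclusive-length
#' identity `seq_length == seq_end - seq_start + 1`, strand values, positive
#' merge counts, and hit-id uniqueness. Called internally after every
#' constructing or transforming stage.
#'
#' @param hits A hit tibble.
#' @return `hits`, invisibly; aborts on any violation.
#' @export
validate_hits <- function(hits) {
  missing <- setdiff(HIT_COLUMNS, names(hits))
  if (length(missing) > 0) {
    abort(paste0("hit table is missing columns: ", toString(missing)))
  }
  if (nrow(hits) == 0) {
    return(invisible(hits))
  }
  if (any(hits$seq_start > hits$seq_end)) {
    abort("hit invariant violated: seq_start > seq_end")
  }
  if (any(hits$seq_start < 1L)) {
    abort("hit invariant violated: coordinates are 1-based (seq_start >= 1)")
  }
  if (any(hits$seq_length != hits$seq_end - hits$seq_start + 1L)) {
    abort("hit invariant violated: seq_length != seq_end - seq_start + 1")
  }
  if (!all(hits$strand %in% c("+", "-"))) {
    abort("hit invariant violated: strand must be '+' or '-'")
  }
  if (any(hits$merged_count < 1L)) {
    abort("hit invariant violated: merged_count >= 1")
  }
  if (anyDuplicated(hits$hit_id)) {
    abort("hit invariant violated: hit_id values must be unique")
  }
  invisible(hits)
}

hit_dialect <- function(hits) attr(hits, "dialect", exact = TRUE)

check_dialect <- function(dialect) {
  if (!is.character(dialect) || length(dialect) != 1 ||
    !dialect %in% DIALECTS) {
    abort(paste0("dialect must be one of: ", toString(DIALECTS)))
  }
  dialect
}

#' Quality-control thresholds for hit filtering
#'
#' Bundles the optional thresholds applied by [apply_filters()] plus the
#' best-N setting used by [select_best()]. A `NULL` threshold is not applied.
#' Score thresholds (`min_bit_score`, `max_e_value`) and the mismatch/gap
#' caps are only meaningful for the BLAST dialect, which is the only one that
#' reports those fields; supplying them for another dialect is a
#' configuration error raised when the filter runs.
#'
#' @param min_length,max_length Bounds on `seq_length`, in bases.
#' @param max_gaps,max_mismatches Caps on the reported gap and mismatch
#'   counts.
#' @param min_bit_score Minimum BLAST bit score.
#' @param max_e_value Maximum BLAST E-value.
#' @param best_n Keep only the N best hits per group by E-value.
#' @return A `filter_params` object.
#' @examples
#' filter_params(min_length = 100, min_bit_score = 100)
#' @export
filter_params <- function(min_length = NULL, max_length = NULL,
                          max_gaps = NULL, max_mismatches = NULL,
                          min_bit_score = NULL, max_e_value = NULL,
                          best_n = NULL) {
  params <- list(
    min_length = min_length, max_length = max_length, max_gaps = max_gaps,
    max_mismatches = max_mismatches, min_bit_score = min_bit_score,
    max_e_value = max_e_value, best_n = best_n
  )
  for (nm in names(params)) {
    v <- params[[nm]]
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      abort(paste0("filter_params: `", nm, "` must be a single number >= 0"))
    }
  }
  if (!is.null(min_length) && !is.null(max_length) &&
    min_length > max_length) {
    abort("filter_params: min_length must be <= max_length")
  }
  if (!is.null(best_n) && best_n < 1) {
    abort("filter_params: best_n must be >= 1")
  }
  structure(params, class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  set <- x[!vapply(x, is.null, logical(1))]
  cat("<filter_params>\n")
  if (length(set) == 0) {
    cat("  (no thresholds set: identity filter)\n")
  } else {
    for (nm in names(set)) cat("  ", nm, " = ", format(set[[nm]]), "\n", sep = "")
  }
  invisible(x)
}
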