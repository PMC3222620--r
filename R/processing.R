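# Gene-processing stage: combine overlapping/nearby hits into single loci,
# apply quality filters, keep the best N per group, and split into groups.
# The pipeline applies these in a fixed order: merge -> filter -> best-N ->
# split, so length filters act on merged spans.

#' Merge policy for combining overlapping or nearby hits
#'
#' Two hits are merge candidates when the number of intervening bases between
#' them is at most `distance`; distance 0 still merges overlapping and
#' directly adjacent hits. By default hits are only merged when they lie on
#' the same database sequence AND carry the same group label AND the same
#' strand, which keeps later splitting and orientation-aware extraction
#' meaningful; the two `require_*` flags relax that to location-only
#' bucketing.
#'
#' @param distance Maximum intervening bases that still allows a merge.
#' @param require_same_group Only merge hits sharing a group label.
#' @param require_same_strand Only merge hits on the same strand.
#' @return A `merge_policy` object.
#' @export
merge_policy <- function(distance = 0L, require_same_group = TRUE,
                         require_same_strand = TRUE) {
  if (!is.numeric(distance) || length(distance) != 1 || is.na(distance) ||
    distance < 0) {
    abort("merge_policy: distance must be a single number >= 0")
  }
  structure(
    list(
      distance = as.integer(distance),
      require_same_group = isTRUE(require_same_group),
      require_same_strand = isTRUE(require_same_strand)
    ),
    class = "merge_policy"
  )
}

# Sum that keeps NA when every member is NA (quality fields absent for a
# dialect stay absent after merging).
na_sum <- function(x) if (all(is.na(x))) x[1] else sum(x, na.rm = TRUE)
na_max <- function(x) if (all(is.na(x))) x[1] else max(x, na.rm = TRUE)
na_min <- function(x) if (all(is.na(x))) x[1] else min(x, na.rm = TRUE)

#' Combine overlapping or nearby hits into single loci
#'
#' Within each merge bucket (same location, plus same group label and/or
#' strand as the policy requires), hits sorted by start coordinate are
#' combined whenever the gap `next_start - previous_end - 1` is at most
#' `policy$distance`. A merged hit spans the minimum start to the maximum
#' end; `merged_count` sums over members, mismatch and gap counts sum,
#' bit score takes the maximum and E-value the minimum of the members, so
#' quality filters remain meaningful after merging. The output is sorted by
#' (location, seq_start) and is closed under the merge condition: merging
#' again changes nothing.
#'
#' @param hits A hit tibble.
#' @param policy A [merge_policy()], or a single number taken as the merge
#'   distance with default bucketing.
#' @return A hit tibble of merged loci.
#' @examples
#' hits <- new_hit_tbl(
#'   hit_id = c("a", "b"), location = "chr1",
#'   seq_start = c(100L, 250L), seq_end = c(200L, 400L),
#'   strand = "+", group_label = "TE1"
#' )
#' merge_hits(hits, merge_policy(distance = 100))
#' @export
merge_hits <- function(hits, policy = merge_policy()) {
  if (is.numeric(policy)) policy <- merge_policy(distance = policy)
  stopifnot(inherits(policy, "merge_policy"))
  validate_hits(hits)
  dialect <- hit_dialect(hits)
  if (nrow(hits) == 0) {
    return(hits)
  }

  bucket_vars <- c(
    "location",
    if (policy$require_same_group) "group_label",
    if (policy$require_same_strand) "strand"
  )
  d <- policy$distance

  merged <- hits |>
    dplyr::arrange(.data$location, .data$seq_start, .data$seq_end) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(bucket_vars))) |>
    dplyr::mutate(
      .reach = cummax(dplyr::lag(as.numeric(.data$seq_end), default = -Inf)),
      .cluster = cumsum(.data$seq_start - .data$.reach - 1 > d)
    ) |>
    dplyr::group_by(.data$.cluster, .add = TRUE) |>
    dplyr::summarise(
      hit_id = .data$hit_id[1],
      seq_start = min(.data$seq_start),
      seq_end = max(.data$seq_end),
      strand = .data$strand[1],
      group_label = .data$group_label[1],
      mismatches = na_sum(.data$mismatches),
      gaps = na_sum(.data$gaps),
      e_value = na_min(.data$e_value),
      bit_score = na_max(.data$bit_score),
      merged_count = sum(.data$merged_count),
      .n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(seq_length = .data$seq_end - .data$seq_start + 1L) |>
    dplyr::arrange(.data$location, .data$seq_start, .data$seq_end)

  # Freshly merged loci get coordinate-accurate ids; untouched hits keep
  # theirs. Uniqueness is then re-established across the whole run.
  new_id <- merged$.n_members > 1L
  base <- merged$hit_id
  base[new_id] <- make_hit_id(
    merged$group_label[new_id], merged$location[new_id],
    merged$seq_start[new_id], merged$seq_end[new_id]
  )
  merged$hit_id <- dedupe_hit_ids(base)
  merged <- dplyr::select(merged, dplyr::all_of(HIT_COLUMNS))
  attr(merged, "dialect") <- dialect
  validate_hits(merged)
  merged
}

# Fields a threshold needs, used to reject score filters on dialects that do
# not report scores.
FILTER_FIELD_NEEDS <- c(
  max_gaps = "gaps", max_mismatches = "mismatches",
  min_bit_score = "bit_score", max_e_value = "e_value"
)

check_filter_dialect <- function(params, dialect) {
  if (is.null(dialect)) {
    return(invisible(NULL))
  }
  have <- DIALECT_FIELDS[[dialect]]
  for (nm in names(FILTER_FIELD_NEEDS)) {
    if (!is.null(params[[nm]]) && !FILTER_FIELD_NEEDS[[nm]] %in% have) {
      abort(
        paste0(
          "configuration error: threshold `", nm, "` requires the ",
          FILTER_FIELD_NEEDS[[nm]], " field, which the '", dialect,
          "' dialect does not report"
        ),
        class = "tehits_config_error"
      )
    }
  }
  invisible(NULL)
}

#' Apply quality-control thresholds to a hit table
#'
#' A hit survives iff every set threshold passes: `seq_length` within
#' `[min_length, max_length]`, `gaps <= max_gaps`,
#' `mismatches <= max_mismatches`, `bit_score >= min_bit_score`,
#' `e_value <= max_e_value`. Input order is preserved. Supplying a threshold
#' on a field the hit dialect does not report is a configuration error, not a
#' silent pass. An empty `filter_params()` is the identity.
#'
#' @param hits A hit tibble.
#' @param params A [filter_params()] object.
#' @return The surviving hits, in input order.
#' @export
apply_filters <- function(hits, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  validate_hits(hits)
  check_filter_dialect(params, hit_dialect(hits))
  keep <- rep(TRUE, nrow(hits))
  if (!is.null(params$min_length)) keep <- keep & hits$seq_length >= params$min_length
  if (!is.null(params$max_length)) keep <- keep & hits$seq_length <= params$max_length
  if (!is.null(params$max_gaps)) keep <- keep & hits$gaps <= params$max_gaps
  if (!is.null(params$max_mismatches)) keep <- keep & hits$mismatches <= params$max_mismatches
  if (!is.null(params$min_bit_score)) keep <- keep & hits$bit_score >= params$min_bit_score
  if (!is.null(params$max_e_value)) keep <- keep & hits$e_value <= params$max_e_value
  out <- hits[which(keep), , drop = FALSE]
  attr(out, "dialect") <- hit_dialect(hits)
  out
}

#' Keep only the N best hits per group by E-value
#'
#' Within each group label the `n` hits with the smallest E-value are kept;
#' ties are broken by larger bit score, then by input order. Relative input
#' order is preserved among survivors. Requires the BLAST dialect (the only
#' one reporting E-values); anything else is a configuration error.
#'
#' @param hits A hit tibble carrying E-values.
#' @param n Number of hits to keep per group, at least 1.
#' @return The surviving hits, in input order.
#' @export
select_best <- function(hits, n) {
  validate_hits(hits)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    abort("select_best: n must be a single integer >= 1")
  }
  dialect <- hit_dialect(hits)
  if ((!is.null(dialect) && dialect != "blast") ||
    (nrow(hits) > 0 && all(is.na(hits$e_value)))) {
    abort(
      "configuration error: best-N selection requires E-values (BLAST dialect)",
      class = "tehits_config_error"
    )
  }
  if (nrow(hits) == 0) {
    return(hits)
  }
  idx <- seq_len(nrow(hits))
  ord <- order(hits$e_value, -hits$bit_score, idx)
  rank_in_group <- stats::ave(
    seq_along(ord), hits$group_label[ord],
    FUN = seq_along
  )
  keep_idx <- sort(idx[ord][rank_in_group <= n])
  out <- hits[keep_idx, , drop = FALSE]
  attr(out, "dialect") <- dialect
  out
}

# Class/family component of a RepeatMasker group label ("name#class/family").
family_of <- function(group_label) sub("^[^#]*#", "", group_label)
element_of <- function(group_label) sub("#.*$", "", group_label)

#' Split hits into groups by query or by repeat class/family
#'
#' `by_query` keys groups on the full group label (BLAST query id, e-PCR
#' marker, or RepeatMasker `element#class/family` label); `by_type` keys on
#' the class/family component of RepeatMasker labels and is a configuration
#' error for dialects without class/family information. Every hit lands in
#' exactly one group, a group exists for every unique key, and within-group
#' order follows input order.
#'
#' @param hits A hit tibble.
#' @param mode `"by_query"` or `"by_type"`.
#' @return A named list of hit tibbles, keyed by group.
#' @export
split_hits <- function(hits, mode = c("by_query", "by_type")) {
  mode <- match.arg(mode)
  validate_hits(hits)
  dialect <- hit_dialect(hits)
  if (mode == "by_type" && !is.null(dialect) && dialect != "repeatmasker") {
    abort(
      "configuration error: by_type splitting requires class/family labels (RepeatMasker dialect)",
      class = "tehits_config_error"
    )
  }
  if (nrow(hits) == 0) {
    return(structure(list(), names = character(0)))
  }
  keys <- if (mode == "by_query") hits$group_label else family_of(hits$group_label)
  groups <- lapply(split(seq_len(nrow(hits)), factor(keys, levels = unique(keys))),
    function(i) {
      g <- hits[i, , drop = FALSE]
      attr(g, "dialect") <- dialect
      g
    }
  )
  groups
}
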