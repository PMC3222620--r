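two_hits <- function(s1, e1, s2, e2) {
  new_hit_tbl(
    hit_id = c("a", "b"), location = "chr1",
    seq_start = c(s1, s2), seq_end = c(e1, e2),
    strand = "+", group_label = "TE1",
    mismatches = c(3L, 4L), gaps = c(1L, 0L),
    e_value = c(1e-10, 1e-20), bit_score = c(100, 150),
    dialect = "blast"
  )
}

test_that("hits within the merge distance combine into one locus", {
  m <- merge_hits(two_hits(100, 200, 250, 400), merge_policy(distance = 100))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$seq_start, m$seq_end), c(100L, 400L))
  expect_equal(m$merged_count, 2L)
  # scores aggregate so filters stay meaningful after merging
  expect_equal(m$mismatches, 7L)
  expect_equal(m$gaps, 1L)
  expect_equal(m$bit_score, 150)
  expect_equal(m$e_value, 1e-20)

  adjacent <- merge_hits(two_hits(100, 200, 201, 300), merge_policy(distance = 0))
  expect_equal(nrow(adjacent), 1L)
  expect_equal(c(adjacent$seq_start, adjacent$seq_end), c(100L, 300L))

  far <- merge_hits(two_hits(100, 200, 400, 500), merge_policy(distance = 100))
  expect_equal(nrow(far), 2L)
})

test_that("merging respects group and strand buckets unless relaxed", {
  h <- two_hits(100, 200, 210, 300)
  h$group_label <- c("TE1", "TE2")
  expect_equal(nrow(merge_hits(h, merge_policy(distance = 50))), 2L)
  relaxed <- merge_policy(distance = 50, require_same_group = FALSE)
  expect_equal(nrow(merge_hits(h, relaxed)), 1L)
  h2 <- two_hits(100, 200, 210, 300)
  h2$strand <- c("+", "-")
  expect_equal(nrow(merge_hits(h2, merge_policy(distance = 50))), 2L)
})

test_that("merge matches the brute-force fixpoint oracle and is idempotent", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      hits <- random_hits(sample(2:30, 1))
      d <- sample(0:300, 1)
      got <- merge_hits(hits, merge_policy(distance = d))
      want <- oracle_merge(as.data.frame(hits), d)
      expect_equal(
        got[, c("location", "group_label", "strand", "seq_start", "seq_end", "merged_count")],
        tibble::as_tibble(want[, c("location", "group_label", "strand", "seq_start", "seq_end", "merged_count")]),
        ignore_attr = TRUE
      )
      again <- merge_hits(got, merge_policy(distance = d))
      expect_equal(hit_tuple(again), hit_tuple(got))
      expect_true(all(coverage_set(hits) %in% coverage_set(got)))
      expect_setequal(
        coverage_set(merge_hits(hits, merge_policy(distance = 0))),
        coverage_set(hits)
      )
    }
  })
})

test_that("filters drop exactly the hits outside every set threshold", {
  h <- random_hits(1)
  h$seq_length <- 150L
  h$seq_end <- h$seq_start + 149L
  expect_equal(nrow(apply_filters(h, filter_params(min_length = 100))), 1L)
  h$seq_end <- h$seq_start + 79L
  h$seq_length <- 80L
  expect_equal(nrow(apply_filters(h, filter_params(min_length = 100))), 0L)

  hb <- random_hits(1)
  hb$bit_score <- 95
  expect_equal(nrow(apply_filters(hb, filter_params(min_bit_score = 100))), 0L)
  hb$bit_score <- 120
  expect_equal(nrow(apply_filters(hb, filter_params(min_bit_score = 100))), 1L)

  many <- withr::with_seed(5, random_hits(30))
  expect_equal(apply_filters(many, filter_params()), many)
})

test_that("score thresholds on scoreless dialects are configuration errors", {
  rm_hits <- withr::with_seed(6, random_hits(5, dialect = "repeatmasker"))
  expect_error(apply_filters(rm_hits, filter_params(min_bit_score = 10)),
    class = "tehits_config_error"
  )
  expect_error(apply_filters(rm_hits, filter_params(max_mismatches = 3)),
    class = "tehits_config_error"
  )
  # length thresholds are always available
  expect_silent(apply_filters(rm_hits, filter_params(min_length = 10)))
  expect_error(select_best(rm_hits, 2), class = "tehits_config_error")
})

test_that("best-N keeps the smallest E-values per group, ties by bit score", {
  h <- new_hit_tbl(
    hit_id = letters[1:3], location = "chr1",
    seq_start = c(1L, 100L, 200L), seq_end = c(50L, 150L, 250L),
    strand = "+", group_label = "TE1",
    mismatches = 0L, gaps = 0L,
    e_value = c(1e-10, 1e-5, 1e-20), bit_score = c(50, 40, 60),
    dialect = "blast"
  )
  kept <- select_best(h, 2)
  expect_setequal(kept$e_value, c(1e-20, 1e-10))
  expect_equal(kept$hit_id, c("a", "c")) # input order preserved

  expect_equal(select_best(h, 10), h)

  h2 <- withr::with_seed(8, random_hits(10, n_groups = 2))
  expect_equal(nrow(select_best(h2, 1)), length(unique(h2$group_label)))

  ties <- h
  ties$e_value <- rep(1e-8, 3)
  expect_equal(select_best(ties, 1)$bit_score, 60)
})

test_that("splitting partitions hits by query or by class/family", {
  h <- withr::with_seed(9, random_hits(12, n_groups = 3))
  g <- split_hits(h, "by_query")
  expect_setequal(names(g), unique(h$group_label))
  expect_equal(sum(vapply(g, nrow, integer(1))), nrow(h))
  expect_false(anyDuplicated(unlist(lapply(g, `[[`, "hit_id"))) > 0)

  rm_hits <- new_hit_tbl(
    hit_id = letters[1:3], location = "chr1",
    seq_start = c(1L, 100L, 200L), seq_end = c(50L, 150L, 250L),
    strand = "+",
    group_label = c("L1MA4#LINE/L1", "L1PA7#LINE/L1", "AluY#SINE/Alu"),
    dialect = "repeatmasker"
  )
  byt <- split_hits(rm_hits, "by_type")
  expect_equal(vapply(byt, nrow, integer(1)), c("LINE/L1" = 2L, "SINE/Alu" = 1L))

  expect_error(split_hits(h, "by_type"), class = "tehits_config_error")
  expect_length(split_hits(empty_hit_tbl("blast"), "by_query"), 0)
})
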