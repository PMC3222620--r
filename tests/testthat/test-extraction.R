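local_store <- function(seqs) {
  build_store(write_test_fasta(seqs))
}

hit_on <- function(location, s, e, strand = "+", label = "TE1",
                   dialect = "blast") {
  new_hit_tbl(
    hit_id = make_hit_id(label, location, s, e), location = location,
    seq_start = as.integer(s), seq_end = as.integer(e), strand = strand,
    group_label = label, dialect = dialect
  )
}

test_that("the store reports lengths and slices match the file residues", {
  chr2 <- withr::with_seed(21, paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))
  chr1 <- withr::with_seed(22, paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = ""))
  store <- local_store(list(chr1 = chr1, chr2 = chr2))
  expect_equal(store_lengths(store), c(chr1 = 5000L, chr2 = 300L))
  expect_equal(fetch_sequence(store, "chr2", 1, 300), chr2)
  expect_equal(fetch_sequence(store, "chr1", 101, 160), substr(chr1, 101, 160))
  expect_error(fetch_sequence(store, "chr1", 0, 10), "out of bounds")
  expect_error(fetch_sequence(store, "chr1", 1, 5001), "out of bounds")
})

test_that("duplicate names and non-FASTA content are fatal at indexing", {
  f <- tempfile()
  writeLines(c(">chr1", "ACGT", ">chr1", "TTTT"), f)
  expect_error(build_store(f), "duplicate sequence name")
  f2 <- tempfile()
  writeLines("this is not fasta", f2)
  expect_error(build_store(f2), "not a FASTA")
  f3 <- tempfile()
  file.create(f3)
  expect_error(build_store(f3), "no '>' headers")
})

test_that("buffered coordinates extend by the flank and clamp at the ends", {
  store <- local_store(list(chr1 = strrep("ACGTT", 1000)))
  h <- hit_on("chr1", 1001, 1200)
  b <- buffered_coordinates(h, 200, store)
  expect_equal(c(b$extract_start, b$extract_end), c(801L, 1400L))
  expect_equal(b$extract_end - b$extract_start + 1L, 600L)

  edge <- buffered_coordinates(hit_on("chr1", 50, 150), 200, store)
  expect_equal(c(edge$extract_start, edge$extract_end), c(1L, 350L))

  ident <- buffered_coordinates(h, 0, store)
  expect_equal(c(ident$extract_start, ident$extract_end), c(1001L, 1200L))
})

test_that("extracted coordinates never leave the sequence for any buffer", {
  store <- local_store(list(s1 = strrep("ACGT", 100))) # 400 nt
  withr::with_seed(23, {
    for (i in 1:20) {
      s <- sample.int(350, 1)
      h <- hit_on("s1", s, min(400L, s + sample.int(50, 1)))
      buf <- sample.int(4000, 1) # up to 10x the sequence length
      b <- buffered_coordinates(h, buf, store)
      expect_gte(b$extract_start, 1L)
      expect_lte(b$extract_end, 400L)
      r <- extract_hits(h, store, buffer = buf)
      expect_equal(nchar(r$sequence), r$extract_end - r$extract_start + 1L)
    }
  })
})

test_that("unknown locations are skipped with a warning, run continues", {
  store <- local_store(list(chr1 = strrep("ACGT", 50)))
  h <- dplyr::bind_rows(hit_on("chr1", 1, 10), hit_on("chrX", 1, 10))
  attr(h, "dialect") <- "blast"
  expect_warning(b <- buffered_coordinates(h, 0, store), "chrX")
  expect_equal(b$location, "chr1")
})

test_that("minus-strand extracts are reverse-complemented by default", {
  store <- local_store(list(chr1 = "GGACGTTGG"))
  plus <- extract_hits(hit_on("chr1", 3, 7, "+"), store)
  expect_equal(plus$sequence, "ACGTT")
  minus <- extract_hits(hit_on("chr1", 3, 7, "-"), store)
  expect_equal(minus$sequence, "AACGT")
  genomic <- extract_hits(hit_on("chr1", 3, 7, "-"), store, revcomp_minus = FALSE)
  expect_equal(genomic$sequence, "ACGTT")
  # involution: undoing the reverse complement recovers the store slice
  expect_equal(rc_chr(rc_chr(minus$sequence)), minus$sequence)
  expect_equal(rc_chr(minus$sequence), plus$sequence)
})

test_that("planted fixture copies extract back exactly", {
  fx <- generate_fixture(
    n_insertions = 8, divergence = 0, seed = 31,
    n_sequences = 2, seq_length = 6000
  )
  store <- build_store(fx$genome)
  hits <- parse_hit_file(fx$blast, "blast")
  rec <- dplyr::arrange(extract_hits(hits, store), location, seq_start)
  truth <- dplyr::arrange(fx$truth, sequence, start)
  expect_equal(rec$sequence, truth$copy_seq)
  expect_equal(rec$sequence, unname(fx$elements[truth$element]))
})

test_that("FASTA output round-trips byte-identically with wrapped lines", {
  store <- local_store(list(chr1 = withr::with_seed(
    24, paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  )))
  h <- dplyr::bind_rows(
    hit_on("chr1", 10, 200), hit_on("chr1", 300, 450, "-"), hit_on("chr1", 500, 640)
  )
  attr(h, "dialect") <- "blast"
  h$hit_id <- dedupe_hit_ids(h$hit_id)
  rec <- extract_hits(h, store)
  out <- tempfile(fileext = ".fas")
  expect_equal(write_fasta(rec, out), 3L)
  lines <- readLines(out)
  expect_equal(sum(startsWith(lines, ">")), 3L)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- Biostrings::readDNAStringSet(out)
  expect_equal(unname(as.character(back)), rec$sequence)
  expect_equal(
    sub("\\s.*$", "", names(back)), rec$hit_id
  )

  empty <- rec[0, ]
  out2 <- tempfile()
  expect_warning(n <- write_fasta(empty, out2), "empty")
  expect_equal(n, 0L)
  expect_true(file.exists(out2))
})

test_that("split FASTA files partition the unsplit output and honor qseq", {
  fx <- generate_fixture(n_insertions = 12, divergence = 0, seed = 32)
  store <- build_store(fx$genome)
  hits <- parse_hit_file(fx$repeatmasker, "repeatmasker")
  groups <- split_hits(hits, "by_query")
  outdir <- withr::local_tempdir()
  res <- write_split_fasta(groups, store, outdir)
  expect_setequal(res$key, names(groups))
  # keys carry '#' and '/' which must not reach the filesystem
  expect_false(any(grepl("[#/]", basename(res$file))))
  unsplit <- extract_hits(hits, store)
  split_records <- unlist(lapply(res$file, function(f) {
    as.character(Biostrings::readDNAStringSet(f))
  }))
  expect_setequal(unname(split_records), unsplit$sequence)
  expect_equal(sum(res$n_records), nrow(unsplit))

  res_q <- write_split_fasta(groups, store, withr::local_tempdir(), qseq = fx$library)
  expect_true(all(res_q$n_query == 1L))
  first <- Biostrings::readDNAStringSet(res_q$file[1])[1]
  expect_equal(names(first), element_of(res_q$key[1]))

  # a group with no matching query warns but still writes
  qf <- tempfile(fileext = ".fas")
  writeLines(c(">SOMETHINGELSE", "ACGT"), qf)
  expect_warning(
    write_split_fasta(groups[1], store, withr::local_tempdir(), qseq = qf),
    "no query sequence"
  )
})

test_that("hit tables serialize back into their own dialect", {
  h <- dplyr::bind_rows(
    parse_blast_line("TE1\tchr1\t97.50\t200\t5\t1\t1\t200\t1001\t1200\t1e-50\t180.0"),
    parse_blast_line("TE2\tchr1\t99.00\t100\t1\t0\t1\t100\t900\t801\t1e-30\t120.0")
  )
  attr(h, "dialect") <- "blast"
  out <- tempfile()
  expect_equal(write_hit_table(h, out = out), 2L)
  lines <- readLines(out)
  expect_length(lines, 2L)
  # minus-strand hit re-inverts subject coordinates
  f2 <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(f2[9:10]), c(900L, 801L))

  merged <- merge_hits(
    dplyr::bind_rows(
      parse_blast_line("TE1\tchr1\t97.50\t100\t2\t0\t1\t100\t100\t199\t1e-20\t90.0"),
      parse_blast_line("TE1\tchr1\t97.50\t100\t2\t0\t1\t100\t230\t329\t1e-20\t90.0")
    ) |> structure(dialect = "blast"),
    merge_policy(distance = 50)
  )
  out3 <- tempfile()
  write_hit_table(merged, out = out3)
  raw <- readLines(out3)
  expect_true(any(grepl("^# .*merged_count=2", raw)))
  reparsed <- parse_hit_file(out3, "blast")
  expect_equal(nrow(reparsed), 1L)
  expect_equal(c(reparsed$seq_start, reparsed$seq_end), c(100L, 329L))
})

test_that("record sampling is seeded, order-preserving and saturating", {
  recs <- withr::with_seed(25, random_hits(10))
  expect_equal(sample_records(recs, 10, seed = 7), recs)
  expect_equal(sample_records(recs, 99, seed = 7), recs)
  s1 <- sample_records(recs, 3, seed = 7)
  s2 <- sample_records(recs, 3, seed = 7)
  expect_equal(s1, s2)
  expect_equal(nrow(s1), 3L)
  expect_true(all(diff(match(s1$hit_id, recs$hit_id)) > 0))
  expect_equal(nrow(sample_records(recs, 0, seed = 7)), 0L)
})
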