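# Synthetic-fixture generator: random background scaffolds with repeat
# copies planted at recorded coordinates/strands, each copy mutated by
# substitution at a fixed per-base rate, and matching hit files in both
# dialects. The returned truth table is the oracle for extraction tests:
# at divergence 0 every buffer-0 extract must equal its planted copy.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitution-only mutation (keeps mismatch bookkeeping exact: the recorded
# count is the number of substitutions actually applied).
mutate_copy <- function(seq, rate) {
  len <- nchar(seq)
  n_mut <- stats::rbinom(1, len, rate)
  if (n_mut == 0) {
    return(list(seq = seq, positions = integer(0)))
  }
  pos <- sort(sample.int(len, n_mut))
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  list(seq = paste(chars, collapse = ""), positions = pos)
}

# A small default library spanning the repeat classes the splitter cares
# about, including one element short enough to fail a min-length 100 filter.
default_library_spec <- function() {
  tibble(
    element = c("TESTL1", "TESTHAT", "TESTALU", "TESTMIR"),
    family = c("LINE/L1", "DNA/hAT", "SINE/Alu", "SINE/MIR"),
    length = c(1200L, 800L, 300L, 80L)
  )
}

# Synthetic BLAST quality bookkeeping: divergence lowers the bit score and
# raises the E-value, so quality filters have something real to reject.
fixture_bit_score <- function(len, n_mut) pmax(1, 2 * (len - 2 * n_mut))
fixture_e_value <- function(bit) 10^(-bit / 10)

#' Generate a synthetic genome fixture with planted repeat copies
#'
#' Builds `n_sequences` random scaffolds of `seq_length` bases, plants
#' `n_insertions` element copies (cycling through the library so every
#' element is represented) at non-overlapping positions on random strands,
#' mutating each copy by substitution at rate `divergence`, and writes: the
#' genome FASTA, the element-library FASTA, a truth table listing every
#' planted locus with its mutated copy sequence, and hit files describing
#' the planted loci in both the BLAST-tabular and RepeatMasker dialects.
#' With `fragments > 1` each insertion is reported as that many hit
#' fragments separated by gaps of at most `fragment_max_gap` bases
#' (emulating indel-broken annotations); the truth table still records the
#' full locus.
#'
#' Everything is drawn under `seed`, so the same seed gives byte-identical
#' files.
#'
#' @param n_sequences Number of background scaffolds.
#' @param seq_length Length of each scaffold, in bases.
#' @param n_insertions Total planted copies across the genome.
#' @param element_library Optional FASTA of elements to plant (headers
#'   `name` or `name#class/family`); defaults to a built-in four-element
#'   library covering LINE, SINE and DNA classes.
#' @param divergence Per-base substitution rate in `[0, 1]`.
#' @param seed Integer seed.
#' @param dir Output directory (created; defaults to a fresh temp dir).
#' @param fragments Hit fragments reported per insertion (1 = whole locus).
#' @param fragment_max_gap Maximum gap between fragments, in bases.
#' @param min_spacing Minimum bases between planted copies on one scaffold,
#'   so distinct insertions never satisfy a modest merge distance.
#' @return A list with paths `genome`, `library`, `blast`, `repeatmasker`,
#'   `truth_path`, the `truth` tibble, and the `elements` sequences.
#' @export
generate_fixture <- function(n_sequences = 5L, seq_length = 10000L,
                             n_insertions = 20L, element_library = NULL,
                             divergence = 0.05, seed = 1L,
                             dir = tempfile("fixture"),
                             fragments = 1L, fragment_max_gap = 100L,
                             min_spacing = 300L) {
  stopifnot(divergence >= 0, divergence <= 1, fragments >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  withr::with_seed(as.integer(seed), {
    if (is.null(element_library)) {
      spec <- default_library_spec()
      elements <- stats::setNames(
        vapply(spec$length, random_dna, character(1)), spec$element
      )
      families <- stats::setNames(spec$family, spec$element)
    } else {
      lib <- Biostrings::readDNAStringSet(element_library)
      hdr <- sub("\\s.*$", "", names(lib))
      elements <- stats::setNames(as.character(lib), element_of(hdr))
      families <- stats::setNames(
        ifelse(grepl("#", hdr), family_of(hdr), "Unknown"), element_of(hdr)
      )
    }

    seq_names <- paste0("scaf", seq_len(n_sequences))
    genome <- stats::setNames(
      vapply(rep(seq_length, n_sequences), random_dna, character(1)),
      seq_names
    )

    occupied <- stats::setNames(
      rep(list(tibble(start = integer(0), end = integer(0))), n_sequences),
      seq_names
    )
    truth_rows <- vector("list", n_insertions)
    for (i in seq_len(n_insertions)) {
      el <- names(elements)[(i - 1L) %% length(elements) + 1L]
      len <- nchar(elements[[el]])
      placed <- FALSE
      for (try in 1:500) {
        sq <- sample(seq_names, 1)
        if (seq_length - len + 1L < 1L) break
        s <- sample.int(seq_length - len + 1L, 1)
        e <- s + len - 1L
        occ <- occupied[[sq]]
        if (all(e + min_spacing < occ$start | s - min_spacing > occ$end)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0(
          "infeasible fixture packing: n_sequences=", n_sequences,
          ", seq_length=", seq_length, ", n_insertions=", n_insertions,
          ", element length=", len, ", min_spacing=", min_spacing
        ))
      }
      occupied[[sq]] <- dplyr::bind_rows(occupied[[sq]], tibble(start = s, end = e))
      strand <- sample(c("+", "-"), 1)
      mut <- mutate_copy(elements[[el]], divergence)
      insert <- if (strand == "+") mut$seq else revcomp_chr(mut$seq)
      substr(genome[[sq]], s, e) <- insert
      truth_rows[[i]] <- tibble(
        sequence = sq, start = s, end = e, strand = strand,
        element = el, family = unname(families[[el]]),
        mismatches = length(mut$positions),
        mut_positions = list(mut$positions),
        copy_seq = mut$seq
      )
    }
    truth <- dplyr::bind_rows(truth_rows) |>
      dplyr::arrange(.data$sequence, .data$start)

    frag <- fragment_truth(truth, fragments, fragment_max_gap)

    paths <- list(
      genome = file.path(dir, "genome.fas"),
      library = file.path(dir, "library.fas"),
      truth_path = file.path(dir, "truth.tsv"),
      blast = file.path(dir, "hits_blast.out"),
      repeatmasker = file.path(dir, "hits_rm.out")
    )
    gset <- Biostrings::DNAStringSet(genome)
    Biostrings::writeXStringSet(gset, paths$genome, width = 60L)
    lset <- Biostrings::DNAStringSet(elements)
    Biostrings::writeXStringSet(lset, paths$library, width = 60L)

    utils::write.table(
      dplyr::select(truth, -"mut_positions"),
      paths$truth_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    writeLines(fixture_blast_lines(frag), paths$blast)
    writeLines(fixture_rm_lines(frag), paths$repeatmasker)

    c(paths, list(truth = truth, fragments = frag, elements = elements, dir = dir))
  })
}

# Break each planted locus into `fragments` reported hits with gaps of
# 10..max_gap bases; mismatch counts are attributed to the fragment the
# mutated base falls in. Loci too short to fragment stay whole.
fragment_truth <- function(truth, fragments, max_gap) {
  min_frag <- 30L
  rows <- purrr::pmap(truth, function(sequence, start, end, strand, element,
                                      family, mismatches, mut_positions,
                                      copy_seq) {
    len <- end - start + 1L
    k <- fragments
    gaps <- if (k > 1) sample(10:max_gap, k - 1, replace = TRUE) else integer(0)
    while (k > 1 && len - sum(gaps) < min_frag * k) {
      k <- k - 1L
      gaps <- if (k > 1) sample(10:max_gap, k - 1, replace = TRUE) else integer(0)
    }
    extra <- len - sum(gaps) - min_frag * k
    add <- if (extra > 0 && k > 1) {
      tabulate(sample.int(k, extra, replace = TRUE), k)
    } else if (k == 1) {
      extra
    } else {
      rep(0L, k)
    }
    frag_len <- min_frag + add
    fs <- start + cumsum(c(0L, utils::head(frag_len, -1) + gaps))
    fe <- fs + frag_len - 1L
    # genome positions of the applied substitutions
    mut_g <- if (strand == "+") start - 1L + mut_positions else end + 1L - mut_positions
    locus <- c(start, end)
    tibble(
      sequence = sequence, start = fs, end = fe, strand = strand,
      element = element, family = family,
      mismatches = vapply(
        seq_len(k),
        function(j) sum(mut_g >= fs[j] & mut_g <= fe[j]), integer(1)
      ),
      locus_start = locus[1], locus_end = locus[2]
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$sequence, .data$start)
}

fixture_blast_lines <- function(frag) {
  len <- frag$end - frag$start + 1L
  bit <- fixture_bit_score(len, frag$mismatches)
  minus <- frag$strand == "-"
  paste(
    frag$element, frag$sequence, fmt_pct(100 * (1 - frag$mismatches / len)),
    len, frag$mismatches, 0L, 1L, len,
    ifelse(minus, frag$end, frag$start), ifelse(minus, frag$start, frag$end),
    fmt_evalue(fixture_e_value(bit)), sprintf("%.1f", bit),
    sep = "\t"
  )
}

fixture_rm_lines <- function(frag) {
  len <- frag$end - frag$start + 1L
  header <- c(
    "   SW   perc perc perc  query         position in query      matching  repeat           position in repeat",
    "score   div. del. ins.  sequence      begin end      (left)  repeat    class/family   begin  end    (left)  ID",
    ""
  )
  c(header, paste(
    10L * (len - frag$mismatches),
    sprintf("%.1f", 100 * frag$mismatches / len), "0.0", "0.0",
    frag$sequence, frag$start, frag$end, "(0)",
    ifelse(frag$strand == "-", "C", "+"),
    frag$element, frag$family, 1L, len, "(0)", seq_len(nrow(frag))
  ))
}
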