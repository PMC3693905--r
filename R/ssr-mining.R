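#' Find perfect SSR arrays in nucleotide sequences
#'
#' Scans sequences for maximal perfect tandem repeats of di- to
#' hexanucleotide motifs, keeping arrays that meet class-specific minimum
#' repeat counts (by default at least six repeats for dinucleotide motifs and
#' at least five for tri- through hexanucleotide motifs).
#'
#' Coordinates are 0-based, half-open; `end - start` always equals
#' `repeats * nchar(motif)` (a trailing partial repeat is not counted, and the
#' array is anchored at the leftmost base of the maximal perfect region).
#' An array whose motif is itself a repetition of a shorter motif (e.g.
#' `ATAT`, or a mononucleotide run seen at even period) is reported once,
#' under its shortest-period representation; arrays of different minimal
#' periods may overlap and are then all reported.  `N` (or any non-ACGT
#' character) interrupts arrays.
#'
#' @param sequences Named character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet` (see [read_fasta()]).
#' @param min_repeats Named integer vector of per-class repeat thresholds with
#'   names `di`, `tri`, `tetra`, `penta`, `hexa`.
#'
#' @return A tibble with columns `sequence_id`, `start`, `end` (0-based
#'   half-open), `motif`, `canonical_motif`, `motif_class`, `repeats`,
#'   ordered left to right within each sequence.
#' @examples
#' find_ssr_arrays(c(s1 = "GGATATATATATATGG"))
#' @export
find_ssr_arrays <- function(sequences,
                            min_repeats = c(di = 6L, tri = 5L, tetra = 5L,
                                            penta = 5L, hexa = 5L)) {
  sequences <- as_sequence_vector(sequences)
  classes <- c("di", "tri", "tetra", "penta", "hexa")
  stopifnot(all(classes %in% names(min_repeats)))
  out <- purrr::imap(sequences, function(s, id) {
    scan_one_sequence(toupper(s), id, min_repeats)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(sequence_id = character(), start = integer(),
                  end = integer(), motif = character(),
                  canonical_motif = character(), motif_class = character(),
                  repeats = integer()))
  }
  dplyr::arrange(res, .data$sequence_id, .data$start, .data$motif_class)
}

scan_one_sequence <- function(s, id, min_repeats) {
  n <- nchar(s)
  if (n == 0) stop("empty sequence: ", id, call. = FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  ok <- ch %in% c("A", "C", "G", "T")
  if (!any(ok) && any(!ch %in% c("A", "C", "G", "T", "N"))) {
    stop("malformed sequence alphabet in ", id, call. = FALSE)
  }
  class_names <- c("2" = "di", "3" = "tri", "4" = "tetra",
                   "5" = "penta", "6" = "hexa")
  rows <- list()
  for (p in 2:6) {
    if (n < 2 * p) next
    thr <- min_repeats[[class_names[[as.character(p)]]]]
    m <- n - p
    eq <- ch[seq_len(m)] == ch[seq_len(m) + p] & ok[seq_len(m)] & ok[seq_len(m) + p]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (k in keep) {
      region_len <- r$lengths[k] + p           # length of perfect stretch
      reps <- region_len %/% p
      if (reps < thr) next
      i <- starts[k]                           # 1-based region start
      motif <- substr(s, i, i + p - 1L)
      if (fundamental_period(motif) < p) next  # shortest-period rule
      rows[[length(rows) + 1L]] <- tibble(
        sequence_id = id,
        start = i - 1L,
        end = i - 1L + reps * p,
        motif = motif,
        canonical_motif = canonical_motif(motif),
        motif_class = class_names[[as.character(p)]],
        repeats = as.integer(reps)
      )
    }
  }
  dplyr::bind_rows(rows)
}

fundamental_period <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0) {
      unit <- substr(motif, 1, p)
      if (strrep(unit, n %/% p) == motif) return(p)
    }
  }
  n
}

as_sequence_vector <- function(sequences) {
  if (inherits(sequences, "DNAStringSet") || inherits(sequences, "XStringSet")) {
    out <- as.character(sequences)
    if (is.null(names(out))) names(out) <- as.character(seq_along(out))
    return(out)
  }
  stopifnot(is.character(sequences))
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  sequences
}

#' Canonical form of an SSR motif
#'
#' The lexicographically smallest string among all rotations of a motif and
#' of its reverse complement, so that all equivalent phases and strands of a
#' repeat aggregate under one key (e.g. `TA`, `AT` and their complements all
#' map to `AT`).
#'
#' @param motif Character vector of motifs, 2-6 nt, ACGT alphabet.
#' @return Character vector of canonical motifs.  Idempotent.
#' @examples
#' canonical_motif(c("TA", "GAA"))  # "AT", "AAG"
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif))
  vapply(motif, function(m) {
    m <- toupper(m)
    n <- nchar(m)
    if (n < 2 || n > 6 || grepl("[^ACGT]", m)) {
      stop("motif must be 2-6 nt over ACGT: ", m, call. = FALSE)
    }
    rc <- revcomp(m)
    rots <- function(x) {
      vapply(seq_len(n), function(i) {
        paste0(substr(x, i, n), substr(x, 1, i - 1))
      }, character(1))
    }
    min(c(rots(m), rots(rc)))
  }, character(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Summarise mined SSR arrays
#'
#' Per-class array counts and a repeat-count histogram, as typically reported
#' for an SSR mining campaign (counts by motif class; repeat numbers bounded
#' below by the class thresholds).
#'
#' @param arrays A tibble from [find_ssr_arrays()].
#' @return A list with `class_counts` (tibble: `motif_class`, `n`) and
#'   `repeat_histogram` (tibble: `repeats`, `n`), plus `n_arrays` and
#'   `mode_repeats`.
#' @export
motif_summary <- function(arrays) {
  classes <- c("di", "tri", "tetra", "penta", "hexa")
  cc <- arrays %>%
    dplyr::count(motif_class = factor(.data$motif_class, levels = classes),
                 .drop = FALSE) %>%
    dplyr::mutate(motif_class = as.character(.data$motif_class))
  rh <- dplyr::count(arrays, .data$repeats)
  list(
    n_arrays = nrow(arrays),
    class_counts = cc,
    repeat_histogram = rh,
    mode_repeats = if (nrow(rh)) rh$repeats[which.max(rh$n)] else NA_integer_
  )
}

#' Primer feasibility screen for an SSR array
#'
#' A design-free feasibility check standing in for full thermodynamic primer
#' design: an array passes when each flank can host a 20-27 nt primer (flank
#' of at least 27 nt on both sides) and some amplicon spanning the array fits
#' the target length window (95-395 bp by default).  The amplicon includes
#' both primers; with primers of minimum length 20 placed anywhere in the
#' flanks, achievable amplicon lengths range from `array length + 40` up to
#' `array length + both flank lengths` (capped by the window).  Melting
#' temperature is recorded as metadata only and never evaluated.
#'
#' @param arrays Tibble from [find_ssr_arrays()] (needs `sequence_id`,
#'   `start`, `end`).
#' @param seq_lengths Named integer vector of sequence lengths (nt).
#' @param amplicon_range Length-2 numeric, allowed amplicon lengths in bp.
#' @param primer_range Length-2 numeric, allowed primer lengths in nt.
#' @param tm Target melting temperature, degrees C (metadata only).
#' @return The input tibble with columns `left_flank`, `right_flank`,
#'   `left_flank_ok`, `right_flank_ok`, `candidate_amplicon_length` (the
#'   shortest achievable in-window amplicon, `NA` if none), `tm` and `passes`.
#' @export
primer_feasibility <- function(arrays, seq_lengths,
                               amplicon_range = c(95, 395),
                               primer_range = c(20, 27),
                               tm = 60) {
  stopifnot(all(arrays$sequence_id %in% names(seq_lengths)))
  len <- unname(seq_lengths[arrays$sequence_id])
  if (any(arrays$end > len | arrays$start < 0)) {
    stop("array coordinates outside sequence bounds", call. = FALSE)
  }
  left <- arrays$start
  right <- len - arrays$end
  array_len <- arrays$end - arrays$start
  pmin_len <- primer_range[1]
  pmax_len <- primer_range[2]
  amp_lo <- pmax(amplicon_range[1], array_len + 2 * pmin_len)
  amp_hi <- pmin(amplicon_range[2], array_len + left + right)
  arrays %>%
    dplyr::mutate(
      left_flank = left,
      right_flank = right,
      left_flank_ok = left >= pmax_len,
      right_flank_ok = right >= pmax_len,
      candidate_amplicon_length = ifelse(amp_lo <= amp_hi, amp_lo, NA_real_),
      tm = tm,
      passes = .data$left_flank_ok & .data$right_flank_ok & amp_lo <= amp_hi
    )
}

#' In silico PCR with exact primer matching
#'
#' Predicts amplicons for a primer pair against a sequence database under
#' exact-match semantics (0 mismatches): one primer must match the plus
#' strand and the other the minus strand downstream of it (convergent
#' orientation).  The product interval runs from the first base of the
#' upstream primer site to the last base of the downstream primer site, so
#' the product length includes both primer lengths (two primers planted with
#' 200 bp between their inner ends yield `200 + nchar(fwd) + nchar(rev)`).
#' Both primer-role orientations are enumerated and duplicate intervals
#' (e.g. from palindromic primers) are removed.
#'
#' @param fwd,rev Primer sequences (character scalars).
#' @param sequences Named character vector or `DNAStringSet`.
#' @param max_length Longest product reported, bp.
#' @return Tibble: `sequence_id`, `start`, `end` (0-based half-open),
#'   `length`, `strand` (strand carrying `fwd`).
#' @export
in_silico_pcr <- function(fwd, rev, sequences, max_length = 5000) {
  sequences <- as_sequence_vector(sequences)
  fwd <- toupper(fwd); rev <- toupper(rev)
  hits <- purrr::imap(sequences, function(s, id) {
    s <- toupper(s)
    # orientation 1: fwd on plus strand, revcomp(rev) downstream
    o1 <- pair_products(s, fwd, revcomp(rev), max_length)
    # orientation 2: rev on plus strand, revcomp(fwd) downstream
    o2 <- pair_products(s, rev, revcomp(fwd), max_length)
    res <- dplyr::bind_rows(
      if (nrow(o1)) dplyr::mutate(o1, strand = "+"),
      if (nrow(o2)) dplyr::mutate(o2, strand = "-")
    )
    if (is.null(res) || nrow(res) == 0) return(NULL)
    dplyr::mutate(res, sequence_id = id, .before = 1)
  })
  res <- dplyr::bind_rows(hits)
  if (nrow(res) == 0) {
    return(tibble(sequence_id = character(), start = integer(),
                  end = integer(), length = integer(), strand = character()))
  }
  res %>%
    dplyr::distinct(.data$sequence_id, .data$start, .data$end,
                    .keep_all = TRUE) %>%
    dplyr::arrange(.data$sequence_id, .data$start)
}

pair_products <- function(s, up, down, max_length) {
  ui <- exact_matches(s, up)
  di <- exact_matches(s, down)
  if (length(ui) == 0 || length(di) == 0) return(tibble())
  grid <- expand.grid(u = ui, d = di)
  grid <- grid[grid$d >= grid$u, , drop = FALSE]
  if (nrow(grid) == 0) return(tibble())
  end <- grid$d + nchar(down) - 1L
  len <- end - grid$u + 1L
  keep <- len <= max_length & len >= nchar(up) + nchar(down)
  tibble(start = as.integer(grid$u[keep] - 1L), end = as.integer(end[keep]),
         length = as.integer(len[keep]))
}

exact_matches <- function(s, pattern) {
  m <- gregexpr(pattern, s, fixed = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Flag redundant primer pairs by shared amplicon
#'
#' Two primer pairs that amplify an identical interval in the database are
#' redundant; all but the first (by marker id) are flagged.
#'
#' @param amplicons Tibble with columns `marker_id`, `sequence_id`, `start`,
#'   `end` (one row per predicted product).
#' @return Input with a logical `redundant` column.
#' @export
flag_redundant <- function(amplicons) {
  amplicons %>%
    dplyr::group_by(.data$sequence_id, .data$start, .data$end) %>%
    dplyr::mutate(redundant = .data$marker_id != min(.data$marker_id)) %>%
    dplyr::ungroup()
}

#' Mean-quality sequence filter
#'
#' Pass/fail screen on per-base quality scores: a sequence passes when its
#' arithmetic mean phred score reaches the threshold (50 by default).  The
#' aggregate-mean interpretation is a configurable package choice; supply a
#' different `threshold` or pre-filter per-base as needed.
#'
#' @param qualities A list of numeric vectors of per-base phred scores, named
#'   by sequence.
#' @param threshold Minimum mean phred score.
#' @return Tibble: `sequence_id`, `mean_quality`, `pass`.
#' @export
quality_filter <- function(qualities, threshold = 50) {
  if (length(qualities) == 0) {
    return(tibble(sequence_id = character(), mean_quality = double(),
                  pass = logical()))
  }
  if (is.null(names(qualities)) || any(!vapply(qualities, is.numeric, TRUE))) {
    stop("qualities must be a named list of numeric vectors", call. = FALSE)
  }
  tibble(
    sequence_id = names(qualities),
    mean_quality = vapply(qualities, mean, double(1), USE.NAMES = FALSE),
    pass = .data$mean_quality >= threshold
  )
}

#' Read sequences from FASTA / FASTQ
#'
#' Thin wrappers over Biostrings readers returning the plain structures the
#' rest of the package consumes.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector of sequences.
#'   `read_fastq_qualities()`: a list with `sequences` (named character) and
#'   `qualities` (named list of integer phred vectors).
#' @export
read_fasta <- function(path) {
  as_sequence_vector(Biostrings::readDNAStringSet(path))
}

#' @rdname read_fasta
#' @export
read_fastq_qualities <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  qlist <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  names(qlist) <- names(x)
  list(sequences = as_sequence_vector(x), qualities = qlist)
}
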