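#' Read and write FASTQ files
#'
#' Thin wrappers around Biostrings FASTQ support that exchange a plain
#' data.frame of reads (`read_id`, `sequence`, `qualities` as a Phred+33
#' string), the representation used throughout the pipeline.
#'
#' @param path FASTQ file path (Sanger / Phred+33 qualities).
#' @param reads A data.frame with columns `read_id`, `sequence`, `qualities`.
#' @return `read_fastq()` returns the reads data.frame; `write_fastq()`
#'   returns `path` invisibly.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' Phred quality to error probability
#'
#' Converts a Phred quality score to the probability of an incorrect base
#' call, `10^(-Q/10)`. At Q30 this is 0.001 — one error in 1,000 calls,
#' i.e. 99.9% base-calling accuracy.
#'
#' @param Q Phred quality score(s), non-negative.
#' @return Error probability in `[0, 1]`.
#' @examples
#' phred_error_prob(30)  # 0.001
#' @export
phred_error_prob <- function(Q) {
  stopifnot(all(Q >= 0))
  10^(-Q / 10)
}

#' Mask low-quality base calls with N
#'
#' Replaces base calls whose Phred quality fails the threshold with the
#' placeholder nucleotide `N`, so that unreliable calls contribute neither
#' to alignment scores nor to base tallies. Two dialects are supported:
#' `strict_below` masks bases with `Q < threshold` (genomic-locus mode);
#' `at_or_below` masks bases with `Q <= threshold` (in-vitro substrate
#' mode).
#'
#' @param reads Reads data.frame from [read_fastq()].
#' @param threshold Phred threshold (default 30).
#' @param mode Masking dialect, `"strict_below"` or `"at_or_below"`.
#' @return The reads data.frame with masked `sequence` and attributes
#'   `mask_threshold_used` and `threshold_mode`.
#' @export
mask_low_quality <- function(reads, threshold = 30L,
                             mode = c("strict_below", "at_or_below")) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0)
  bad_len <- which(nchar(reads$sequence) != nchar(reads$qualities))
  if (length(bad_len))
    stop("malformed record '", reads$read_id[bad_len[1]],
         "': sequence and quality lengths differ", call. = FALSE)
  # a read needs masking only if its worst quality fails the threshold
  cut_char <- if (mode == "strict_below") threshold + 33L - 1L
              else threshold + 33L
  need <- vapply(reads$qualities,
                 function(q) any(utf8ToInt(q) <= cut_char),
                 logical(1), USE.NAMES = FALSE)
  if (any(need)) {
    reads$sequence[need] <- mapply(function(s, q) {
      qs <- utf8ToInt(q) - 33L
      b <- strsplit(s, "")[[1]]
      b[if (mode == "strict_below") qs < threshold else qs <= threshold] <- "N"
      paste(b, collapse = "")
    }, reads$sequence[need], reads$qualities[need], USE.NAMES = FALSE)
  }
  attr(reads, "mask_threshold_used") <- as.integer(threshold)
  attr(reads, "threshold_mode") <- mode
  reads
}

#' Alignment scoring scheme
#'
#' Affine-gap local alignment parameters. A gap of length L costs
#' `gap_open + L * gap_extend`. Defaults (match +5, mismatch -4, open 10,
#' extend 1) favour a single multi-base gap over scattered mismatches,
#' matching the downstream definition of an indel as a contiguous event of
#' two or more bases. `N` scores 0 against every base. Reads whose best
#' local score falls below `floor_frac` times the perfect-match score for
#' their length are rejected.
#'
#' @param match,mismatch Per-base scores.
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @param floor_frac Acceptance floor as a fraction of the perfect score.
#' @param try_revcomp Also align the reverse-complemented read and keep the
#'   better orientation.
#' @return A list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 5L, mismatch = -4L,
                              gap_open = 10L, gap_extend = 1L,
                              floor_frac = 0.6, try_revcomp = TRUE) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            floor_frac >= 0, floor_frac <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 floor_frac = floor_frac, try_revcomp = try_revcomp),
            class = "alignment_scoring")
}

#' Align reads to an amplicon reference
#'
#' Smith-Waterman local alignment with affine gaps of each (masked) read
#' against the amplicon reference. Each read is optionally also aligned in
#' reverse complement and the better-scoring orientation kept (ties go to
#' the forward orientation). Reads scoring below the acceptance floor are
#' rejected and counted, never silently dropped.
#'
#' @param reads Reads data.frame ([read_fastq()] / [mask_low_quality()]).
#' @param spec An [amplicon_spec()].
#' @param scoring An [alignment_scoring()].
#' @return An object of class `read_alignments`: a list with
#'   \describe{
#'     \item{alignments}{per-read data.frame: `read_id`, `score`,
#'       `ref_start` (0-based), `strand`, gapped `pattern`/`subject`
#'       strings, `accepted`, `reject_reason`.}
#'     \item{events}{indel events from accepted reads: `read_id`, `type`
#'       (`ins`/`del`), `length`, `anchor` (0-based reference offset; a
#'       deletion is anchored at its first deleted reference base, an
#'       insertion at the reference base immediately 5' of the inserted
#'       run).}
#'     \item{n_input, n_accepted}{stage read counts.}
#'   }
#' @export
align_reads <- function(reads, spec, scoring = alignment_scoring()) {
  stopifnot(inherits(spec, "amplicon_spec"))
  seqs <- reads$sequence
  n <- length(seqs)
  empty <- !nzchar(seqs)

  res <- .sw_align_batch(seqs, spec$reference, scoring$match,
                         scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend,
                         isTRUE(scoring$try_revcomp))
  strand <- res$strand

  floor_score <- scoring$floor_frac * scoring$match * nchar(seqs)
  accepted <- !empty & res$score >= floor_score
  reason <- rep(NA_character_, n)
  reason[empty] <- "empty"
  reason[!empty & !accepted] <- "low_score"

  aln <- data.frame(read_id = reads$read_id, score = res$score,
                    ref_start = res$ref_start, strand = strand,
                    pattern = res$pattern, subject = res$subject,
                    accepted = accepted, reject_reason = reason,
                    stringsAsFactors = FALSE)
  events <- alignment_events(aln[accepted, , drop = FALSE])
  structure(list(alignments = aln, events = events,
                 n_input = n, n_accepted = sum(accepted),
                 scoring = scoring, locus_name = spec$locus_name,
                 reference = spec$reference),
            class = "read_alignments")
}

#' @export
print.read_alignments <- function(x, ...) {
  cat("read_alignments for locus", x$locus_name, "\n")
  cat("  ", x$n_accepted, "of", x$n_input, "reads accepted\n")
  if (nrow(x$events))
    cat("  ", nrow(x$events), "indel events in accepted reads\n")
  invisible(x)
}

# Extract indel events from gapped alignment strings. Deletions are runs of
# '-' in the pattern (read); insertions are runs of '-' in the subject
# (reference). Anchors are 0-based reference offsets.
alignment_events <- function(aln) {
  out <- list()
  has_gap <- grepl("-", aln$pattern, fixed = TRUE) |
             grepl("-", aln$subject, fixed = TRUE)
  for (i in which(has_gap)) {
    p <- strsplit(aln$pattern[i], "")[[1]]
    s <- strsplit(aln$subject[i], "")[[1]]
    is_ref <- s != "-"
    # reference offset at each column (offset of the column's ref base, or of
    # the most recent ref base for insertion columns)
    offs <- aln$ref_start[i] + cumsum(is_ref) - 1L
    for (type in c("del", "ins")) {
      gap <- if (type == "del") p == "-" else !is_ref
      if (!any(gap)) next
      r <- rle(gap)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      for (k in runs) {
        anchor <- if (type == "del") offs[starts[k]]
                  else max(offs[starts[k]], aln$ref_start[i] - 1L)
        out[[length(out) + 1L]] <- data.frame(
          read_id = aln$read_id[i], type = type,
          length = r$lengths[k], anchor = anchor,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(), type = character(),
                      length = integer(), anchor = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Re-score a gapped alignment under a scoring scheme (used to check the
# aligner's score invariant).
rescore_alignment <- function(pattern, subject, scoring) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  stopifnot(length(p) == length(s))
  score <- 0
  for (gap_in in list(p == "-", s == "-")) {
    if (any(gap_in)) {
      r <- rle(gap_in)
      nruns <- sum(r$values)
      score <- score - nruns * scoring$gap_open -
        sum(r$lengths[r$values]) * scoring$gap_extend
    }
  }
  base_cols <- p != "-" & s != "-"
  pb <- p[base_cols]; sb <- s[base_cols]
  isn <- pb == "N" | sb == "N"
  score + sum(ifelse(isn, 0,
                     ifelse(pb == sb, scoring$match, scoring$mismatch)))
}

#' Tally base calls per reference position
#'
#' Counts A/C/G/T calls at every reference offset over the accepted
#' alignments. Masked (`N`) bases and gap columns are excluded, so at any
#' offset `A + C + G + T <= aligned_read_total`.
#'
#' @param aln A [align_reads()] result.
#' @return A data.frame of class `base_call_table` with columns `offset`
#'   (0-based), `ref_base`, `A`, `C`, `G`, `T`, `depth`, and attribute
#'   `aligned_read_total`.
#' @export
tally_bases <- function(aln) {
  stopifnot(inherits(aln, "read_alignments"))
  L <- nchar(aln$reference)
  acc <- aln$alignments[aln$alignments$accepted, , drop = FALSE]
  all_off <- vector("list", nrow(acc))
  all_base <- vector("list", nrow(acc))
  for (i in seq_len(nrow(acc))) {
    s <- strsplit(acc$subject[i], "")[[1]]
    is_ref <- s != "-"
    p <- strsplit(acc$pattern[i], "")[[1]][is_ref]
    offs <- acc$ref_start[i] + seq_len(sum(is_ref)) - 1L
    keep <- p %in% c("A", "C", "G", "T")
    all_off[[i]] <- offs[keep]
    all_base[[i]] <- p[keep]
  }
  offs <- unlist(all_off)
  bases <- unlist(all_base)
  counts <- table(factor(offs, levels = 0:(L - 1L)),
                  factor(bases, levels = c("A", "C", "G", "T")))
  tab <- data.frame(offset = 0:(L - 1L),
                    ref_base = strsplit(aln$reference, "")[[1]],
                    A = as.integer(counts[, "A"]),
                    C = as.integer(counts[, "C"]),
                    G = as.integer(counts[, "G"]),
                    T = as.integer(counts[, "T"]),
                    stringsAsFactors = FALSE)
  tab$depth <- tab$A + tab$C + tab$G + tab$T
  attr(tab, "aligned_read_total") <- nrow(acc)
  class(tab) <- c("base_call_table", "data.frame")
  tab
}

#' Extract protospacers from in-vitro substrate reads
#'
#' Scans each read for exact matches to the two 14-base flanks of an
#' in-vitro substrate. A read is accepted only when both flanks match
#' exactly and the intervening sequence has exactly the expected
#' protospacer length; otherwise it is rejected with a reason
#' (`no_flank5`, `no_flank3`, `wrong_length`). Rejection is a counted,
#' normal outcome.
#'
#' @param reads Reads data.frame (typically after [mask_low_quality()] in
#'   `at_or_below` mode).
#' @param spec An [amplicon_spec()] with `flank5` and `flank3`.
#' @return A list with `protospacers` (per-read data.frame: `read_id`,
#'   `status`, `protospacer`), and `counts`, a named integer vector over
#'   `accepted`, `no_flank5`, `no_flank3`, `wrong_length`.
#' @export
extract_protospacer <- function(reads, spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (is.null(spec$flank5) || is.null(spec$flank3))
    stop("spec has no in-vitro flanks (flank5/flank3)", call. = FALSE)
  L <- spec$expected_protospacer_len
  seqs <- reads$sequence
  p5 <- regexpr(spec$flank5, seqs, fixed = TRUE)
  status <- rep("accepted", length(seqs))
  proto <- rep(NA_character_, length(seqs))
  status[p5 < 0] <- "no_flank5"
  ok <- p5 > 0
  # search flank3 only downstream of flank5
  rest_start <- as.integer(p5) + 14L
  rest <- substring(seqs, rest_start)
  p3 <- rep(-1L, length(seqs))
  p3[ok] <- regexpr(spec$flank3, rest[ok], fixed = TRUE)
  status[ok & p3 < 0] <- "no_flank3"
  ok <- ok & p3 > 0
  gap_len <- p3 - 1L
  status[ok & gap_len != L] <- "wrong_length"
  hit <- ok & gap_len == L
  proto[hit] <- substr(rest[hit], 1L, L)
  counts <- table(factor(status, levels = c("accepted", "no_flank5",
                                            "no_flank3", "wrong_length")))
  list(protospacers = data.frame(read_id = reads$read_id, status = status,
                                 protospacer = proto,
                                 stringsAsFactors = FALSE),
       counts = c(counts))
}

#' Tally extracted protospacer base calls by position
#'
#' Counts A/C/G/T at each protospacer position (1..20) over accepted
#' extracted protospacers, the in-vitro analogue of [tally_bases()].
#'
#' @param extraction Result of [extract_protospacer()].
#' @param spec The [amplicon_spec()].
#' @return A data.frame with `position`, `proto_base`, counts and `depth`.
#' @export
tally_protospacers <- function(extraction, spec) {
  L <- spec$expected_protospacer_len
  acc <- extraction$protospacers
  acc <- acc$protospacer[acc$status == "accepted"]
  # tally on the protospacer strand
  if (spec$protospacer_strand == "-" && length(acc)) acc <- revcomp(acc)
  chars <- matrix("N", nrow = length(acc), ncol = L)
  if (length(acc))
    chars <- do.call(rbind, strsplit(acc, ""))
  counts <- sapply(c("A", "C", "G", "T"), function(b)
    colSums(matrix(chars == b, ncol = L)))
  counts <- matrix(counts, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  rp <- resolve_protospacer(spec)
  # reference protospacer on the protospacer strand, in position order
  proto <- strsplit(rp$protospacer, "")[[1]]
  out <- data.frame(position = seq_len(L), proto_base = proto,
                    A = as.integer(counts[, "A"]),
                    C = as.integer(counts[, "C"]),
                    G = as.integer(counts[, "G"]),
                    T = as.integer(counts[, "T"]),
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out
}
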