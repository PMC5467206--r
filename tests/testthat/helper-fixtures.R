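# Shared fixtures: loci are built in code so no sequencing data is needed.

# protospacer with cytosines at positions 4-8 (and 12); PAM "AGG" appended
TOY_PROTO <- "ATGCCCCCAGTCGATGAAGT"

# TC-repeat protospacer used by the in-vitro substrate fixture: C at every
# even position 2..20
TC_PROTO <- strrep("TC", 10)

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# genomic-mode locus: flank + protospacer + PAM + flank
toy_spec <- function(strand = "+", window = c(4L, 8L), seed = 42,
                     proto = TOY_PROTO, name = "toy") {
  set.seed(seed)
  left <- rand_dna(40)
  right <- rand_dna(40)
  if (strand == "+") {
    ref <- paste0(left, proto, "AGG", right)
  } else {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      paste0(proto, "AGG"))))
    ref <- paste0(left, rc, right)
  }
  amplicon_spec(name, ref, protospacer = proto, protospacer_strand = strand,
                activity_window = window)
}

# in-vitro substrate: junk + flank5 + TC-repeat protospacer + flank3 + junk
invitro_spec <- function(seed = 7, name = "invitro") {
  set.seed(seed)
  flank5 <- "GATTACAGGATCCA"   # 14 bases
  flank3 <- "TGGATAACTGCAGT"   # 14 bases
  ref <- paste0(rand_dna(12), flank5, TC_PROTO, flank3, rand_dna(12))
  amplicon_spec(name, ref, protospacer = TC_PROTO,
                activity_window = c(4L, 8L),
                flank5 = flank5, flank3 = flank3)
}

reads_df <- function(seqs, q = 40L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(read_id = ids, sequence = seqs,
             qualities = strrep(intToUtf8(q + 33L), nchar(seqs)),
             stringsAsFactors = FALSE)
}

# read builders: modify the reference by a deletion / insertion at a 0-based
# offset (del removes offsets off..off+L-1; ins adds bases after offset off-1)
del_read <- function(ref, off, L) {
  paste0(substr(ref, 1, off), substring(ref, off + L + 1))
}
ins_read <- function(ref, off, bases) {
  paste0(substr(ref, 1, off), bases, substring(ref, off + 1))
}
sub_read <- function(ref, off, base) {
  substr(ref, off + 1, off + 1) <- base
  ref
}

# brute-force affine-gap local-alignment score (independent oracle):
# plain 3-matrix dynamic programme, O(m*n), no traceback
sw_oracle_score <- function(read, ref, match = 5, mismatch = -4,
                            gap_open = 10, gap_extend = 1) {
  p <- strsplit(read, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  m <- length(p); n <- length(s)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      sc <- if (p[i - 1] == "N" || s[j - 1] == "N") 0
            else if (p[i - 1] == s[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# independent recount of windowed indels straight from alignment columns,
# scanning each gapped pair character by character
recount_indels <- function(aln, spec, window_width = 30L, min_len = 2L) {
  b <- nick_boundary(spec)
  lo <- b - window_width %/% 2L
  hi <- b + window_width %/% 2L
  acc <- aln$alignments[aln$alignments$accepted, , drop = FALSE]
  n_pos <- 0L
  for (i in seq_len(nrow(acc))) {
    p <- strsplit(acc$pattern[i], "")[[1]]
    s <- strsplit(acc$subject[i], "")[[1]]
    ref_off <- acc$ref_start[i]
    k <- 1L
    hit <- FALSE
    while (k <= length(p)) {
      if (p[k] == "-") {            # deletion run
        anchor <- ref_off
        len <- 0L
        while (k <= length(p) && p[k] == "-") {
          len <- len + 1L; ref_off <- ref_off + 1L; k <- k + 1L
        }
        if (len >= min_len && anchor >= lo && anchor < hi) hit <- TRUE
      } else if (s[k] == "-") {     # insertion run
        anchor <- ref_off - 1L
        len <- 0L
        while (k <= length(p) && k <= length(s) && s[k] == "-") {
          len <- len + 1L; k <- k + 1L
        }
        if (len >= min_len && anchor >= lo && anchor < hi) hit <- TRUE
      } else {
        ref_off <- ref_off + 1L; k <- k + 1L
      }
    }
    if (hit) n_pos <- n_pos + 1L
  }
  list(n_indel_reads = n_pos,
       percent = if (nrow(acc)) 100 * n_pos / nrow(acc) else NA_real_)
}
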