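#' Define an amplicon locus for base-editing quantification
#'
#' An `amplicon_spec` describes one sequenced locus: the reference amplicon
#' (as sequenced), where the 20-base protospacer sits and on which strand,
#' the deaminase activity window, the nickase cut position, and (for the
#' in-vitro substrate mode) the two 14-base flanks used to anchor
#' protospacer extraction.
#'
#' Protospacer positions are numbered 1-20 with position 1 most PAM-distal,
#' so the activity window "C4-C8" refers to protospacer positions 4 through 8.
#' The PAM sits 3' of position 20 on the protospacer strand and is not
#' stored. All reference offsets are 0-based internally; reports are 1-based.
#'
#' @param locus_name Identifier for the locus.
#' @param reference Amplicon reference sequence over A/C/G/T, as sequenced.
#' @param protospacer_start 0-based offset of the protospacer's first
#'   reference base (leftmost base on the sequenced strand). If `NULL`, the
#'   `protospacer` sequence is searched on both strands and must occur
#'   exactly once.
#' @param protospacer Optional 20-mer used for search-based placement and,
#'   when `protospacer_start` is given, verified against the reference.
#' @param protospacer_strand `"+"` if the protospacer reads 5'->3' on
#'   `reference`, `"-"` if on its reverse complement.
#' @param activity_window Inclusive protospacer-position range of the
#'   deaminase activity window, e.g. `c(4, 8)`.
#' @param nick_offset Protospacer position after which the nickase cut
#'   falls; the canonical SpCas9 nick is between positions 17 and 18
#'   (3 nt 5' of the PAM), i.e. `nick_offset = 17`.
#' @param flank5,flank3 Optional 14-base flanks for in-vitro protospacer
#'   extraction; each must occur exactly once in `reference`.
#' @param expected_protospacer_len Protospacer length (default 20).
#' @return An object of class `amplicon_spec`.
#' @examples
#' ref <- paste0("GATTACAGATTACA", "ACCCTAGCCTCAGTCTGAAC", "TTGACCTGAGGCAT")
#' spec <- amplicon_spec("toy", ref, protospacer_start = 14)
#' resolve_protospacer(spec)$protospacer
#' @export
amplicon_spec <- function(locus_name, reference,
                          protospacer_start = NULL,
                          protospacer = NULL,
                          protospacer_strand = c("+", "-"),
                          activity_window = c(4L, 8L),
                          nick_offset = 17L,
                          flank5 = NULL, flank3 = NULL,
                          expected_protospacer_len = 20L) {
  protospacer_strand <- match.arg(protospacer_strand)
  reference <- toupper(reference)
  if (!grepl("^[ACGT]+$", reference))
    stop("reference must be a non-empty DNA string over A/C/G/T", call. = FALSE)
  L <- as.integer(expected_protospacer_len)

  if (is.null(protospacer_start)) {
    if (is.null(protospacer))
      stop("supply protospacer_start or a protospacer sequence to search for",
           call. = FALSE)
    hit <- locate_protospacer(reference, toupper(protospacer))
    protospacer_start <- hit$start
    protospacer_strand <- hit$strand
  }
  protospacer_start <- as.integer(protospacer_start)
  if (protospacer_start < 0L || protospacer_start + L > nchar(reference))
    stop("protospacer does not lie fully within the reference", call. = FALSE)

  spec <- structure(list(
    locus_name = as.character(locus_name),
    reference = reference,
    protospacer_start = protospacer_start,
    protospacer_strand = protospacer_strand,
    activity_window = as.integer(activity_window),
    nick_offset = as.integer(nick_offset),
    flank5 = if (is.null(flank5)) NULL else toupper(flank5),
    flank3 = if (is.null(flank3)) NULL else toupper(flank3),
    expected_protospacer_len = L
  ), class = "amplicon_spec")

  if (!is.null(protospacer)) {
    got <- resolve_protospacer(spec)$protospacer
    if (!identical(got, toupper(protospacer)))
      stop("protospacer sequence does not match the reference at ",
           "protospacer_start ", protospacer_start, " on strand ",
           protospacer_strand, call. = FALSE)
  }
  validate_amplicon_spec(spec)
}

validate_amplicon_spec <- function(spec) {
  L <- spec$expected_protospacer_len
  aw <- spec$activity_window
  if (length(aw) != 2L || aw[1] > aw[2] || aw[1] < 1L || aw[2] > L)
    stop("activity_window must be an inclusive range within [1, ", L, "]",
         call. = FALSE)
  if (spec$nick_offset < 1L || spec$nick_offset >= L)
    stop("nick_offset must lie in [1, ", L - 1L, "]", call. = FALSE)
  for (fl in c("flank5", "flank3")) {
    f <- spec[[fl]]
    if (is.null(f)) next
    if (nchar(f) != 14L || !grepl("^[ACGT]+$", f))
      stop(fl, " must be exactly 14 bases over A/C/G/T", call. = FALSE)
    n_occ <- length(gregexpr(f, spec$reference, fixed = TRUE)[[1]])
    if (n_occ != 1L || gregexpr(f, spec$reference, fixed = TRUE)[[1]][1] == -1L)
      stop(fl, " must occur exactly once in the reference", call. = FALSE)
  }
  spec
}

#' @export
print.amplicon_spec <- function(x, ...) {
  rp <- resolve_protospacer(x)
  cat("amplicon_spec:", x$locus_name, "\n")
  cat("  reference:", nchar(x$reference), "bp\n")
  cat("  protospacer:", rp$protospacer, "(", x$protospacer_strand,
      "strand, ref offset", x$protospacer_start, ")\n")
  cat("  activity window: positions", x$activity_window[1], "-",
      x$activity_window[2], "\n")
  cat("  nick: between positions", x$nick_offset, "and", x$nick_offset + 1L,
      "(reference boundary", nick_boundary(x), ")\n")
  if (!is.null(x$flank5))
    cat("  in-vitro flanks:", x$flank5, "/", x$flank3, "\n")
  invisible(x)
}

# search-based placement: the 20-mer must occur exactly once over both strands
locate_protospacer <- function(reference, protospacer) {
  fwd <- gregexpr(protospacer, reference, fixed = TRUE)[[1]]
  fwd <- fwd[fwd > 0]
  rcp <- revcomp(protospacer)
  rev <- gregexpr(rcp, reference, fixed = TRUE)[[1]]
  rev <- rev[rev > 0]
  n <- length(fwd) + length(rev)
  if (n == 0L)
    stop("protospacer not found in reference on either strand", call. = FALSE)
  if (n > 1L)
    stop("protospacer occurs ", n, " times in reference; placement ambiguous",
         call. = FALSE)
  if (length(fwd) == 1L) list(start = fwd - 1L, strand = "+")
  else list(start = rev - 1L, strand = "-")
}

#' Map protospacer positions to reference offsets
#'
#' Resolves the 20-base protospacer of an [amplicon_spec()] into a
#' position-by-position map. Position 1 is PAM-distal. On the `-` strand the
#' map descends along the reference and each protospacer base is the
#' complement of the reference base.
#'
#' @param spec An [amplicon_spec()].
#' @return A list with `protospacer` (the 20-mer on the protospacer strand)
#'   and `map`, a data.frame with columns `position` (1..20), `ref_offset`
#'   (0-based), `strand`, `ref_base` (sequenced strand) and `proto_base`
#'   (protospacer strand).
#' @export
resolve_protospacer <- function(spec) {
  L <- spec$expected_protospacer_len
  s <- spec$protospacer_start
  if (spec$protospacer_strand == "+") {
    off <- s + seq_len(L) - 1L
  } else {
    off <- s + L - seq_len(L)
  }
  ref_base <- strsplit(substr(spec$reference, s + 1L, s + L), "")[[1]]
  ref_base <- ref_base[off - s + 1L]
  proto_base <- if (spec$protospacer_strand == "+") ref_base
                else comp_bases(ref_base)
  list(
    protospacer = paste(proto_base, collapse = ""),
    map = data.frame(position = seq_len(L), ref_offset = off,
                     strand = spec$protospacer_strand,
                     ref_base = ref_base, proto_base = proto_base,
                     stringsAsFactors = FALSE)
  )
}

#' Reference boundary of the nickase cut
#'
#' Returns the 0-based reference boundary index `b` such that the nick falls
#' between reference offsets `b - 1` and `b`. The 30-base indel window is
#' `[b - 15, b + 15)`.
#'
#' @param spec An [amplicon_spec()].
#' @return Integer boundary offset.
#' @export
nick_boundary <- function(spec) {
  if (spec$protospacer_strand == "+")
    spec$protospacer_start + spec$nick_offset
  else
    spec$protospacer_start + spec$expected_protospacer_len - spec$nick_offset
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(comp_bases(strsplit(s, "")[[1]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

comp_bases <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")[b]
}

#' Read and write locus configuration files
#'
#' A locus config is a YAML document with the [amplicon_spec()] fields; a
#' sample sheet is a TSV with one row per sequencing sample. Both are
#' validated on load with messages naming the offending entry.
#'
#' @param path File path.
#' @param spec An [amplicon_spec()] to serialize.
#' @return `read_locus_config()` returns an [amplicon_spec()];
#'   `write_locus_config()` returns `path` invisibly.
#' @export
read_locus_config <- function(path) {
  doc <- yaml::read_yaml(path)
  req <- c("locus_name", "reference", "protospacer_start",
           "protospacer_strand")
  miss <- setdiff(req, names(doc))
  if (length(miss))
    stop("locus config ", path, ": missing field(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  amplicon_spec(
    locus_name = doc$locus_name,
    reference = doc$reference,
    protospacer_start = doc$protospacer_start,
    protospacer_strand = doc$protospacer_strand,
    activity_window = if (is.null(doc$activity_window)) c(4L, 8L)
                      else as.integer(doc$activity_window),
    nick_offset = if (is.null(doc$nick_offset)) 17L
                  else as.integer(doc$nick_offset),
    flank5 = doc$flank5, flank3 = doc$flank3,
    expected_protospacer_len =
      if (is.null(doc$expected_protospacer_len)) 20L
      else as.integer(doc$expected_protospacer_len)
  )
}

#' @rdname read_locus_config
#' @export
write_locus_config <- function(spec, path) {
  stopifnot(inherits(spec, "amplicon_spec"))
  doc <- spec[!vapply(spec, is.null, logical(1))]
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet is a TSV with columns `sample_id`, `locus_name`,
#' `condition` (`treated` / `untreated_control`), `delivery`
#' (`plasmid` / `protein` / `none`), `replicate_index`, and optionally
#' `dose` and `fastq_path`. Every treated locus must have at least one
#' untreated control sample, and replicate indices must be unique within
#' (locus, condition, delivery, dose).
#'
#' @param path TSV file path.
#' @param loci Optional character vector of known locus names to validate
#'   against.
#' @return A data.frame of sample records.
#' @export
read_sample_sheet <- function(path, loci = NULL) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "locus_name", "condition", "delivery",
           "replicate_index")
  miss <- setdiff(req, names(ss))
  if (length(miss))
    stop("sample sheet ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"dose" %in% names(ss)) ss$dose <- NA_real_
  if (!"fastq_path" %in% names(ss)) ss$fastq_path <- NA_character_
  bad <- which(!ss$condition %in% c("treated", "untreated_control"))
  if (length(bad))
    stop("sample sheet line ", bad[1] + 1L, ": condition must be ",
         "'treated' or 'untreated_control', got '", ss$condition[bad[1]],
         "'", call. = FALSE)
  bad <- which(!ss$delivery %in% c("plasmid", "protein", "none"))
  if (length(bad))
    stop("sample sheet line ", bad[1] + 1L, ": delivery must be one of ",
         "plasmid/protein/none, got '", ss$delivery[bad[1]], "'",
         call. = FALSE)
  if (!is.null(loci)) {
    bad <- which(!ss$locus_name %in% loci)
    if (length(bad))
      stop("sample sheet line ", bad[1] + 1L, ": unknown locus '",
           ss$locus_name[bad[1]], "'", call. = FALSE)
  }
  key <- paste(ss$locus_name, ss$condition, ss$delivery, ss$dose,
               ss$replicate_index, sep = "\r")
  if (anyDuplicated(key))
    stop("sample sheet: duplicate replicate_index within ",
         "(locus, condition, delivery, dose) at line ",
         which(duplicated(key))[1] + 1L, call. = FALSE)
  treated <- unique(ss$locus_name[ss$condition == "treated"])
  ctrl <- unique(ss$locus_name[ss$condition == "untreated_control"])
  orphan <- setdiff(treated, ctrl)
  if (length(orphan))
    stop("sample sheet: treated locus without an untreated control: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  ss
}
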