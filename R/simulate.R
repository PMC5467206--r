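#' Configuration for the synthetic read generator
#'
#' Describes one simulated amplicon sample: how many reads, which
#' protospacer cytosines are edited and at what rate, background
#' deamination noise, indel geometry, sequencing error and the quality
#' model. Identical (config, seed) pairs produce byte-identical FASTQ
#' output.
#'
#' @param n_reads Number of reads to emit.
#' @param editing_profile Named numeric vector: protospacer position ->
#'   C-to-T probability in `[0,1]`. Each named position must be a cytosine
#'   on the protospacer strand.
#' @param background_ct_rate Probability of a spontaneous C-to-T per
#'   cytosine outside the profile, modelling deamination and PCR artefacts.
#'   Applied symmetrically (C-to-T and G-to-A on the sequenced strand) so
#'   both protospacer orientations see background. The default 0.05% is a
#'   synthetic fixture value, not an empirical estimate.
#' @param indel_rate Probability that a read carries one indel.
#' @param indel_length_dist Named numeric vector of probabilities over
#'   indel lengths (names are lengths), e.g. `c("2" = 1)`.
#' @param indel_type_probs Named probabilities over `del` / `ins`.
#' @param indel_jitter Max absolute positional jitter (bases) of the indel
#'   centre around the nick boundary.
#' @param subst_error_rate Per-base substitution sequencing-error
#'   probability (uniform over the three alternative bases).
#' @param quality_model Either `list(type = "constant", q = 40)` or
#'   `list(type = "mixture", q_high = , q_low = , low_fraction = )`
#'   assigning a fraction of bases a low quality.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 1000L,
                       editing_profile = numeric(0),
                       background_ct_rate = 5e-4,
                       indel_rate = 0,
                       indel_length_dist = c("2" = 1),
                       indel_type_probs = c(del = 0.5, ins = 0.5),
                       indel_jitter = 0L,
                       subst_error_rate = 0,
                       quality_model = list(type = "constant", q = 40L),
                       seed = 1L) {
  probs <- c(editing_profile, background_ct_rate, indel_rate,
             subst_error_rate, indel_length_dist, indel_type_probs)
  stopifnot(n_reads >= 0, all(probs >= 0), all(probs <= 1),
            quality_model$type %in% c("constant", "mixture"))
  structure(list(n_reads = as.integer(n_reads),
                 editing_profile = editing_profile,
                 background_ct_rate = background_ct_rate,
                 indel_rate = indel_rate,
                 indel_length_dist = indel_length_dist,
                 indel_type_probs = indel_type_probs,
                 indel_jitter = as.integer(indel_jitter),
                 subst_error_rate = subst_error_rate,
                 quality_model = quality_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an amplicon sequencing sample with known truth
#'
#' Emits full-length single-end amplicon reads derived from the reference
#' by (optionally) one indel near the nick, then per-base C-to-T edits at
#' the profiled protospacer positions, background deamination, and uniform
#' substitution sequencing errors, with per-base Phred qualities from the
#' quality model. A truth table records exactly what was injected, so the
#' downstream pipeline's estimates can be checked against known rates.
#'
#' @param config A [sim_config()].
#' @param spec An [amplicon_spec()].
#' @return A list of class `sim_sample`: `reads` (data.frame for
#'   [write_fastq()]), `truth_edits` (per profiled position: `position`,
#'   `ref_offset`, `n_covered`, `n_edited`, `true_rate`), `truth_indels`
#'   (per read: `read_id`, `has_indel`, `type`, `length`, `anchor`),
#'   plus the `config` and the locus name.
#' @export
simulate_sample <- function(config, spec) {
  stopifnot(inherits(config, "sim_config"), inherits(spec, "amplicon_spec"))
  map <- resolve_protospacer(spec)$map
  prof_pos <- as.integer(names(config$editing_profile))
  if (length(prof_pos)) {
    bad <- !prof_pos %in% map$position[map$proto_base == "C"]
    if (any(bad))
      stop("editing_profile position(s) ",
           paste(prof_pos[bad], collapse = ", "),
           " are not cytosines on the protospacer strand", call. = FALSE)
  }
  prof_off <- map$ref_offset[match(prof_pos, map$position)]
  # edited base as seen on the sequenced strand
  edit_to <- if (spec$protospacer_strand == "+") "T" else "A"

  ref_chars <- strsplit(spec$reference, "")[[1]]
  len0 <- length(ref_chars)
  bg_off <- setdiff(c(which(ref_chars == "C"), which(ref_chars == "G")) - 1L,
                    prof_off)
  bg_to <- ifelse(ref_chars[bg_off + 1L] == "C", "T", "A")
  b <- nick_boundary(spec)
  lens <- as.integer(names(config$indel_length_dist))
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))

  set.seed(config$seed)
  n <- config$n_reads
  seqs <- character(n)
  quals <- character(n)
  ids <- sprintf("sim_%06d", seq_len(n))
  n_cov <- integer(length(prof_pos))
  n_edit <- integer(length(prof_pos))
  tr_type <- rep(NA_character_, n)
  tr_len <- rep(NA_integer_, n)
  tr_anchor <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    chars <- ref_chars
    del_off <- integer(0)
    shift_at <- NA_integer_  # boundary offset where coordinates shift
    shift_by <- 0L
    if (config$indel_rate > 0 && stats::runif(1) < config$indel_rate) {
      type <- sample(names(config$indel_type_probs), 1L,
                     prob = config$indel_type_probs)
      L <- if (length(lens) == 1L) lens
           else sample(lens, 1L, prob = config$indel_length_dist)
      jit <- if (config$indel_jitter > 0)
        sample(seq(-config$indel_jitter, config$indel_jitter), 1L) else 0L
      centre <- b + jit
      if (type == "del") {
        del_off <- pmin(pmax(centre + 0:(L - 1L), 0L), len0 - 1L)
        del_off <- unique(del_off)
        tr_anchor[i] <- del_off[1]
        tr_len[i] <- length(del_off)
      } else {
        centre <- min(max(centre, 1L), len0 - 1L)
        tr_anchor[i] <- centre - 1L
        tr_len[i] <- L
      }
      tr_type[i] <- type
      if (type == "ins") { shift_at <- centre; shift_by <- L }
    }
    # programmed edits at surviving profiled positions
    if (length(prof_off)) {
      surv <- !prof_off %in% del_off
      n_cov <- n_cov + surv
      hit <- surv & stats::runif(length(prof_off)) < config$editing_profile
      chars[prof_off[hit] + 1L] <- edit_to
      n_edit <- n_edit + hit
    }
    # background deamination outside the profile
    if (config$background_ct_rate > 0 && length(bg_off)) {
      hit <- stats::runif(length(bg_off)) < config$background_ct_rate
      chars[bg_off[hit] + 1L] <- bg_to[hit]
    }
    # apply the indel to the character vector
    if (length(del_off)) {
      chars <- chars[-(del_off + 1L)]
    } else if (!is.na(shift_at)) {
      ins <- sample(c("A", "C", "G", "T"), shift_by, replace = TRUE)
      chars <- append(chars, ins, after = shift_at)
    }
    # sequencing substitution errors, uniform over the 3 alternatives
    if (config$subst_error_rate > 0) {
      err <- which(stats::runif(length(chars)) < config$subst_error_rate)
      for (j in err)
        chars[j] <- sample(alt[[chars[j]]], 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
    quals[i] <- sim_qualities(length(chars), config$quality_model)
  }

  truth_edits <- data.frame(position = prof_pos, ref_offset = prof_off,
                            n_covered = n_cov, n_edited = n_edit,
                            true_rate = ifelse(n_cov > 0, n_edit / n_cov,
                                               NA_real_),
                            stringsAsFactors = FALSE)
  truth_indels <- data.frame(read_id = ids, has_indel = !is.na(tr_type),
                             type = tr_type, length = tr_len,
                             anchor = tr_anchor, stringsAsFactors = FALSE)
  structure(list(reads = data.frame(read_id = ids, sequence = seqs,
                                    qualities = quals,
                                    stringsAsFactors = FALSE),
                 truth_edits = truth_edits, truth_indels = truth_indels,
                 config = config, locus_name = spec$locus_name),
            class = "sim_sample")
}

sim_qualities <- function(len, model) {
  if (model$type == "constant") {
    strrep(intToUtf8(model$q + 33L), len)
  } else {
    q <- ifelse(stats::runif(len) < model$low_fraction,
                model$q_low, model$q_high)
    intToUtf8(q + 33L, multiple = FALSE)
  }
}

#' Simulate in-vitro substrate reads for the protospacer extractor
#'
#' Like [simulate_sample()] but for the flank-anchored in-vitro substrate
#' mode: a configurable fraction of reads is corrupted so that the
#' extractor's rejection paths are exercised. Exactly
#' `round(reject_fraction * n_reads)` reads are corrupted, so on
#' error-free input the extractor's acceptance equals
#' `1 - reject_fraction` exactly.
#'
#' @param config A [sim_config()] (indels are not injected in this mode).
#' @param spec An [amplicon_spec()] with `flank5`/`flank3`.
#' @param reject_fraction Fraction of reads to corrupt.
#' @param reject_mode How corrupted reads fail: `"flank_mutation"` (one
#'   base of the 5' flank substituted -> `no_flank5`), `"truncation"`
#'   (read cut inside the 3' flank -> `no_flank3`), or `"spacer_length"`
#'   (one protospacer base deleted -> `wrong_length`).
#' @return A `sim_sample` whose `truth_reject` field records which reads
#'   were corrupted.
#' @export
simulate_invitro_sample <- function(config, spec, reject_fraction = 0,
                                    reject_mode = c("flank_mutation",
                                                    "truncation",
                                                    "spacer_length")) {
  reject_mode <- match.arg(reject_mode)
  stopifnot(reject_fraction >= 0, reject_fraction <= 1)
  if (is.null(spec$flank5) || is.null(spec$flank3))
    stop("in-vitro simulation needs a spec with flank5/flank3", call. = FALSE)
  if (config$indel_rate > 0)
    stop("indels are not simulated in in-vitro substrate mode", call. = FALSE)
  sim <- simulate_sample(config, spec)
  n <- config$n_reads
  n_rej <- round(reject_fraction * n)
  idx <- if (n_rej > 0) sample(n, n_rej) else integer(0)
  if (length(idx)) {
    sim$reads$sequence[idx] <- vapply(
      sim$reads$sequence[idx], corrupt_invitro_read, character(1),
      spec = spec, mode = reject_mode, USE.NAMES = FALSE)
    sim$reads$qualities[idx] <- vapply(
      nchar(sim$reads$sequence[idx]),
      sim_qualities, character(1), model = config$quality_model,
      USE.NAMES = FALSE)
  }
  sim$truth_reject <- data.frame(read_id = sim$reads$read_id,
                                 rejected = seq_len(n) %in% idx,
                                 mode = ifelse(seq_len(n) %in% idx,
                                               reject_mode, NA_character_),
                                 stringsAsFactors = FALSE)
  sim
}

corrupt_invitro_read <- function(seq, spec, mode) {
  p5 <- regexpr(spec$flank5, seq, fixed = TRUE)
  if (mode == "flank_mutation") {
    if (p5 < 0) return(seq)  # flank already absent; read will be rejected
    old <- substr(seq, p5, p5)
    new <- if (old == "A") "C" else "A"
    substr(seq, p5, p5) <- new
    seq
  } else if (mode == "truncation") {
    # cut the read inside the 3' flank so no exact 14-base match remains
    start3 <- p5 + 14L + spec$expected_protospacer_len
    substr(seq, 1L, start3 + 6L)
  } else {
    # delete one base inside the protospacer -> 19-base gap between flanks
    cut <- p5 + 14L + 2L
    paste0(substr(seq, 1L, cut - 1L), substring(seq, cut + 1L))
  }
}

#' Write a simulated sample's truth tables to TSV
#'
#' @param sim A `sim_sample`.
#' @param dir Output directory.
#' @param prefix File-name prefix (default the locus name).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(sim, dir, prefix = sim$locus_name) {
  stopifnot(inherits(sim, "sim_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_truth_edits.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_truth_indels.tsv"))
  utils::write.table(sim$truth_edits, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth_indels, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
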