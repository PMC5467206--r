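#' Detection limit of base calling at a Phred threshold
#'
#' With a quality threshold Q, the residual base-calling error probability
#' is `10^(-Q/10)`; assuming errors are distributed uniformly across the
#' four bases, the lower limit for calling a specific substitution is a
#' quarter of that. At Q30 (0.1% error) the limit is 0.1/4 = 0.025%.
#' Editing percentages at or below this limit are classified undetectable.
#'
#' @param q_threshold Phred quality threshold (default 30).
#' @return Detection limit in percent.
#' @examples
#' detection_limit(30)  # 0.025
#' @export
detection_limit <- function(q_threshold = 30L) {
  stopifnot(all(q_threshold >= 0))
  100 * phred_error_prob(q_threshold) / 4
}

#' Per-cytosine editing percentages across the protospacer
#'
#' Converts a [tally_bases()] table into per-position C-to-T (and C-to-A,
#' C-to-G) percentages on the protospacer strand, for every protospacer
#' position whose reference base is C on that strand. For minus-strand
#' protospacers the sequenced-strand G-to-A counts are reported as C-to-T
#' on the protospacer strand (the base editor converts C:G to T:A).
#' Positions with zero depth are flagged undefined, not 0%.
#'
#' @param table A `base_call_table` from [tally_bases()].
#' @param spec The [amplicon_spec()] the table was built against.
#' @return A data.frame of class `editing_table`: `position`, `ref_offset`,
#'   `proto_base`, `depth`, `pct_CtoT`, `pct_CtoA`, `pct_CtoG`, `defined`,
#'   `in_window`.
#' @export
compute_editing <- function(table, spec) {
  stopifnot(inherits(table, "base_call_table"),
            inherits(spec, "amplicon_spec"))
  map <- resolve_protospacer(spec)$map
  cyt <- map[map$proto_base == "C", , drop = FALSE]
  non_c_in_window <- map$position >= spec$activity_window[1] &
    map$position <= spec$activity_window[2] & map$proto_base != "C"
  if (any(non_c_in_window))
    warning("activity-window position(s) ",
            paste(map$position[non_c_in_window], collapse = ", "),
            " are not cytosines on the protospacer strand; skipped",
            call. = FALSE)
  idx <- match(cyt$ref_offset, table$offset)
  # protospacer-strand call counts: complement on the minus strand
  if (spec$protospacer_strand == "+") {
    tC <- table$C[idx]; tT <- table$T[idx]
    tA <- table$A[idx]; tG <- table$G[idx]
  } else {
    tC <- table$G[idx]; tT <- table$A[idx]
    tA <- table$T[idx]; tG <- table$C[idx]
  }
  depth <- tA + tC + tG + tT
  defined <- depth > 0
  pct <- function(x) ifelse(defined, 100 * x / depth, NA_real_)
  out <- data.frame(position = cyt$position, ref_offset = cyt$ref_offset,
                    proto_base = cyt$proto_base, depth = depth,
                    pct_CtoT = pct(tT), pct_CtoA = pct(tA),
                    pct_CtoG = pct(tG), defined = defined,
                    stringsAsFactors = FALSE)
  out$in_window <- out$position >= spec$activity_window[1] &
    out$position <= spec$activity_window[2]
  class(out) <- c("editing_table", "data.frame")
  out
}

#' Mean editing over the activity window
#'
#' Unweighted mean of per-cytosine C-to-T percentages over the activity
#' window, taken over window positions whose protospacer base is C and
#' whose value is defined (e.g. C4-C8 averaging for a 4-8 window).
#'
#' @param editing An `editing_table` from [compute_editing()].
#' @return The mean percentage, or `NA` (flagged undefined) when no window
#'   cytosine has a defined value.
#' @export
window_mean_editing <- function(editing) {
  vals <- editing$pct_CtoT[editing$in_window & editing$defined]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Student's t-test of treated versus untreated editing
#'
#' Classical (pooled-variance) two-tailed two-sample t-test comparing
#' replicate-level editing percentages in a treated condition against the
#' untreated control, the significance rule used throughout the pipeline
#' (threshold P < 0.05). With fewer than two replicates in either group the
#' p-value is undefined and flagged; when both groups are identical
#' constant vectors the p-value is 1. When both groups have zero variance
#' but different means the t statistic is undefined and significance is not
#' computed (undefined, flagged) rather than forced to 0.
#'
#' @param treated,control Numeric vectors of per-replicate percentages.
#' @return A list with `p_value` (`NA` when undefined) and `defined`.
#' @export
test_vs_control <- function(treated, control) {
  treated <- treated[!is.na(treated)]
  control <- control[!is.na(control)]
  if (length(treated) < 2L || length(control) < 2L)
    return(list(p_value = NA_real_, defined = FALSE))
  if (stats::var(treated) == 0 && stats::var(control) == 0) {
    # degenerate: no within-group variance. Identical groups are the exact
    # null (p = 1); with differing means the t statistic is undefined
    # (division by zero), so significance is not computed.
    if (mean(treated) == mean(control))
      return(list(p_value = 1, defined = TRUE))
    return(list(p_value = NA_real_, defined = FALSE))
  }
  p <- stats::t.test(treated, control, var.equal = TRUE,
                     alternative = "two.sided")$p.value
  list(p_value = p, defined = TRUE)
}

#' Classify whether editing at a position is detectable
#'
#' A position is detectable only when its editing percentage exceeds the
#' detection limit AND the treated-versus-control difference is significant
#' (P < 0.05). At or below the limit, significance is not evaluated and the
#' result is `FALSE`.
#'
#' @param percent Editing percentage (may be `NA`).
#' @param p_value t-test p-value (may be `NA`).
#' @param limit Detection limit in percent, from [detection_limit()].
#' @param alpha Significance threshold (default 0.05).
#' @return Logical.
#' @export
classify_detectable <- function(percent, p_value, limit = detection_limit(30),
                                alpha = 0.05) {
  mapply(function(pc, pv) {
    if (is.na(pc) || pc <= limit) return(FALSE)
    !is.na(pv) && pv < alpha
  }, percent, p_value, USE.NAMES = FALSE)
}

#' Windowed indel frequency
#'
#' Percentage of aligned reads carrying an indel of at least `min_len`
#' bases anchored inside a `window_width`-base window centred on the
#' nickase cut site (`[nick - w/2, nick + w/2)` on the reference). A
#' deletion is anchored at its first deleted reference base and an
#' insertion at the reference base immediately 5' of the inserted run; a
#' read counts at most once however many qualifying events it carries.
#'
#' @param aln A [align_reads()] result.
#' @param spec The [amplicon_spec()].
#' @param window_width Window size in bases (default 30).
#' @param min_len Minimum indel length counted (default 2).
#' @return A list of class `indel_summary`: `percent_reads_with_indel`,
#'   `n_indel_reads`, `reads_counted`, `window` (0-based half-open),
#'   `min_indel_len`.
#' @export
count_indels <- function(aln, spec, window_width = 30L, min_len = 2L) {
  stopifnot(inherits(aln, "read_alignments"), inherits(spec, "amplicon_spec"))
  b <- nick_boundary(spec)
  half <- window_width %/% 2L
  win <- c(b - half, b + half)  # half-open
  ev <- aln$events
  qual <- ev[ev$length >= min_len & ev$anchor >= win[1] & ev$anchor < win[2],
             , drop = FALSE]
  n_pos <- length(unique(qual$read_id))
  n_tot <- aln$n_accepted
  structure(list(
    percent_reads_with_indel = if (n_tot > 0) 100 * n_pos / n_tot
                               else NA_real_,
    n_indel_reads = n_pos, reads_counted = n_tot,
    window = win, min_indel_len = as.integer(min_len)
  ), class = "indel_summary")
}

#' @export
print.indel_summary <- function(x, ...) {
  cat(sprintf(
    "indel_summary: %.3f%% of %d aligned reads (>=%d-base indels in [%d, %d))\n",
    x$percent_reads_with_indel, x$reads_counted, x$min_indel_len,
    x$window[1], x$window[2]))
  invisible(x)
}

#' Aggregate replicate editing tables with significance and detectability
#'
#' Combines per-replicate editing tables for one (locus, condition) against
#' matched untreated-control replicates: per position, the mean and s.d.
#' across replicates, the pooled-variance t-test p-value against control,
#' and the detectability call (percent above the detection limit and
#' P < 0.05). Raw p-values are reported; an optional Benjamini-Hochberg
#' adjustment across positions can be switched on.
#'
#' @param treated_tables,control_tables Lists of `editing_table`s
#'   (one per replicate).
#' @param limit Detection limit in percent.
#' @param p_adjust Apply Benjamini-Hochberg adjustment across positions
#'   before the detectability call (default `FALSE`, matching raw-p
#'   reporting).
#' @return A data.frame with per-position `mean_pct_CtoT`, `sd_pct_CtoT`,
#'   `control_mean_pct_CtoT`, `p_value`, `detectable`.
#' @export
aggregate_editing <- function(treated_tables, control_tables,
                              limit = detection_limit(30),
                              p_adjust = FALSE) {
  pos <- treated_tables[[1]]$position
  tmat <- sapply(treated_tables, function(t) t$pct_CtoT)
  cmat <- sapply(control_tables, function(t) t$pct_CtoT)
  tmat <- matrix(tmat, nrow = length(pos))
  cmat <- matrix(cmat, nrow = length(pos))
  mean_t <- rowMeans(tmat, na.rm = TRUE)
  sd_t <- apply(tmat, 1, stats::sd, na.rm = TRUE)
  mean_c <- rowMeans(cmat, na.rm = TRUE)
  p <- vapply(seq_along(pos), function(i)
    test_vs_control(tmat[i, ], cmat[i, ])$p_value, numeric(1))
  p_used <- if (p_adjust) stats::p.adjust(p, method = "BH") else p
  data.frame(position = pos,
             ref_offset = treated_tables[[1]]$ref_offset,
             in_window = treated_tables[[1]]$in_window,
             mean_pct_CtoT = mean_t, sd_pct_CtoT = sd_t,
             control_mean_pct_CtoT = mean_c,
             p_value = p,
             detectable = classify_detectable(mean_t, p_used, limit),
             stringsAsFactors = FALSE)
}
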