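# construct a base_call_table directly (counts are the quantity under test)
fake_table <- function(spec, counts) {
  ref_chars <- strsplit(spec$reference, "")[[1]]
  tab <- data.frame(offset = seq_along(ref_chars) - 1L, ref_base = ref_chars,
                    A = 0L, C = 0L, G = 0L, T = 0L, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(counts))) {
    i <- which(tab$offset == counts$offset[k])
    tab[i, c("A", "C", "G", "T")] <- counts[k, c("A", "C", "G", "T")]
  }
  tab$depth <- tab$A + tab$C + tab$G + tab$T
  attr(tab, "aligned_read_total") <- max(tab$depth)
  class(tab) <- c("base_call_table", "data.frame")
  tab
}

test_that("editing percentages are plain call fractions on the protospacer strand", {
  spec <- toy_spec()
  off6 <- resolve_protospacer(spec)$map$ref_offset[6]
  tab <- fake_table(spec, data.frame(offset = off6, A = 0, C = 75, G = 0,
                                     T = 25))
  ed <- compute_editing(tab, spec)
  expect_equal(ed$pct_CtoT[ed$position == 6], 25.0)
  expect_equal(ed$depth[ed$position == 6], 100L)
  # zero depth elsewhere is undefined, not 0%
  expect_true(all(is.na(ed$pct_CtoT[ed$position != 6])))
  expect_false(any(ed$defined[ed$position != 6]))
})

test_that("minus-strand protospacers report sequenced G-to-A as C-to-T", {
  spec <- toy_spec(strand = "-")
  off6 <- resolve_protospacer(spec)$map$ref_offset[6]
  tab <- fake_table(spec, data.frame(offset = off6, A = 10, C = 0, G = 90,
                                     T = 0))
  ed <- compute_editing(tab, spec)
  expect_equal(ed$pct_CtoT[ed$position == 6], 10.0)
})

test_that("non-cytosine activity-window positions are skipped with a warning", {
  # window 4-9: position 9 of the toy protospacer is A, not C
  spec <- toy_spec(window = c(4L, 9L))
  tab <- fake_table(spec, data.frame(offset = 0, A = 1, C = 0, G = 0, T = 0))
  expect_warning(ed <- compute_editing(tab, spec), "not cytosines")
  expect_false(9 %in% ed$position)
})

test_that("detection limit follows the quarter-error-rate rule and is monotone", {
  expect_equal(detection_limit(30), 0.025)
  expect_equal(detection_limit(20), 0.25)
  expect_equal(detection_limit(40), 0.0025)
  q <- seq(0, 41)
  expect_true(all(diff(detection_limit(q)) < 0))
})

test_that("treated-vs-control t-test matches the pooled-variance formula", {
  trt <- c(0.50, 0.55, 0.45)
  ctl <- c(0.010, 0.020, 0.015)
  res <- test_vs_control(trt, ctl)
  expect_lt(res$p_value, 0.001)
  # hand-computed classical Student's t with pooled variance
  sp2 <- ((length(trt) - 1) * var(trt) + (length(ctl) - 1) * var(ctl)) /
    (length(trt) + length(ctl) - 2)
  tstat <- (mean(trt) - mean(ctl)) /
    sqrt(sp2 * (1 / length(trt) + 1 / length(ctl)))
  p_hand <- 2 * pt(abs(tstat), df = length(trt) + length(ctl) - 2,
                   lower.tail = FALSE)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)

  # identical vectors: null case
  expect_equal(test_vs_control(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  # single replicate: undefined, flagged
  single <- test_vs_control(0.5, ctl)
  expect_true(is.na(single$p_value))
  expect_false(single$defined)
})

test_that("detectability requires both the limit and significance", {
  lim <- detection_limit(30)
  # below the limit significance is not evaluated
  expect_false(classify_detectable(0.020, NA, lim))
  expect_false(classify_detectable(0.020, 0.0001, lim))
  expect_true(classify_detectable(1.1, 0.003, lim))
  expect_false(classify_detectable(1.1, 0.20, lim))
  # monotone in percent for fixed significant p above the limit
  pcts <- seq(0.03, 50, length.out = 40)
  det <- classify_detectable(pcts, rep(0.01, 40), lim)
  expect_true(all(det))
  expect_false(any(diff(det) < 0))
})

test_that("windowed indel counting applies the 30-base, two-base-minimum rule", {
  spec <- toy_spec()
  ref <- spec$reference
  b <- nick_boundary(spec)
  reads <- c(
    del_read(ref, b, 2),           # 2-base deletion at the nick: counted
    del_read(ref, b, 1),           # 1-base deletion: below minimum
    del_read(ref, b + 20, 2),      # 2-base deletion outside the window
    ins_read(ref, b + 21, "TAG"),  # 3-base insertion 20+ bases from the nick
    ins_read(ref, b, "AC"),        # 2-base insertion at the nick: counted
    del_read(del_read(ref, b + 20, 2), b, 2),  # two indels, one in window
    ref                            # untouched
  )
  aln <- align_reads(reads_df(reads), spec)
  ind <- count_indels(aln, spec)
  expect_equal(ind$reads_counted, 7L)
  expect_equal(ind$n_indel_reads, 3L)
  expect_equal(ind$percent_reads_with_indel, 100 * 3 / 7)
  expect_equal(ind$window, c(b - 15L, b + 15L))
  # arithmetic check from the spec example: 7 qualifying of 100 reads -> 7%
  many <- c(replicate(7, del_read(ref, b, 3)), replicate(93, ref))
  ind100 <- count_indels(align_reads(reads_df(many), spec), spec)
  expect_equal(ind100$percent_reads_with_indel, 7.0)
})

test_that("count_indels agrees with an independent column-level recount", {
  spec <- toy_spec()
  cfg <- sim_config(n_reads = 400, indel_rate = 0.15,
                    indel_length_dist = c("1" = 0.3, "2" = 0.4, "3" = 0.3),
                    indel_type_probs = c(del = 0.6, ins = 0.4),
                    indel_jitter = 18L, background_ct_rate = 0, seed = 23)
  sim <- simulate_sample(cfg, spec)
  aln <- align_reads(sim$reads, spec)
  ind <- count_indels(aln, spec)
  oracle <- recount_indels(aln, spec)
  expect_equal(ind$n_indel_reads, oracle$n_indel_reads)
  expect_equal(ind$percent_reads_with_indel, oracle$percent)
})

test_that("window means average defined cytosines only", {
  spec <- toy_spec()
  ed <- data.frame(position = 4:8, pct_CtoT = c(10, 20, 30, 20, 20),
                   in_window = TRUE, defined = TRUE)
  expect_equal(window_mean_editing(ed), 20.0)
  ed$defined[3] <- FALSE
  ed$pct_CtoT[3] <- NA
  expect_equal(window_mean_editing(ed), 17.5)
  ed$defined <- FALSE
  expect_true(is.na(window_mean_editing(ed)))
})
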