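test_that("quality masking follows the threshold dialects exactly", {
  mk <- function(q) data.frame(read_id = "r1", sequence = "ACGT",
                               qualities = intToUtf8(q + 33L))
  # nothing below threshold
  out <- mask_low_quality(mk(c(40, 40, 40, 40)), 30, "strict_below")
  expect_identical(out$sequence, "ACGT")
  # Q < 30 masked in strict_below
  out <- mask_low_quality(mk(c(40, 29, 40, 40)), 30, "strict_below")
  expect_identical(out$sequence, "ANGT")
  # Q == 30 kept in strict_below but masked in at_or_below
  out <- mask_low_quality(mk(c(40, 30, 40, 40)), 30, "strict_below")
  expect_identical(out$sequence, "ACGT")
  out <- mask_low_quality(mk(c(40, 30, 40, 40)), 30, "at_or_below")
  expect_identical(out$sequence, "ANGT")
})

test_that("masking is idempotent and flags malformed records", {
  reads <- reads_df(c("ACGTACGT", "GGGTTTAA"))
  reads$qualities <- c("II(IIII(", "IIIIIIII")
  once <- mask_low_quality(reads, 30, "strict_below")
  twice <- mask_low_quality(once, 30, "strict_below")
  expect_identical(once$sequence, twice$sequence)
  bad <- reads; bad$qualities[1] <- "III"
  expect_error(mask_low_quality(bad, 30), "malformed")
})

test_that("phred_error_prob is the closed form 10^(-Q/10)", {
  expect_equal(phred_error_prob(30), 0.001)
  expect_equal(phred_error_prob(0), 1.0)
  expect_equal(phred_error_prob(10), 0.1)
  expect_error(phred_error_prob(-1))
})

test_that("FASTQ round-trips through the Biostrings readers", {
  spec <- toy_spec()
  sim <- simulate_sample(sim_config(n_reads = 25, seed = 9,
                                    quality_model = list(type = "mixture",
                                                         q_high = 38,
                                                         q_low = 20,
                                                         low_fraction = 0.2)),
                         spec)
  path <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_identical(back$sequence, sim$reads$sequence)
  expect_identical(back$qualities, sim$reads$qualities)
})

test_that("base tallies count aligned unmasked bases only", {
  spec <- toy_spec()
  ref <- spec$reference
  off <- resolve_protospacer(spec)$map$ref_offset[6]
  # 10 perfect reads
  aln <- align_reads(reads_df(rep(ref, 10)), spec)
  tab <- tally_bases(aln)
  ref_chars <- strsplit(ref, "")[[1]]
  for (b in c("A", "C", "G", "T"))
    expect_equal(tab[[b]], ifelse(ref_chars == b, 10L, 0L))
  expect_equal(attr(tab, "aligned_read_total"), 10L)

  # 3 of 10 reads carry T at a reference-C offset
  seqs <- c(rep(ref, 7), rep(sub_read(ref, off, "T"), 3))
  tab <- tally_bases(align_reads(reads_df(seqs), spec))
  expect_equal(tab$C[tab$offset == off], 7L)
  expect_equal(tab$T[tab$offset == off], 3L)

  # a masked (N) base is excluded from the tally
  reads <- reads_df(rep(ref, 10))
  q <- strsplit(reads$qualities[1], "")[[1]]
  q[off + 1] <- "("  # Q = 7
  reads$qualities[1] <- paste(q, collapse = "")
  masked <- mask_low_quality(reads, 30, "strict_below")
  tab <- tally_bases(align_reads(masked, spec))
  expect_equal(tab$depth[tab$offset == off], 9L)
})

test_that("tally totals conserve the number of aligned unmasked bases", {
  spec <- toy_spec()
  cfg <- sim_config(n_reads = 300, editing_profile = c("6" = 0.3),
                    indel_rate = 0.05, subst_error_rate = 0.01, seed = 13,
                    quality_model = list(type = "mixture", q_high = 40,
                                         q_low = 10, low_fraction = 0.03))
  sim <- simulate_sample(cfg, spec)
  masked <- mask_low_quality(sim$reads, 30, "strict_below")
  aln <- align_reads(masked, spec)
  tab <- tally_bases(aln)
  acc <- aln$alignments[aln$alignments$accepted, ]
  # independent count: non-gap, non-N read characters in reference columns
  expected <- 0L
  for (i in seq_len(nrow(acc))) {
    p <- strsplit(acc$pattern[i], "")[[1]]
    s <- strsplit(acc$subject[i], "")[[1]]
    expected <- expected + sum(s != "-" & p %in% c("A", "C", "G", "T"))
  }
  expect_equal(sum(tab$A + tab$C + tab$G + tab$T), expected)
  expect_true(all(tab$depth <= attr(tab, "aligned_read_total")))
})

test_that("protospacer extraction accepts exact flanks and rejects with reasons", {
  spec <- invitro_spec()
  f5 <- spec$flank5; f3 <- spec$flank3
  good <- paste0("AAAT", f5, TC_PROTO, f3, "GGCA")
  mut5 <- paste0("AAAT", paste0("T", substring(f5, 2)), TC_PROTO, f3, "GGCA")
  short <- paste0("AAAT", f5, substr(TC_PROTO, 1, 19), f3, "GGCA")
  long <- paste0("AAAT", f5, TC_PROTO, "A", f3, "GGCA")
  no3 <- paste0("AAAT", f5, TC_PROTO, "GGCAGGCAGGCA")
  res <- extract_protospacer(reads_df(c(good, mut5, short, long, no3)), spec)
  expect_equal(res$protospacers$status,
               c("accepted", "no_flank5", "wrong_length", "wrong_length",
                 "no_flank3"))
  expect_identical(res$protospacers$protospacer[1], TC_PROTO)
  expect_equal(unname(res$counts),
               c(accepted = 1L, no_flank5 = 1L, no_flank3 = 1L,
                 wrong_length = 2L), ignore_attr = TRUE)
})

test_that("extraction acceptance equals 1 - flank-mutation fraction exactly", {
  spec <- invitro_spec()
  for (f in c(0, 0.3, 1)) {
    cfg <- sim_config(n_reads = 200, background_ct_rate = 0, seed = 21)
    sim <- simulate_invitro_sample(cfg, spec, reject_fraction = f)
    res <- extract_protospacer(sim$reads, spec)
    expect_equal(unname(res$counts["accepted"]), round((1 - f) * 200))
  }
})
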