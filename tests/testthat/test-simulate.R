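test_that("null model emits reads identical to the reference", {
  spec <- toy_spec()
  cfg <- sim_config(n_reads = 100, background_ct_rate = 0, seed = 1)
  sim <- simulate_sample(cfg, spec)
  expect_equal(nrow(sim$reads), 100L)
  expect_true(all(sim$reads$sequence == spec$reference))
  expect_true(all(sim$truth_edits$n_edited == 0))
  expect_false(any(sim$truth_indels$has_indel))
  expect_true(all(sim$reads$qualities == strrep("I", nchar(spec$reference))))
})

test_that("saturating the profile edits every read at that position", {
  spec <- toy_spec()
  off <- resolve_protospacer(spec)$map$ref_offset[6]
  cfg <- sim_config(n_reads = 50, editing_profile = c("6" = 1),
                    background_ct_rate = 0, seed = 2)
  sim <- simulate_sample(cfg, spec)
  at6 <- substr(sim$reads$sequence, off + 1, off + 1)
  expect_true(all(at6 == "T"))
  # reference elsewhere
  rest <- paste0(substr(sim$reads$sequence, 1, off),
                 substring(sim$reads$sequence, off + 2))
  expect_true(all(rest == paste0(substr(spec$reference, 1, off),
                                 substring(spec$reference, off + 2))))
})

test_that("injected edit fraction obeys the binomial oracle", {
  spec <- toy_spec()
  cfg <- sim_config(n_reads = 10000, editing_profile = c("6" = 0.25),
                    background_ct_rate = 0, seed = 3)
  sim <- simulate_sample(cfg, spec)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(sim$truth_edits$true_rate - 0.25), 3 * se)
})

test_that("profile positions that are not cytosines are a configuration error", {
  spec <- toy_spec()  # position 1 is A
  cfg <- sim_config(n_reads = 10, editing_profile = c("1" = 0.5))
  expect_error(simulate_sample(cfg, spec), "not cytosines")
})

test_that("simulation is deterministic in the seed", {
  spec <- toy_spec()
  cfg <- sim_config(n_reads = 200, editing_profile = c("6" = 0.3),
                    indel_rate = 0.05, subst_error_rate = 0.005, seed = 11)
  a <- simulate_sample(cfg, spec)
  b <- simulate_sample(cfg, spec)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth_edits, b$truth_edits)
  # byte-identical FASTQ
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(a$reads, f1); write_fastq(b$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  cfg2 <- cfg; cfg2$seed <- 12L
  c <- simulate_sample(cfg2, spec)
  expect_false(identical(a$reads$sequence, c$reads$sequence))
})

test_that("truth table equals a direct recount of injected edits", {
  # no indels / errors, so the edited offset can be read straight off
  spec <- toy_spec()
  off <- resolve_protospacer(spec)$map$ref_offset[6]
  cfg <- sim_config(n_reads = 1500, editing_profile = c("6" = 0.4),
                    background_ct_rate = 0, seed = 4)
  sim <- simulate_sample(cfg, spec)
  n_t <- sum(substr(sim$reads$sequence, off + 1, off + 1) == "T")
  expect_equal(sim$truth_edits$n_edited, n_t)
  expect_equal(sim$truth_edits$n_covered, 1500L)
})

test_that("in-vitro reads carry exact flanks separated by 20 bases", {
  spec <- invitro_spec()
  cfg <- sim_config(n_reads = 100, background_ct_rate = 0, seed = 5)
  sim <- simulate_invitro_sample(cfg, spec, reject_fraction = 0)
  p5 <- regexpr(spec$flank5, sim$reads$sequence, fixed = TRUE)
  expect_true(all(p5 > 0))
  gap_start <- p5 + 14
  after <- substring(sim$reads$sequence, gap_start)
  expect_true(all(substr(after, 21, 34) == spec$flank3))
})

test_that("uniform in-vitro editing is recovered per position within 3 sigma", {
  spec <- invitro_spec()
  cpos <- seq(2, 20, by = 2)
  prof <- setNames(rep(0.5, length(cpos)), cpos)
  n <- 2000
  cfg <- sim_config(n_reads = n, editing_profile = prof,
                    background_ct_rate = 0, seed = 6)
  sim <- simulate_invitro_sample(cfg, spec, reject_fraction = 0)
  ext <- extract_protospacer(sim$reads, spec)
  expect_equal(unname(ext$counts["accepted"]), n)
  tal <- tally_protospacers(ext, spec)
  se <- sqrt(0.5 * 0.5 / n)
  for (p in cpos) {
    frac <- tal$T[tal$position == p] / tal$depth[tal$position == p]
    expect_lt(abs(frac - 0.5), 3 * se)
  }
})
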