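#' Run configuration for the end-to-end pipeline
#'
#' Bundles everything one analysis run needs: locus definitions, the sample
#' sheet, per-sample read sources (FASTQ paths or simulation configs), the
#' masking dialect and quality threshold, alignment scoring, indel-window
#' parameters, and the run seed from which every per-sample simulation seed
#' is derived.
#'
#' @param loci A list of [amplicon_spec()]s (named by locus or not).
#' @param samples Sample-sheet data.frame ([read_sample_sheet()] columns).
#' @param sim_configs Optional named list (by `sample_id`) of
#'   [sim_config()]s for samples without a `fastq_path`.
#' @param mode `"genomic"` or `"invitro"`; selects the masking dialect
#'   (`strict_below` for genomic, `at_or_below` for in-vitro) unless
#'   `masking_mode` overrides it.
#' @param masking_mode Optional explicit masking dialect.
#' @param q_threshold Phred threshold (default 30).
#' @param scoring An [alignment_scoring()].
#' @param window_width,min_indel_len Indel-window parameters (30, 2).
#' @param control_indel_threshold Untreated-control indel percentage above
#'   which a locus is flagged indel-unreliable and excluded from indel
#'   reporting (default 5).
#' @param on_target Optional name of the on-target locus, enabling
#'   specificity ratios against every other locus.
#' @param seed Run seed; per-sample substream seeds are derived from it.
#' @param outdir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(loci, samples, sim_configs = list(),
                       mode = c("genomic", "invitro"), masking_mode = NULL,
                       q_threshold = 30L, scoring = alignment_scoring(),
                       window_width = 30L, min_indel_len = 2L,
                       control_indel_threshold = 5,
                       on_target = NULL, seed = 1L, outdir = tempfile("run")) {
  mode <- match.arg(mode)
  if (is.null(masking_mode))
    masking_mode <- if (mode == "genomic") "strict_below" else "at_or_below"
  names(loci) <- vapply(loci, `[[`, character(1), "locus_name")
  bad <- setdiff(samples$locus_name, names(loci))
  if (length(bad))
    stop("sample sheet references undefined locus: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  no_src <- is.na(samples$fastq_path) & !samples$sample_id %in% names(sim_configs)
  if (any(no_src))
    stop("sample(s) without fastq_path or simulation config: ",
         paste(samples$sample_id[no_src], collapse = ", "), call. = FALSE)
  structure(list(loci = loci, samples = samples, sim_configs = sim_configs,
                 mode = mode, masking_mode = masking_mode,
                 q_threshold = as.integer(q_threshold), scoring = scoring,
                 window_width = as.integer(window_width),
                 min_indel_len = as.integer(min_indel_len),
                 control_indel_threshold = control_indel_threshold,
                 on_target = on_target, seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

#' Load a run configuration from a YAML document
#'
#' The document names locus config files ([read_locus_config()]), a sample
#' sheet TSV ([read_sample_sheet()]), optional per-sample simulation blocks
#' for samples without a `fastq_path`, and any [run_config()] scalar
#' (`mode`, `q_threshold`, `on_target`, `seed`, `outdir`, ...). Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param outdir Optional override of the document's output directory.
#' @param seed Optional override of the document's seed.
#' @return A [run_config()].
#' @export
load_run_config <- function(path, outdir = NULL, seed = NULL) {
  doc <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  loci <- lapply(resolve(unlist(doc$loci)), read_locus_config)
  samples <- read_sample_sheet(resolve(doc$sample_sheet),
                               loci = vapply(loci, `[[`, character(1),
                                             "locus_name"))
  has_path <- !is.na(samples$fastq_path) & nzchar(samples$fastq_path)
  samples$fastq_path[has_path] <- resolve(samples$fastq_path[has_path])
  sims <- lapply(doc$sim_configs, function(b) {
    if (!is.null(b$editing_profile))
      b$editing_profile <- unlist(b$editing_profile)
    if (!is.null(b$indel_length_dist))
      b$indel_length_dist <- unlist(b$indel_length_dist)
    if (!is.null(b$indel_type_probs))
      b$indel_type_probs <- unlist(b$indel_type_probs)
    do.call(sim_config, b)
  })
  run_config(loci, samples, sim_configs = sims,
             mode = if (is.null(doc$mode)) "genomic" else doc$mode,
             masking_mode = doc$masking_mode,
             q_threshold = if (is.null(doc$q_threshold)) 30L
                           else doc$q_threshold,
             window_width = if (is.null(doc$window_width)) 30L
                            else doc$window_width,
             min_indel_len = if (is.null(doc$min_indel_len)) 2L
                             else doc$min_indel_len,
             on_target = doc$on_target,
             seed = if (!is.null(seed)) seed
                    else if (is.null(doc$seed)) 1L else doc$seed,
             outdir = if (!is.null(outdir)) outdir
                      else if (is.null(doc$outdir)) tempfile("run")
                      else resolve(doc$outdir))
}

# deterministic per-sample substream seed (kept below 2^31)
sample_seed <- function(run_seed, i) {
  as.integer((as.double(run_seed) * 1009 + i * 7919) %% 2147483629)
}

#' Run the full quantification pipeline
#'
#' For every sample: obtain reads (from FASTQ or the synthetic generator),
#' mask low-quality calls, align to the amplicon reference, tally base
#' calls, and compute per-cytosine editing and windowed indel statistics.
#' Replicates are then aggregated per (locus, condition, delivery, dose)
#' with treated-versus-control significance and detectability calls, and
#' cross-locus specificity statistics are produced when an on-target locus
#' is named. All outputs (per-sample and aggregate TSVs, a JSON run report,
#' a run log listing every parameter) are written under `config$outdir`.
#' Given the same config and seed the TSV outputs are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, the run report (also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("ampliconBE run, seed %d", config$seed),
           sprintf("mode: %s; masking: %s; q_threshold: %d",
                   config$mode, config$masking_mode, config$q_threshold),
           sprintf("alignment: match %+d mismatch %+d gap_open %d gap_extend %d floor_frac %.2f revcomp %s",
                   config$scoring$match, config$scoring$mismatch,
                   config$scoring$gap_open, config$scoring$gap_extend,
                   config$scoring$floor_frac, config$scoring$try_revcomp),
           sprintf("indel window: %d bases around nick boundary; min length %d; deletion anchored at first deleted base, insertion at base 5' of run",
                   config$window_width, config$min_indel_len),
           sprintf("detection limit: %.4g%% at Q%d",
                   detection_limit(config$q_threshold), config$q_threshold),
           sprintf("control indel-unreliability threshold: %g%%",
                   config$control_indel_threshold))

  ss <- config$samples
  limit <- detection_limit(config$q_threshold)
  per_sample <- list()
  errors <- list()
  for (i in seq_len(nrow(ss))) {
    sid <- ss$sample_id[i]
    res <- tryCatch(
      process_one_sample(config, i),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sid]] <- list(sample = sid, stage = "process",
                            message = conditionMessage(res))
      log <- c(log, sprintf("ERROR sample %s: %s", sid,
                            conditionMessage(res)))
      next
    }
    per_sample[[sid]] <- res
    log <- c(log, sprintf(
      "sample %s (%s): %d reads in -> %d aligned (%d rejected); window mean %.4g%%; indel %.4g%%",
      sid, ss$locus_name[i], res$n_input, res$n_aligned,
      res$n_input - res$n_aligned, res$window_mean, res$indel_percent))
  }

  agg <- aggregate_run(config, per_sample, limit)
  spec_tabs <- specificity_tables(config, agg, limit)

  # persist outputs
  for (sid in names(per_sample)) {
    s <- per_sample[[sid]]
    write_tsv(s$editing, file.path(out, paste0(sid, "_editing.tsv")))
    write_tsv(s$basecalls, file.path(out, paste0(sid, "_basecalls.tsv")))
  }
  write_tsv(agg$editing_summary, file.path(out, "editing_summary.tsv"))
  write_tsv(agg$indel_summary, file.path(out, "indel_summary.tsv"))
  if (!is.null(spec_tabs$specificity))
    write_tsv(spec_tabs$specificity, file.path(out, "specificity.tsv"))
  if (!is.null(spec_tabs$regression))
    write_tsv(spec_tabs$regression, file.path(out, "regression.tsv"))
  writeLines(log, file.path(out, "run.log"))

  report <- list(
    parameters = list(seed = config$seed, mode = config$mode,
                      masking_mode = config$masking_mode,
                      q_threshold = config$q_threshold,
                      detection_limit_percent = limit,
                      scoring = unclass(config$scoring),
                      window_width = config$window_width,
                      min_indel_len = config$min_indel_len),
    read_counts = lapply(per_sample, function(s)
      list(input = s$n_input, masked = s$n_input, aligned = s$n_aligned,
           rejected = s$n_input - s$n_aligned)),
    samples = lapply(per_sample, function(s)
      list(locus = s$locus_name, window_mean = s$window_mean,
           indel_percent = s$indel_percent)),
    editing_summary = agg$editing_summary,
    indel_summary = agg$indel_summary,
    specificity = spec_tabs$specificity,
    regression = spec_tabs$regression,
    errors = unname(errors))
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  write_markdown_summary(report, file.path(out, "report.md"))
  invisible(report)
}

process_one_sample <- function(config, i) {
  ss <- config$samples
  sid <- ss$sample_id[i]
  spec <- config$loci[[ss$locus_name[i]]]
  if (!is.na(ss$fastq_path[i]) && nzchar(ss$fastq_path[i])) {
    reads <- read_fastq(ss$fastq_path[i])
  } else {
    sc <- config$sim_configs[[sid]]
    sc$seed <- sample_seed(config$seed, i)
    sim <- simulate_sample(sc, spec)
    fq <- file.path(config$outdir, paste0(sid, ".fastq"))
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(sim$reads, fq)
    write_truth(sim, config$outdir, prefix = sid)
    reads <- sim$reads
  }
  masked <- mask_low_quality(reads, config$q_threshold, config$masking_mode)
  aln <- align_reads(masked, spec, config$scoring)
  tab <- tally_bases(aln)
  ed <- compute_editing(tab, spec)
  ind <- count_indels(aln, spec, config$window_width, config$min_indel_len)
  list(sample_id = sid, locus_name = spec$locus_name,
       n_input = aln$n_input, n_aligned = aln$n_accepted,
       basecalls = as.data.frame(tab), editing = as.data.frame(ed),
       editing_table = ed,
       window_mean = window_mean_editing(ed),
       indel_percent = ind$percent_reads_with_indel)
}

aggregate_run <- function(config, per_sample, limit) {
  ss <- config$samples
  ss <- ss[ss$sample_id %in% names(per_sample), , drop = FALSE]
  ed_rows <- list(); ind_rows <- list()
  for (locus in unique(ss$locus_name)) {
    is_ctrl <- ss$locus_name == locus & ss$condition == "untreated_control"
    ctrl_ids <- ss$sample_id[is_ctrl]
    ctrl_tabs <- lapply(per_sample[ctrl_ids], `[[`, "editing_table")
    ctrl_indel <- vapply(per_sample[ctrl_ids], `[[`, numeric(1),
                         "indel_percent")
    indel_unreliable <- length(ctrl_indel) > 0 &&
      mean(ctrl_indel, na.rm = TRUE) > config$control_indel_threshold
    trt <- ss[ss$locus_name == locus & ss$condition == "treated", ,
              drop = FALSE]
    grp_key <- paste(trt$delivery, trt$dose, sep = "\r")
    for (grp in split(trt, grp_key)) {
      if (!nrow(grp)) next
      ids <- grp$sample_id
      tabs <- lapply(per_sample[ids], `[[`, "editing_table")
      agg <- aggregate_editing(tabs, ctrl_tabs, limit = limit)
      agg <- cbind(locus_name = locus, delivery = grp$delivery[1],
                   dose = grp$dose[1], n_replicates = nrow(grp), agg)
      ed_rows[[length(ed_rows) + 1L]] <- agg
      wm <- vapply(per_sample[ids], `[[`, numeric(1), "window_mean")
      ip <- vapply(per_sample[ids], `[[`, numeric(1), "indel_percent")
      ind_p <- test_vs_control(ip, ctrl_indel)
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        locus_name = locus, delivery = grp$delivery[1], dose = grp$dose[1],
        n_replicates = nrow(grp),
        window_mean_pct = mean(wm, na.rm = TRUE),
        window_mean_sd = stats::sd(wm),
        indel_pct = mean(ip, na.rm = TRUE), indel_sd = stats::sd(ip),
        control_indel_pct = if (length(ctrl_indel)) mean(ctrl_indel)
                            else NA_real_,
        indel_p_value = ind_p$p_value,
        indel_detectable = !indel_unreliable &&
          isTRUE(ind_p$defined && ind_p$p_value < 0.05 &&
                 mean(ip, na.rm = TRUE) > limit),
        indel_unreliable = indel_unreliable,
        stringsAsFactors = FALSE)
    }
  }
  list(editing_summary = if (length(ed_rows)) do.call(rbind, ed_rows)
                         else data.frame(),
       indel_summary = if (length(ind_rows)) do.call(rbind, ind_rows)
                       else data.frame())
}

specificity_tables <- function(config, agg, limit) {
  if (is.null(config$on_target) || !nrow(agg$indel_summary))
    return(list(specificity = NULL, regression = NULL))
  ind <- agg$indel_summary
  on <- ind[ind$locus_name == config$on_target, , drop = FALSE]
  off <- ind[ind$locus_name != config$on_target, , drop = FALSE]
  if (!nrow(on)) return(list(specificity = NULL, regression = NULL))
  rows <- list()
  for (i in seq_len(nrow(off))) {
    key <- on$delivery == off$delivery[i] &
      (is.na(on$dose) & is.na(off$dose[i]) |
         !is.na(on$dose) & !is.na(off$dose[i]) & on$dose == off$dose[i])
    if (!any(key)) next
    o <- on[which(key)[1], ]
    sr <- specificity_ratio(o$window_mean_pct, off$window_mean_pct[i],
                            limit = limit)
    eir <- editing_indel_ratio(off$window_mean_pct[i], off$indel_pct[i],
                               limit = limit)
    rows[[length(rows) + 1L]] <- data.frame(
      on_target = config$on_target, off_target = off$locus_name[i],
      delivery = off$delivery[i], dose = off$dose[i],
      on_pct = sr$on_percent, off_pct_observed = sr$off_percent_observed,
      off_pct_used = sr$off_percent_used, specificity_ratio = sr$ratio,
      lower_bound = sr$lower_bound,
      off_editing_indel_ratio = eir$ratio,
      off_editing_indel_lower_bound = eir$lower_bound,
      stringsAsFactors = FALSE)
  }
  specificity <- if (length(rows)) do.call(rbind, rows) else NULL

  # dose-response regression per off-target locus, when >= 3 doses exist
  regression <- NULL
  doses_on <- on[!is.na(on$dose), , drop = FALSE]
  if (nrow(doses_on) >= 3L) {
    reg_rows <- list()
    for (loc in unique(off$locus_name)) {
      o2 <- off[off$locus_name == loc & !is.na(off$dose), , drop = FALSE]
      common <- intersect(doses_on$dose, o2$dose)
      if (length(common) < 3L) next
      x <- doses_on$window_mean_pct[match(common, doses_on$dose)]
      y <- o2$window_mean_pct[match(common, o2$dose)]
      fit <- tryCatch(fit_dose_response(x, y), error = function(e) NULL)
      if (is.null(fit)) next
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        off_target = loc, n = fit$n, slope = fit$slope,
        intercept = fit$intercept, r_squared = fit$r_squared,
        f_statistic = fit$f_statistic, p_value = fit$p_value,
        stringsAsFactors = FALSE)
    }
    if (length(reg_rows)) regression <- do.call(rbind, reg_rows)
  }
  list(specificity = specificity, regression = regression)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_markdown_summary <- function(report, path) {
  lines <- c("# ampliconBE run summary", "",
             sprintf("- seed: %d; mode: %s; masking: %s; Q threshold: %d",
                     report$parameters$seed, report$parameters$mode,
                     report$parameters$masking_mode,
                     report$parameters$q_threshold),
             sprintf("- detection limit: %.4g%%",
                     report$parameters$detection_limit_percent), "")
  if (length(report$samples)) {
    lines <- c(lines, "## Samples", "",
               "| sample | locus | window mean C>T % | indel % |",
               "|---|---|---|---|")
    for (sid in names(report$samples)) {
      s <- report$samples[[sid]]
      lines <- c(lines, sprintf("| %s | %s | %.4g | %.4g |", sid, s$locus,
                                s$window_mean, s$indel_percent))
    }
    lines <- c(lines, "")
  }
  if (!is.null(report$specificity) && nrow(report$specificity)) {
    lines <- c(lines, "## Specificity", "",
               "| off-target | delivery | on % | off % used | ratio | lower bound |",
               "|---|---|---|---|---|---|")
    sp <- report$specificity
    for (i in seq_len(nrow(sp)))
      lines <- c(lines, sprintf("| %s | %s | %.4g | %.4g | %s%.4g | %s |",
                                sp$off_target[i], sp$delivery[i],
                                sp$on_pct[i], sp$off_pct_used[i],
                                if (sp$lower_bound[i]) ">= " else "",
                                sp$specificity_ratio[i], sp$lower_bound[i]))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
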