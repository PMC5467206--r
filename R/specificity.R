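#' On-target:off-target specificity ratio with detection-limit imputation
#'
#' Divides the observed on-target editing efficiency by the off-target
#' efficiency. When off-target editing is at or below the detection limit,
#' the limit itself is used as a conservative stand-in, and the resulting
#' ratio is marked as a lower bound ("at least this specific").
#'
#' @param on_percent On-target editing percentage (> 0 for a defined ratio).
#' @param off_percent Observed off-target editing percentage (may be `NA`
#'   or 0 when nothing was measured).
#' @param limit Detection limit in percent ([detection_limit()]).
#' @return A list of class `specificity_report`: `on_percent`,
#'   `off_percent_observed`, `off_percent_used`, `ratio`, `imputed`,
#'   `lower_bound`, `defined`.
#' @examples
#' specificity_ratio(26.0, 0, limit = 0.025)$ratio  # 1040, a lower bound
#' @export
specificity_ratio <- function(on_percent, off_percent,
                              limit = detection_limit(30)) {
  if (is.na(on_percent) || on_percent <= 0)
    return(structure(list(on_percent = on_percent,
                          off_percent_observed = off_percent,
                          off_percent_used = NA_real_, ratio = NA_real_,
                          imputed = FALSE, lower_bound = FALSE,
                          defined = FALSE),
                     class = "specificity_report"))
  imputed <- is.na(off_percent) || off_percent <= limit
  used <- if (imputed) limit else off_percent
  structure(list(on_percent = on_percent,
                 off_percent_observed = off_percent,
                 off_percent_used = used,
                 ratio = on_percent / used,
                 imputed = imputed, lower_bound = imputed,
                 defined = TRUE),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  if (!x$defined) {
    cat("specificity ratio undefined (on-target editing not positive)\n")
    return(invisible(x))
  }
  cat(sprintf("specificity ratio: %s%.3g (on %.3g%% / off %.3g%%%s)\n",
              if (x$lower_bound) ">= " else "", x$ratio, x$on_percent,
              x$off_percent_used,
              if (x$imputed) ", imputed to detection limit" else ""))
  invisible(x)
}

#' Fold change between two editing percentages
#'
#' Plain ratio `a / b`; the reporting layer rounds to the nearest integer
#' fold ("37-fold"). When the denominator is zero it is imputed to the
#' detection limit and the fold is a lower bound.
#'
#' @param a,b Percentages; `b` the baseline.
#' @param limit Detection limit used when `b` is 0.
#' @return A list with `fold`, `lower_bound`, and `label` (e.g. `"37-fold"`).
#' @examples
#' fold_change(1.1, 0.03)$label  # "37-fold"
#' @export
fold_change <- function(a, b, limit = detection_limit(30)) {
  stopifnot(!is.na(a))
  lower <- FALSE
  if (is.na(b) || b == 0) {
    b <- limit
    lower <- TRUE
  }
  fold <- a / b
  list(fold = fold, lower_bound = lower,
       label = paste0(if (lower) ">=" else "", format(round(fold)), "-fold"))
}

#' Editing:indel ratio
#'
#' Window-averaged C-to-T read percentage divided by the percentage of
#' reads carrying an indel, a per-locus measure of base-editing precision.
#' An indel percentage at or below its detection limit is imputed to the
#' limit and the ratio marked a lower bound.
#'
#' @param window_mean Window-mean editing percentage ([window_mean_editing()]).
#' @param indel_percent Indel read percentage ([count_indels()]).
#' @param limit Detection limit in percent.
#' @return A list with `ratio`, `lower_bound`, `defined`.
#' @export
editing_indel_ratio <- function(window_mean, indel_percent,
                                limit = detection_limit(30)) {
  if (is.na(window_mean))
    return(list(ratio = NA_real_, lower_bound = FALSE, defined = FALSE))
  lower <- is.na(indel_percent) || indel_percent <= limit
  denom <- if (lower) limit else indel_percent
  list(ratio = window_mean / denom, lower_bound = lower, defined = TRUE)
}

#' Dose-response regression of off-target on on-target editing
#'
#' Ordinary least-squares fit of off-target editing against on-target
#' editing across a titration series, with the F-test for a non-zero slope.
#' A tight fit (R-squared near 1) indicates off-target editing scales with
#' on-target editing across doses; a flat fit indicates the two are
#' decoupled.
#'
#' @param on,off Numeric vectors (>= 3 points) of on- and off-target
#'   editing percentages per dose.
#' @return A list of class `dose_response_fit`: `n`, `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `p_value`.
#' @export
fit_dose_response <- function(on, off) {
  ok <- !is.na(on) & !is.na(off)
  on <- on[ok]; off <- off[ok]
  n <- length(on)
  if (n < 3L) stop("dose-response regression needs at least 3 points",
                   call. = FALSE)
  if (stats::var(on) == 0)
    stop("dose-response regression undefined: no variance in on-target axis",
         call. = FALSE)
  if (stats::var(off) == 0) {
    # constant response: slope 0 by construction, no association
    fit <- list(n = n, slope = 0, intercept = off[1], r_squared = 0,
                f_statistic = 0, p_value = 1)
    class(fit) <- "dose_response_fit"
    return(fit)
  }
  m <- stats::lm(off ~ on)
  # summary.lm warns on numerically perfect fits; the fit itself is valid
  sm <- suppressWarnings(summary(m))
  fstat <- unname(sm$fstatistic)
  fit <- list(n = n,
              slope = unname(stats::coef(m)[2]),
              intercept = unname(stats::coef(m)[1]),
              r_squared = sm$r.squared,
              f_statistic = fstat[1],
              p_value = stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE))
  class(fit) <- "dose_response_fit"
  fit
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "dose-response fit (n=%d): off = %.4g + %.4g * on, R^2 = %.3f, P = %.4g (F-test)\n",
    x$n, x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Mean specificity improvement across cytosines
#'
#' Aggregates per-cytosine specificity-ratio improvements between two
#' conditions (e.g. a high-fidelity editor versus the original, or protein
#' versus plasmid delivery) as the arithmetic mean of per-cytosine ratio
#' quotients. The ratio-of-means variant is also returned for comparison.
#' Any imputed (lower-bound) input propagates a lower-bound flag into the
#' aggregate.
#'
#' @param ratios_a,ratios_b Lists of `specificity_report`s for matched
#'   cytosines under condition A and B; the improvement is A over B.
#' @return A list with `mean_of_ratios`, `ratio_of_means`, `lower_bound`,
#'   `n`, and `method` (the declared default, `"mean_of_ratios"`).
#' @export
specificity_improvement <- function(ratios_a, ratios_b) {
  stopifnot(length(ratios_a) == length(ratios_b))
  ra <- vapply(ratios_a, `[[`, numeric(1), "ratio")
  rb <- vapply(ratios_b, `[[`, numeric(1), "ratio")
  ok <- !is.na(ra) & !is.na(rb)
  lower <- any(vapply(ratios_a[ok], `[[`, logical(1), "lower_bound")) ||
           any(vapply(ratios_b[ok], `[[`, logical(1), "lower_bound"))
  list(mean_of_ratios = mean(ra[ok] / rb[ok]),
       ratio_of_means = mean(ra[ok]) / mean(rb[ok]),
       lower_bound = lower, n = sum(ok), method = "mean_of_ratios")
}
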