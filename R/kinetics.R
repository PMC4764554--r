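#' @title Reporter mRNA decay kinetics
#' @description Semilog least-squares quantification of transcription-
#'   shutoff decay assays: band-ratio normalization to a co-transfected
#'   control, first-order decay fits (t1/2 = ln2 / k_decay) with t-based
#'   95% confidence intervals, ANCOVA comparison of decay slopes, the
#'   delta-delta-Ct qPCR statistic, and immunoprecipitation relative
#'   recovery.
#' @name kinetics
NULL

#' Normalize a decay time course
#'
#' Experimental band intensities are divided by the matched transfection-
#' control bands, and the ratio series is rescaled so the first time point
#' equals 1 (fraction of RNA remaining).
#'
#' @param times time points in minutes, strictly increasing.
#' @param raw_exp,raw_ctrl positive band intensities, matched lengths.
#' @return Data frame of class `decay_timecourse` with columns `time`,
#'   `abundance`.
#' @export
normalize_timecourse <- function(times, raw_exp, raw_ctrl) {
  if (length(times) != length(raw_exp) || length(times) != length(raw_ctrl)) {
    stop("times, raw_exp, raw_ctrl must have matched lengths")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(raw_ctrl <= 0)) stop("zero or negative control band")
  if (any(raw_exp <= 0)) stop("zero or negative experimental band")
  ratio <- raw_exp / raw_ctrl
  out <- data.frame(time = times, abundance = ratio / ratio[1])
  class(out) <- c("decay_timecourse", class(out))
  out
}

#' Fit first-order decay by semilog least squares
#'
#' Ordinary least squares of ln(abundance) on time; `k_decay` is the
#' negative slope and `t_half = ln2 / k_decay`. The 95% confidence
#' interval for the half-life is the slope's t-based interval with its
#' endpoints transformed through `t = ln2 / k` (not the delta method).
#' Replicates, when present, are pooled into one regression. A
#' non-positive estimated k leaves the half-life unresolved, reported as a
#' one-sided bound ("> last time point"); the same applies to the upper
#' confidence limit when the slope interval crosses zero.
#'
#' @param tc data frame with columns `time` and `abundance` (optionally a
#'   `replicate` column; rows are pooled), >= 3 points over >= 2 distinct
#'   times.
#' @return Object of class `decay_fit`: `k_decay` (per minute), `t_half`
#'   (minutes, `Inf` when unresolved), `ci95`, `r_squared`, `n`,
#'   `resolved`, `bound` (text bound such as "> 390 min" when
#'   unresolved).
#' @export
fit_exponential_decay <- function(tc) {
  stopifnot(all(c("time", "abundance") %in% names(tc)))
  if (nrow(tc) < 3L || length(unique(tc$time)) < 2L) {
    stop("need >= 3 points spanning >= 2 distinct times")
  }
  if (any(tc$abundance <= 0)) stop("abundances must be positive")
  fit <- stats::lm(log(abundance) ~ time, data = tc)
  slope <- unname(stats::coef(fit)[2])
  k <- -slope
  ci_slope <- suppressWarnings(stats::confint(fit, "time", level = 0.95))
  k_lo <- -ci_slope[1, 2]  # smaller k from the upper slope limit
  k_hi <- -ci_slope[1, 1]
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  tmax <- max(tc$time)
  resolved <- is.finite(k) && k > 0
  t_half <- if (resolved) log(2) / k else Inf
  ci <- c(
    low = if (is.finite(k_hi) && k_hi > 0) log(2) / k_hi else NA_real_,
    high = if (is.finite(k_lo) && k_lo > 0) log(2) / k_lo else Inf
  )
  structure(
    list(k_decay = k, t_half = t_half, ci95 = ci, r_squared = r2,
         n = nrow(tc), resolved = resolved,
         bound = if (resolved) NA_character_ else sprintf("> %g min", tmax)),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$resolved) {
    cat(sprintf("<decay_fit: t1/2 = %.1f min [%.1f, %s], k = %.4g/min, R2 = %.3f>\n",
                x$t_half, x$ci95["low"],
                if (is.finite(x$ci95["high"])) sprintf("%.1f", x$ci95["high"])
                else "Inf",
                x$k_decay, x$r_squared))
  } else {
    cat(sprintf("<decay_fit: half-life not resolved (%s)>\n", x$bound))
  }
  invisible(x)
}

#' ANCOVA comparison of decay slopes
#'
#' Fits ln(abundance) against time, group, and their interaction; the
#' returned p-value is the two-tailed F test on the time-by-group
#' interaction (equality of slopes). In the two-group case F equals the
#' square of the classical two-slope t statistic. Replicates are pooled
#' into the regression by default; `use_replicate_means = TRUE` averages
#' log abundance per (group, time) first.
#'
#' @param groups named list of data frames with columns `time` and either
#'   `log_abundance` or `abundance` (log taken internally), >= 3 points
#'   each.
#' @param use_replicate_means collapse replicates to means per time point.
#' @return A [test_result]; `statistic` is the interaction F.
#' @export
compare_slopes_ancova <- function(groups, use_replicate_means = FALSE) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  dat <- do.call(rbind, lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    y <- if ("log_abundance" %in% names(g)) g$log_abundance else {
      if (any(g$abundance <= 0)) stop("abundances must be positive")
      log(g$abundance)
    }
    data.frame(time = g$time, y = y, group = nm, stringsAsFactors = FALSE)
  }))
  if (use_replicate_means) {
    dat <- stats::aggregate(y ~ time + group, dat, mean)
  }
  if (any(tapply(dat$y, dat$group, length) < 3L)) {
    stop("each group needs >= 3 points")
  }
  dat$group <- factor(dat$group)
  fit <- stats::lm(y ~ time * group, data = dat)
  if (any(is.na(stats::coef(fit)))) stop("singular design")
  an <- stats::anova(fit)
  row <- grep("time:group", rownames(an))
  f <- an[row, "F value"]
  p <- an[row, "Pr(>F)"]
  if (is.na(f)) { # zero residual variance with identical slopes
    f <- 0; p <- 1
  }
  test_result(f, p, as.integer(table(dat$group)),
              "ANCOVA equality of slopes (two-tailed)")
}

#' Relative transcript abundance by the delta-delta-Ct method
#'
#' `2 ^ -((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   finite Ct values.
#' @return Relative abundance (1 = no change).
#' @export
delta_delta_ct <- function(ct_target_treated, ct_ref_treated,
                           ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control,
            ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Immunoprecipitation relative recovery
#'
#' Bound/total ratio of the experimental RNA divided by the bound/total
#' ratio of the co-expressed recovery-control RNA, optionally normalized
#' to the same quantity for a designated reference condition (so the
#' reference reads 1).
#'
#' @param bound_exp,total_exp experimental RNA in bound and total
#'   fractions.
#' @param bound_ctrl,total_ctrl recovery-control RNA in bound and total
#'   fractions.
#' @param reference_value optional relative recovery of the reference
#'   condition to normalize against.
#' @return Normalized recovery (unitless).
#' @export
relative_recovery <- function(bound_exp, total_exp, bound_ctrl, total_ctrl,
                              reference_value = NULL) {
  if (any(c(total_exp, total_ctrl) <= 0)) stop("total fractions must be positive")
  if (bound_ctrl == 0) stop("zero control recovery")
  r <- (bound_exp / total_exp) / (bound_ctrl / total_ctrl)
  if (!is.null(reference_value)) {
    if (reference_value == 0) stop("zero reference recovery")
    r <- r / reference_value
  }
  r
}
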