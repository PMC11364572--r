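#' Consensus vertebral level of an odd reader panel
#'
#' The consensus level is the median of the readers' chosen levels under
#' cranio-caudal ordering; with three mutually distinct levels this is the
#' middle one.
#'
#' @param levels character vector of chosen levels, one per reader; the
#'   panel must be odd-sized with at least 3 readers.
#' @param ordering level names in cranio-caudal order (e.g.
#'   `default_scheme()$vertebrae$name`).
#' @return The consensus level name.
#' @export
consensus_level <- function(levels, ordering) {
  n <- length(levels)
  if (n < 3L || n %% 2L == 0L)
    sc_stop("unsupported_configuration",
            "consensus requires an odd panel of >= 3 readers, got %d", n)
  idx <- match(levels, ordering)
  if (anyNA(idx))
    sc_stop("unavailable_level", "level(s) not in the ordering: %s",
            paste(levels[is.na(idx)], collapse = ", "))
  ordering[sort(idx)[(n + 1L) %/% 2L]]
}

#' Mean absolute error between paired measurements
#'
#' @param a,b numeric vectors of paired angles.
#' @return list with `mae` (mean of `|a - b|`) and `sd` (sample SD of the
#'   absolute differences).
#' @export
mae <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 1L) sc_stop("no_measurement", "no pairs")
  d <- abs(a - b)
  list(mae = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC with
#' its F-based 95% confidence interval, computed from the two-way ANOVA mean
#' squares (rows = cases, columns = raters). The reliability band follows
#' the usual cut-points: below 0.50 poor, 0.50-0.75 moderate, 0.75-0.90
#' good, above 0.90 excellent.
#'
#' @param ratings numeric matrix, cases x raters, no missing cells.
#' @param conf confidence level.
#' @return list with `icc` (clipped to `[0, 1]`; `clipped` flags a negative
#'   estimate), `lower`, `upper`, `band`, and the mean squares `ms`.
#' @export
icc <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L)
    sc_stop("unsupported_configuration", "need >= 5 cases and >= 2 raters")
  if (anyNA(ratings))
    sc_stop("unsupported_configuration", "missing cells are not supported")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based CI for ICC(A,1), two-way random absolute agreement
  alpha <- 1 - conf
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_u <- stats::qf(1 - alpha / 2, n - 1, v)
  f_l <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  clipped <- est < 0
  band <- function(x) {
    if (x < 0.5) "poor" else if (x < 0.75) "moderate"
    else if (x <= 0.90) "good" else "excellent"
  }
  list(icc = max(0, min(1, est)), estimate = est, lower = lower, upper = upper,
       band = band(max(0, min(1, est))), clipped = clipped,
       ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k)
}

#' Bland-Altman analysis
#'
#' Bias is `mean(a - b)`; the limits of agreement are bias +/- 1.96 SD of
#' the differences.
#'
#' @param a,b numeric vectors of paired measurements (>= 2 pairs).
#' @param mult multiplier for the limits (1.96 for 95%).
#' @return A `bland_altman` object with `bias`, `sd`, `lower`, `upper` and
#'   the per-pair `means`/`diffs`.
#' @export
bland_altman <- function(a, b, mult = 1.96) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) sc_stop("no_measurement", "need >= 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  structure(list(bias = mean(d), sd = s,
                 lower = mean(d) - mult * s, upper = mean(d) + mult * s,
                 means = (a + b) / 2, diffs = d, mult = mult),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %+.2f, limits of agreement [%+.2f, %+.2f] (n = %d)\n",
              x$bias, x$lower, x$upper, length(x$diffs)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against means with the bias (solid), limits of agreement
#' (dashed) and the clinical tolerance band (red) drawn.
#'
#' @param ba a [bland_altman()] result.
#' @param tolerance clinical tolerance in the units of the measurements
#'   (drawn at +/- tolerance).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, tolerance = 5) {
  df <- data.frame(m = ba$means, d = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = m, y = d)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(ba$lower, ba$upper), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-tolerance, tolerance), colour = "red") +
    ggplot2::labs(x = "Mean of paired measurements (deg)",
                  y = "Difference (deg)") +
    ggplot2::theme_minimal()
}

#' Clinical acceptance simulation
#'
#' Emulates a reader reviewing the automatic measurement: an automatic
#' measurement at the reader's levels is accepted when it differs from the
#' manual one by strictly less than the tolerance (5 degrees is the
#' clinically acceptable Cobb measurement error); otherwise the reader is
#' assumed to reject and re-measure.
#'
#' @param manual data.frame with columns `case`, `source`, `top`, `bottom`,
#'   `angle`.
#' @param automatic data.frame with columns `case`, `top`, `bottom`,
#'   `angle`: the automatic angles at the needed level pairs.
#' @param tolerance acceptance threshold in degrees (strict less-than).
#' @return list with `fraction` accepted, `n`, and `verdicts` (per manual
#'   measurement: the paired automatic angle, difference and verdict).
#' @export
acceptance_simulation <- function(manual, automatic, tolerance = 5) {
  needed <- c("case", "top", "bottom", "angle")
  stopifnot(all(c(needed, "source") %in% names(manual)), all(needed %in% names(automatic)))
  key <- function(df) paste(df$case, df$top, df$bottom, sep = "|")
  am <- automatic$angle[match(key(manual), key(automatic))]
  if (anyNA(am)) {
    miss <- unique(key(manual)[is.na(am)])
    sc_stop("unavailable_level",
            "no automatic measurement at level(s): %s", paste(miss, collapse = ", "))
  }
  diff <- manual$angle - am
  accepted <- abs(diff) < tolerance
  verdicts <- data.frame(case = manual$case, source = manual$source,
                         top = manual$top, bottom = manual$bottom,
                         manual = manual$angle, automatic = am, diff = diff,
                         accepted = accepted, stringsAsFactors = FALSE)
  list(fraction = mean(accepted), n = length(accepted), verdicts = verdicts)
}

#' Vertebral level agreement table
#'
#' Tabulates, per reader, how far the reader's chosen levels lie from the
#' reference (e.g. the levels of the maximal automatic angle). The distance
#' of a measurement is the absolute top-level offset plus the absolute
#' bottom-level offset, in vertebral levels; buckets are exact match, one
#' level, two levels, and more than two.
#'
#' @param manual data.frame with `case`, `source`, `top`, `bottom`.
#' @param reference data.frame with `case`, `top`, `bottom` (one row per
#'   case).
#' @param ordering vertebra names in cranio-caudal order.
#' @return data.frame with one row per reader and columns `same`,
#'   `one_level`, `two_levels`, `more` (fractions) plus `n`.
#' @export
level_agreement_table <- function(manual, reference, ordering) {
  mi <- match(manual$case, reference$case)
  if (anyNA(mi))
    sc_stop("unavailable_level", "case(s) missing from the reference: %s",
            paste(unique(manual$case[is.na(mi)]), collapse = ", "))
  dist <- abs(match(manual$top, ordering) - match(reference$top[mi], ordering)) +
    abs(match(manual$bottom, ordering) - match(reference$bottom[mi], ordering))
  out <- lapply(split(dist, manual$source), function(d) {
    data.frame(same = mean(d == 0), one_level = mean(d == 1),
               two_levels = mean(d == 2), more = mean(d > 2), n = length(d))
  })
  cbind(source = names(out), do.call(rbind, out), row.names = NULL)
}

#' Threefold manual-vs-automatic comparison
#'
#' Reproduces the reliability workflow on a set of cases: (1) level
#' agreement between each reader and the maximal automatic measurement, (2)
#' angle agreement of the automatic measurement at the reader-chosen levels
#' (ICC, MAE, Bland-Altman, acceptance fraction), and (3) the maximal
#' automatic angle against the per-case mean manual angle, plus the
#' automatic angle at the consensus levels.
#'
#' @param manual data.frame: `case`, `source`, `top`, `bottom`, `angle` for
#'   every reader and case (complete panel).
#' @param auto_max data.frame: `case`, `top`, `bottom`, `angle` of the
#'   maximal automatic measurement per case.
#' @param auto_at_levels data.frame: `case`, `top`, `bottom`, `angle` of
#'   automatic measurements covering all reader-chosen and consensus level
#'   pairs.
#' @param ordering vertebra names cranial to caudal.
#' @param tolerance acceptance threshold (degrees).
#' @return An `agreement_report` list; see the fields in the examples.
#' @export
compare_measurements <- function(manual, auto_max, auto_at_levels, ordering,
                                 tolerance = 5) {
  readers <- sort(unique(manual$source))
  cases <- sort(unique(manual$case))
  wide <- sapply(readers, function(r) {
    m <- manual[manual$source == r, ]
    m$angle[match(cases, m$case)]
  })
  if (anyNA(wide))
    sc_stop("unsupported_configuration", "incomplete reader panel")
  mean_manual <- rowMeans(wide)
  amax <- auto_max$angle[match(cases, auto_max$case)]

  level_tab <- level_agreement_table(manual, auto_max, ordering)

  acc <- acceptance_simulation(manual, auto_at_levels, tolerance = tolerance)
  same_level_auto <- acc$verdicts$automatic
  icc_same_level <- lapply(readers, function(r) {
    sel <- acc$verdicts$source == r
    icc(cbind(acc$verdicts$manual[sel], acc$verdicts$automatic[sel]))
  })
  names(icc_same_level) <- readers

  cons <- do.call(rbind, lapply(cases, function(cs) {
    m <- manual[manual$case == cs, ]
    data.frame(case = cs,
               top = consensus_level(m$top, ordering),
               bottom = consensus_level(m$bottom, ordering),
               stringsAsFactors = FALSE)
  }))
  ka <- paste(auto_at_levels$case, auto_at_levels$top, auto_at_levels$bottom, sep = "|")
  kc <- paste(cons$case, cons$top, cons$bottom, sep = "|")
  cons$angle <- auto_at_levels$angle[match(kc, ka)]
  if (anyNA(cons$angle))
    sc_stop("unavailable_level", "no automatic measurement at consensus level(s): %s",
            paste(kc[is.na(cons$angle)], collapse = ", "))

  structure(list(
    cases = cases, readers = readers,
    level_agreement = level_tab,
    acceptance = acc,
    icc_same_level = icc_same_level,
    mae_same_level = mae(acc$verdicts$manual, acc$verdicts$automatic),
    icc_readers = icc(wide),
    icc_max_vs_mean = icc(cbind(amax, mean_manual)),
    mae_max_vs_mean = mae(amax, mean_manual),
    ba_max_vs_manual = bland_altman(rep(amax, times = length(readers)),
                                    as.vector(wide)),
    ba_same_level = bland_altman(acc$verdicts$automatic, acc$verdicts$manual),
    consensus = cons,
    icc_consensus_vs_mean = icc(cbind(cons$angle, mean_manual)),
    mean_manual = mean_manual, auto_max = amax
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d cases, %d readers\n",
              length(x$cases), length(x$readers)))
  cat(sprintf("  reader-panel ICC: %.3f [%.3f, %.3f] (%s)\n",
              x$icc_readers$icc, x$icc_readers$lower, x$icc_readers$upper,
              x$icc_readers$band))
  cat(sprintf("  max auto vs mean manual: ICC %.3f, MAE %.2f deg\n",
              x$icc_max_vs_mean$icc, x$mae_max_vs_mean$mae))
  cat(sprintf("  same-level acceptance (<%g deg): %.1f%%\n",
              5, 100 * x$acceptance$fraction))
  invisible(x)
}
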