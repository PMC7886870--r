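#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator S(t) = prod over event times t_i <= t of
#' (1 - d_i/n_i), with d_i deaths among n_i at risk.  Censored observations
#' reduce risk sets only.  With no events at all the curve is identically 1
#' and the event list is empty.
#'
#' @param times positive survival times in months.
#' @param events 0/1 event indicators (1 = death observed, 0 = censored).
#' @return Object of class `km_curve` with fields `event_times`,
#'   `n_at_risk`, `n_events`, `survival` (estimates at each event time) and
#'   `n` (patients).
#' @export
km_fit <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 n_at_risk = fit$n.risk[keep],
                 n_events = fit$n.event[keep],
                 survival = fit$surv[keep],
                 n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d patients, %d event time(s)\n",
              x$n, length(x$event_times)))
  med <- median_survival(x)
  cat(sprintf("  median survival: %s\n",
              if (is.na(med)) "not reached" else sprintf("%g months", med)))
  invisible(x)
}

#' Median survival of a Kaplan-Meier curve
#'
#' The smallest event time at which the survival estimate drops to 0.5 or
#' below; `NA` when the curve never reaches 0.5.
#'
#' @param curve a `km_curve`.
#' @return Months, or NA when undefined.
#' @export
median_survival <- function(curve) {
  hit <- which(curve$survival <= 0.5)
  if (!length(hit)) NA_real_ else curve$event_times[hit[1L]]
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' At each distinct event time the 2x2 table of deaths by group is
#' accumulated as observed-minus-expected for group A with its
#' hypergeometric variance; chi2 = (sum O-E)^2 / sum Var and p is taken
#' from the chi-square distribution with 1 df.  With no events (zero total
#' variance) the test returns chi2 = 0, p = 1.
#'
#' @param timesA,eventsA survival times and 0/1 event flags of group A.
#' @param timesB,eventsB same for group B.
#' @return List with `chi2` (>= 0) and `p` (in (0, 1\]).
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  stopifnot(length(timesA) > 0, length(timesB) > 0)
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- rep(0:1, c(length(timesA), length(timesB)))
  if (sum(event) == 0) return(list(chi2 = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  chi2 <- unname(sd$chisq)
  if (!is.finite(chi2)) return(list(chi2 = 0, p = 1))
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Single-gene marker values for a cohort
#'
#' @param cohort a `cohort`.
#' @param gene gene symbol carried as an expression column.
#' @return Object of class `marker_values`: `marker_name`, `values` (named
#'   by sample id), `excluded` (data frame of dropped samples with reasons).
#' @export
marker_values <- function(cohort, gene) {
  gene <- toupper(gene)
  if (!gene %in% cohort_genes(cohort))
    stop("gene column missing from cohort: ", gene,
         " (available: ", toString(cohort_genes(cohort)), ")", call. = FALSE)
  structure(list(marker_name = gene,
                 values = stats::setNames(cohort[[gene]], cohort$sample_id),
                 excluded = data.frame(sample_id = character(0),
                                       reason = character(0))),
            class = "marker_values")
}

#' Two-gene expression-ratio marker
#'
#' Per-patient ratio of two expression columns (e.g. GCK/HK2).  Patients
#' with both values zero are excluded with a logged reason (the ratio is
#' undefined); a zero denominator with a positive numerator yields +Inf,
#' which participates in cutoff scans by rank only, never arithmetic.
#'
#' @param cohort a `cohort`.
#' @param numerator,denominator gene symbols.
#' @return A `marker_values` named `"<numerator>/<denominator>"`.
#' @export
ratio_values <- function(cohort, numerator, denominator) {
  numerator <- toupper(numerator); denominator <- toupper(denominator)
  for (g in c(numerator, denominator))
    if (!g %in% cohort_genes(cohort))
      stop("gene column missing from cohort: ", g,
           " (available: ", toString(cohort_genes(cohort)), ")", call. = FALSE)
  num <- cohort[[numerator]]
  den <- cohort[[denominator]]
  undef <- num == 0 & den == 0
  vals <- ifelse(den == 0, Inf, num / den)
  excluded <- data.frame(sample_id = cohort$sample_id[undef],
                         reason = rep("ratio undefined (numerator and denominator both zero)",
                                      sum(undef)),
                         stringsAsFactors = FALSE)
  if (nrow(excluded))
    message("ratio marker: excluded ", nrow(excluded), " patient(s): ",
            toString(excluded$sample_id))
  structure(list(marker_name = paste0(numerator, "/", denominator),
                 values = stats::setNames(vals[!undef], cohort$sample_id[!undef]),
                 excluded = excluded),
            class = "marker_values")
}

#' @export
print.marker_values <- function(x, ...) {
  cat(sprintf("Marker %s: %d value(s), %d excluded\n",
              x$marker_name, length(x$values), nrow(x$excluded)))
  invisible(x)
}

#' Optimal-cutoff survival stratification
#'
#' Scans all distinct observed marker values as candidate cutoffs (high
#' group: value strictly greater than the cutoff), keeping only cutoffs
#' where both groups contain at least `floor(min_group_frac * n)` patients,
#' and returns the stratification with the smallest log-rank p (ties broken
#' by the smaller cutoff).  This is the "best expression cutoff" convention
#' of the Protein Atlas survival analyses; no multiple-testing correction
#' is applied across cutoffs, and the number scanned is reported so the
#' optimism of the minimum can be judged.
#'
#' @param cohort a `cohort`.
#' @param marker a `marker_values` (its excluded samples are not used).
#' @param min_group_frac minimum fraction of retained patients per group
#'   (default 0.2, bounding the scan to the 20th-80th percentile band).
#' @return Object of class `strat_result`: `marker_name`, `cutoff`, `chi2`,
#'   `p`, `high_group`/`low_group` sample ids, per-group `km_curve`s and
#'   medians, `delta_median` (NA when either median is undefined),
#'   `n_cutoffs_scanned`.
#' @export
best_cutoff_stratify <- function(cohort, marker, min_group_frac = 0.2) {
  stopifnot(inherits(marker, "marker_values"),
            min_group_frac >= 0, min_group_frac <= 0.5)
  keep <- cohort$sample_id %in% names(marker$values)
  d <- as.data.frame(cohort)[keep, c("sample_id", "os_months", "event")]
  v <- marker$values[d$sample_id]
  n <- nrow(d)
  if (n < 10L) stop("need at least 10 retained patients", call. = FALSE)
  min_size <- max(1L, floor(min_group_frac * n))
  candidates <- sort(unique(v[is.finite(v)]))
  best <- NULL
  n_scanned <- 0L
  for (cut in candidates) {
    high <- v > cut
    if (sum(high) < min_size || sum(!high) < min_size) next
    n_scanned <- n_scanned + 1L
    lr <- logrank_test(d$os_months[high], d$event[high],
                       d$os_months[!high], d$event[!high])
    if (is.null(best) || lr$p < best$p) best <- c(lr, cutoff = cut)
  }
  if (is.null(best))
    stop("no admissible cutoff for marker ", marker$marker_name,
         " (group-size constraint unsatisfiable)", call. = FALSE)
  high <- v > best$cutoff
  km_high <- km_fit(d$os_months[high], d$event[high])
  km_low <- km_fit(d$os_months[!high], d$event[!high])
  med_h <- median_survival(km_high)
  med_l <- median_survival(km_low)
  structure(list(marker_name = marker$marker_name,
                 cutoff = best$cutoff, chi2 = best$chi2, p = best$p,
                 high_group = d$sample_id[high], low_group = d$sample_id[!high],
                 km_high = km_high, km_low = km_low,
                 median_high = med_h, median_low = med_l,
                 delta_median = if (is.na(med_h) || is.na(med_l)) NA_real_
                                else abs(med_h - med_l),
                 n_cutoffs_scanned = n_scanned,
                 excluded = marker$excluded),
            class = "strat_result")
}

#' @export
print.strat_result <- function(x, ...) {
  cat(sprintf("Optimal-cutoff stratification: %s\n", x$marker_name))
  cat(sprintf("  cutoff %.4g: high n=%d, low n=%d (%d cutoffs scanned)\n",
              x$cutoff, length(x$high_group), length(x$low_group),
              x$n_cutoffs_scanned))
  cat(sprintf("  log-rank chi2 = %.3f, p = %.3g\n", x$chi2, x$p))
  cat(sprintf("  median survival high/low: %s / %s months; delta %s\n",
              fmt_med(x$median_high), fmt_med(x$median_low),
              fmt_med(x$delta_median)))
  invisible(x)
}

fmt_med <- function(m) if (is.na(m)) "undefined" else sprintf("%.1f", m)

#' Kaplan-Meier plot of a stratification
#' @param x a `strat_result`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.strat_result <- function(x, ...) {
  step <- function(km) list(t = c(0, rep(km$event_times, each = 2)),
                            s = c(1, 1, rep(km$survival, each = 2))[
                              seq_len(2 * length(km$event_times) + 1)])
  h <- step(x$km_high); l <- step(x$km_low)
  graphics::plot(NA, xlim = c(0, max(h$t, l$t, 1)), ylim = c(0, 1),
                 xlab = "Overall survival (months)", ylab = "Survival probability",
                 main = sprintf("%s (cutoff %.3g, p = %.2g)",
                                x$marker_name, x$cutoff, x$p), ...)
  graphics::lines(h$t, h$s, col = "#2166AC", lwd = 2)
  graphics::lines(l$t, l$s, col = "#B2182B", lwd = 2)
  graphics::legend("topright", c("high", "low"),
                   col = c("#2166AC", "#B2182B"), lwd = 2, bty = "n")
  invisible(x)
}

#' Restrict a cohort to uncensored patients
#'
#' Keeps only patients whose death was observed (event = 1), i.e. those for
#' whom the period between diagnosis and death is precisely known, as used
#' for rank-correlation analyses.
#'
#' @param cohort a `cohort`.
#' @return The uncensored `cohort` (possibly empty); idempotent.
#' @export
uncensored <- function(cohort) {
  out <- as.data.frame(cohort)[cohort$event == 1, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_dropped = attr(cohort, "n_dropped"),
            class = c("cohort", "data.frame"))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Ranks both inputs (mean ranks for ties), computes the Pearson
#' correlation of the ranks, and derives p from the t distribution with
#' n - 2 degrees of freedom.  The t-approximation is accurate for the
#' cohort sizes this package targets (n >= 100); for n below about 10 the
#' exact permutation distribution would differ.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return Object of class `correlation_result`: `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("constant input", call. = FALSE)
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.3g, n = %d\n",
              x$rho, x$p, x$n))
  invisible(x)
}

#' Write Kaplan-Meier curves of a stratification as TSV
#'
#' One row per event time per group: group, time, at_risk, events, survival.
#'
#' @param x a `strat_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_curves <- function(x, path) {
  row <- function(km, label) {
    if (!length(km$event_times))
      return(data.frame(group = character(0), time = numeric(0),
                        at_risk = numeric(0), events = numeric(0),
                        survival = numeric(0)))
    data.frame(group = label, time = km$event_times, at_risk = km$n_at_risk,
               events = km$n_events, survival = km$survival)
  }
  utils::write.table(rbind(row(x$km_high, "high"), row(x$km_low, "low")),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
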