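#' Split participants into high- and low-accuracy groups
#'
#' Participants strictly above `hi` form the high group and strictly below
#' `lo` the low group; the middle band (and exact boundary values) is
#' excluded. The defaults, 0.505 and 0.12, keep the two groups roughly
#' balanced in the original study samples.
#'
#' @param accuracy Named numeric vector of accuracies in \[0, 1\].
#' @param hi High-group threshold (exclusive), default 0.505.
#' @param lo Low-group threshold (exclusive), default 0.12.
#' @return A list of class `group_split`: `high_ids`, `low_ids`,
#'   `excluded_ids`, `hi`, `lo`.
#' @export
split_groups <- function(accuracy, hi = 0.505, lo = 0.12) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop("need 0 <= lo < hi <= 1", call. = FALSE)
  }
  if (is.null(names(accuracy))) {
    names(accuracy) <- as.character(seq_along(accuracy))
  }
  high <- names(accuracy)[accuracy > hi]
  low <- names(accuracy)[accuracy < lo]
  if (length(high) == 0L) warning("high-accuracy group is empty",
                                  call. = FALSE)
  if (length(low) == 0L) warning("low-accuracy group is empty",
                                 call. = FALSE)
  structure(list(high_ids = high, low_ids = low,
                 excluded_ids = setdiff(names(accuracy), c(high, low)),
                 hi = hi, lo = lo),
            class = "group_split")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value (thin wrapper over [stats::t.test()]).
#'
#' @param x,y Numeric samples (>= 2 each; at least one with positive
#'   variance).
#' @return List with `t`, `p`, `df`, `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @export
welch_ttest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("degenerate samples: both groups have zero variance",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_x = mean(x), mean_y = mean(y),
       n_x = length(x), n_y = length(y))
}

#' Simple ordinary least-squares fit
#'
#' OLS of `y` on `x` with conventional standard errors (thin wrapper over
#' [stats::lm()]), returning the handful of quantities the study report
#' needs.
#'
#' @param x Predictor (>= 3 points, positive variance).
#' @param y Response, same length; a constant response is rejected as
#'   degenerate.
#' @return List with `slope`, `intercept`, `se_slope`, `r_squared`, `p`
#'   (two-sided, for the slope) and `n`.
#' @export
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  # zero variance up to floating-point noise counts as degenerate
  if (stats::sd(x) <= 1e-10 * max(1, max(abs(x)))) {
    stop("predictor has zero variance", call. = FALSE)
  }
  if (stats::sd(y) <= 1e-10 * max(1, max(abs(y)))) {
    stop("response has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  sxx <- sum((x - mean(x))^2)
  se_slope <- sqrt(sum(res^2) / (n - 2) / sxx)
  slope <- unname(stats::coef(fit)[2L])
  tval <- if (se_slope > 0) slope / se_slope else sign(slope) * Inf
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1L]),
       se_slope = se_slope,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       p = 2 * stats::pt(-abs(tval), df = n - 2),
       n = n)
}

#' Study pipeline configuration
#'
#' @param dt Resampling interval in ms (default 20).
#' @param variance_threshold Cumulative variance threshold for the
#'   reference subspace (default 0.5).
#' @param hi,lo Accuracy group thresholds (defaults 0.505 and 0.12).
#' @param k Optional explicit subspace dimension (overrides the threshold).
#' @param center Center the spectra matrix before the SVD? Default `FALSE`.
#' @param dfa_min_scale,dfa_n_scales DFA scale-grid settings; the maximum
#'   scale is N/4.
#' @param dfa_degree DFA detrending degree (default 1).
#' @return A list of class `study_config`.
#' @export
study_config <- function(dt = 20, variance_threshold = 0.5, hi = 0.505,
                         lo = 0.12, k = NULL, center = FALSE,
                         dfa_min_scale = 4, dfa_n_scales = 20,
                         dfa_degree = 1) {
  structure(list(dt = dt, variance_threshold = variance_threshold, hi = hi,
                 lo = lo, k = k, center = center,
                 dfa_min_scale = dfa_min_scale,
                 dfa_n_scales = dfa_n_scales, dfa_degree = dfa_degree),
            class = "study_config")
}

#' Run the full two-sample study pipeline
#'
#' End-to-end analysis of two cohorts of accuracy-labelled traces:
#' \enumerate{
#'   \item resample every trace to the common grid and trim jointly across
#'     both samples to one even length;
#'   \item Fourier transform every trace;
#'   \item fit the reference (accuracy) subspace on sample 1's
#'     high-accuracy group at the configured variance threshold;
#'   \item score every sample-2 participant with eta;
#'   \item Welch-test eta between sample 2's high and low groups;
#'   \item regress eta and accuracy over all of sample 2 — both directions
#'     are computed and labelled, since either reading ("fit regressed on
#'     accuracy" vs "performance regressed on fit") may be wanted;
#'   \item run DFA on every participant's trace;
#'   \item regress the DFA exponent alpha on accuracy over sample 2.
#' }
#' The pipeline is deterministic given its inputs and configuration.
#' Degenerate regressions (for instance a rank-1 cohort where every eta is
#' 1) are flagged in the report rather than raised.
#'
#' @param sample1,sample2 Lists of [raw_trace()] or [uniform_trace()]
#'   objects, each carrying an `accuracy`.
#' @param config A [study_config()].
#' @return An object of class `study_report`.
#' @export
run_study <- function(sample1, sample2, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage: ", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  as_uniform <- function(tr) {
    if (inherits(tr, "uniform_trace")) tr else resample_uniform(tr, config$dt)
  }
  u1 <- stage("preprocess sample 1", lapply(sample1, as_uniform))
  u2 <- stage("preprocess sample 2", lapply(sample2, as_uniform))
  trimmed <- stage("joint trim", trim_cohort(c(u1, u2)))
  u1 <- trimmed[seq_along(u1)]
  u2 <- trimmed[length(u1) + seq_along(u2)]

  acc_of <- function(traces) {
    a <- vapply(traces, function(tr) {
      if (is.null(tr$accuracy)) NA_real_ else tr$accuracy
    }, numeric(1))
    names(a) <- vapply(traces, function(tr) tr$participant_id, character(1))
    if (anyNA(a)) stop("every trace must carry an accuracy", call. = FALSE)
    a
  }
  acc1 <- stage("accuracy sample 1", acc_of(u1))
  acc2 <- stage("accuracy sample 2", acc_of(u2))

  s1 <- stage("spectra sample 1", lapply(u1, spectrum_dft))
  s2 <- stage("spectra sample 2", lapply(u2, spectrum_dft))

  g1 <- stage("group split sample 1",
              split_groups(acc1, hi = config$hi, lo = config$lo))
  g2 <- stage("group split sample 2",
              split_groups(acc2, hi = config$hi, lo = config$lo))

  ids1 <- names(acc1)
  sub <- stage("subspace fit", {
    fit_cohort <- s1[ids1 %in% g1$high_ids]
    if (length(fit_cohort) < 2L) {
      stop("sample-1 high-accuracy group has fewer than 2 members")
    }
    reference_subspace(fit_cohort, threshold = config$variance_threshold,
                       k = config$k, center = config$center)
  })

  eta_tab <- stage("eta projection", predict(sub, s2))
  eta_tab$group <- ifelse(eta_tab$participant_id %in% g2$high_ids, "high",
                          ifelse(eta_tab$participant_id %in% g2$low_ids,
                                 "low", "middle"))

  welch <- stage("welch test", {
    hi_eta <- eta_tab$eta[eta_tab$group == "high"]
    lo_eta <- eta_tab$eta[eta_tab$group == "low"]
    if (length(hi_eta) < 2L || length(lo_eta) < 2L) {
      list(degenerate = TRUE,
           message = "fewer than 2 members in a group")
    } else {
      tryCatch(welch_ttest(hi_eta, lo_eta),
               error = function(e) list(degenerate = TRUE,
                                        message = conditionMessage(e)))
    }
  })

  try_ols <- function(x, y) {
    tryCatch(ols_fit(x, y),
             error = function(e) list(degenerate = TRUE,
                                      message = conditionMessage(e)))
  }
  ols_eta_on_acc <- try_ols(eta_tab$accuracy, eta_tab$eta)
  ols_acc_on_eta <- try_ols(eta_tab$eta, eta_tab$accuracy)

  dfa_one <- function(tr, sample_label) {
    fit <- dfa(tr, scales = dfa_scales(length(tr$z),
                                       min_scale = config$dfa_min_scale,
                                       n_scales = config$dfa_n_scales),
               degree = config$dfa_degree)
    data.frame(participant_id = tr$participant_id, sample = sample_label,
               accuracy = tr$accuracy, alpha = fit$alpha, H = fit$H,
               classification = fit$classification,
               stationarity = fit$stationarity,
               n_scales_used = fit$n_scales_used,
               stringsAsFactors = FALSE)
  }
  dfa_tab <- stage("dfa", do.call(rbind, c(
    lapply(u1, dfa_one, sample_label = "sample1"),
    lapply(u2, dfa_one, sample_label = "sample2"))))
  dfa2 <- dfa_tab[dfa_tab$sample == "sample2", ]
  ols_alpha_on_acc <- try_ols(dfa2$accuracy, dfa2$alpha)

  structure(list(k = sub$k, variance_fraction = sub$variance_fraction,
                 subspace = sub,
                 n_common = sub$n,
                 groups = list(sample1 = g1, sample2 = g2),
                 eta = eta_tab,
                 welch_eta = welch,
                 ols_eta_on_accuracy = ols_eta_on_acc,
                 ols_accuracy_on_eta = ols_acc_on_eta,
                 dfa = dfa_tab,
                 ols_alpha_on_accuracy = ols_alpha_on_acc,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Two-sample cursor-dynamics study report\n")
  cat(sprintf("  common trace length N = %d, dt = %g ms\n", x$n_common,
              x$config$dt))
  cat(sprintf("  reference subspace: k = %d (%.1f%% variance, threshold %.2f)\n",
              x$k, 100 * x$variance_fraction, x$config$variance_threshold))
  cat(sprintf("  groups: sample1 %d high / %d low; sample2 %d high / %d low\n",
              length(x$groups$sample1$high_ids),
              length(x$groups$sample1$low_ids),
              length(x$groups$sample2$high_ids),
              length(x$groups$sample2$low_ids)))
  if (isTRUE(x$welch_eta$degenerate)) {
    cat("  Welch test on eta: degenerate (", x$welch_eta$message, ")\n",
        sep = "")
  } else {
    cat(sprintf(
      "  Welch test, eta high vs low (sample 2): t = %.3f, df = %.1f, p = %.3g\n",
      x$welch_eta$t, x$welch_eta$df, x$welch_eta$p))
  }
  fmt_ols <- function(label, o) {
    if (isTRUE(o$degenerate)) {
      cat(sprintf("  %s: degenerate (%s)\n", label, o$message))
    } else {
      cat(sprintf("  %s: slope = %.3f (SE %.3f), R^2 = %.3f, p = %.3g\n",
                  label, o$slope, o$se_slope, o$r_squared, o$p))
    }
  }
  fmt_ols("OLS eta ~ accuracy     ", x$ols_eta_on_accuracy)
  fmt_ols("OLS accuracy ~ eta     ", x$ols_accuracy_on_eta)
  fmt_ols("OLS alpha ~ accuracy   ", x$ols_alpha_on_accuracy)
  cat(sprintf("  DFA: %d / %d participants with alpha > 1\n",
              sum(x$dfa$alpha > 1), nrow(x$dfa)))
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits a JSON summary plus per-participant eta and DFA tables as CSV.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary_list <- list(
    n_common = report$n_common,
    k = report$k,
    variance_fraction = report$variance_fraction,
    groups = list(
      sample1 = list(n_high = length(report$groups$sample1$high_ids),
                     n_low = length(report$groups$sample1$low_ids)),
      sample2 = list(n_high = length(report$groups$sample2$high_ids),
                     n_low = length(report$groups$sample2$low_ids))
    ),
    welch_eta = report$welch_eta,
    ols_eta_on_accuracy = report$ols_eta_on_accuracy,
    ols_accuracy_on_eta = report$ols_accuracy_on_eta,
    ols_alpha_on_accuracy = report$ols_alpha_on_accuracy,
    config = unclass(report$config)
  )
  jsonlite::write_json(summary_list, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(report$eta, file.path(dir, "eta.csv"), row.names = FALSE)
  utils::write.csv(report$dfa, file.path(dir, "dfa.csv"), row.names = FALSE)
  invisible(dir)
}
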