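# From per-replica event times to the ranking statistics: replica
# summaries with an explicit censoring policy, Spearman/Pearson against
# experimental pk_off, regression with outlier removal and prediction,
# bootstrap sample-size analysis, and median-threshold classification.

#' pk_off from a dissociation rate
#' @param k_off Dissociation rate in 1/min (positive).
#' @return `-log10(k_off)`.
#' @export
pkoff_from_koff <- function(k_off) {
  if (any(k_off <= 0)) stop("k_off must be positive")
  -log10(k_off)
}

#' Summarise replica event times under a censoring policy
#'
#' @param times Numeric replica times.
#' @param censored Logical per replica (default none).
#' @param policy "cap" keeps censored replicas at their recorded cap value
#'   (never biases the mean fast), "drop" removes them, "cap2" doubles the
#'   cap value.
#' @return List (mean, sem, n, n_censored). SEM is sd/sqrt(n) over the
#'   retained values.
#' @export
summarize_replicas <- function(times, censored = rep(FALSE, length(times)),
                               policy = c("cap", "drop", "cap2")) {
  policy <- match.arg(policy)
  stopifnot(length(times) == length(censored), length(times) >= 1L)
  vals <- switch(policy,
                 cap = times,
                 drop = times[!censored],
                 cap2 = ifelse(censored, 2 * times, times))
  if (length(vals) == 0L) stop("all replicas censored under the drop policy")
  list(mean = mean(vals),
       sem = if (length(vals) > 1L) sd(vals) / sqrt(length(vals)) else 0,
       n = length(vals), n_censored = sum(censored))
}

#' Spearman rank correlation (average ranks for ties)
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  cor(x, y, method = "spearman")
}

#' Pearson correlation on raw values
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return r in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  cor(x, y, method = "pearson")
}

#' Least-squares regression of mean times on pk_off
#'
#' @param mean_times Per-system mean event times.
#' @param pk_off Per-system experimental pk_off.
#' @param ids Optional system ids (for outlier reporting).
#' @return Object of class `rt_regression`: slope, intercept, r_squared,
#'   residuals, fitted, ids, the pk_off range used, excluded ids (empty
#'   here), and the underlying `lm` fit.
#' @export
fit_regression <- function(mean_times, pk_off, ids = NULL) {
  stopifnot(length(mean_times) == length(pk_off), length(mean_times) >= 3L)
  if (is.null(ids)) ids <- as.character(seq_along(mean_times))
  fit <- lm(mean_times ~ pk_off)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((mean_times - mean(mean_times))^2)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 residuals = unname(residuals(fit)),
                 fitted = unname(fitted(fit)),
                 ids = ids, pk_off = pk_off, mean_times = mean_times,
                 range = range(pk_off), excluded = character(), lm = fit),
            class = "rt_regression")
}

#' @export
print.rt_regression <- function(x, ...) {
  cat(sprintf("rt_regression: time = %.3g + %.3g * pk_off, R^2 = %.3f (n = %d%s)\n",
              x$intercept, x$slope, x$r_squared, length(x$residuals),
              if (length(x$excluded)) paste0(", excluded: ",
                                             paste(x$excluded, collapse = ", "))
              else ""))
  invisible(x)
}

#' Refit after discarding the m largest-residual systems
#'
#' @param regression An `rt_regression`.
#' @param m Number of outliers to remove (default 2; `m = 0` returns the
#'   fit unchanged; error when fewer than 3 points would remain).
#' @return An `rt_regression` on the retained points, with `excluded`
#'   naming the removed systems.
#' @export
drop_outliers <- function(regression, m = 2L) {
  stopifnot(inherits(regression, "rt_regression"))
  n <- length(regression$residuals)
  if (m == 0L) return(regression)
  if (m >= n - 2L) stop("cannot drop that many points: fit degenerate")
  drop <- order(abs(regression$residuals), decreasing = TRUE)[seq_len(m)]
  keep <- setdiff(seq_len(n), drop)
  out <- fit_regression(regression$mean_times[keep], regression$pk_off[keep],
                        ids = regression$ids[keep])
  out$excluded <- regression$ids[drop]
  out
}

#' Predict a mean time from the regression
#'
#' @param regression An `rt_regression`.
#' @param pk_off pk_off value(s) to predict at.
#' @return data.frame (pk_off, predicted, extrapolated) where
#'   `extrapolated` flags values outside the training pk_off range.
#' @export
predict_time <- function(regression, pk_off) {
  data.frame(pk_off = pk_off,
             predicted = regression$intercept + regression$slope * pk_off,
             extrapolated = pk_off < regression$range[1L] |
               pk_off > regression$range[2L])
}

#' Median-threshold slow/fast classification
#'
#' Systems with pk_off above `pkoff_threshold` are the slow class;
#' predicted slow means a mean time above `time_threshold` (the median of
#' the mean times by default).
#'
#' @param mean_times,pk_off Per-system values.
#' @param pkoff_threshold Experimental class boundary (default 1.5).
#' @param time_threshold Predicted class boundary (default: median of
#'   `mean_times`).
#' @return List (accuracy, mcc, confusion, time_threshold). MCC is 0 when a
#'   confusion-margin product is zero (degenerate denominator).
#' @export
classify_by_threshold <- function(mean_times, pk_off, pkoff_threshold = 1.5,
                                  time_threshold = NULL) {
  stopifnot(length(mean_times) == length(pk_off))
  if (is.null(time_threshold)) time_threshold <- median(mean_times)
  truth <- pk_off > pkoff_threshold
  pred <- mean_times > time_threshold
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(accuracy = (tp + tn) / length(truth), mcc = mcc,
       confusion = matrix(c(tp, fn, fp, tn), 2L, 2L,
                          dimnames = list(pred = c("slow", "fast"),
                                          truth = c("slow", "fast"))),
       time_threshold = time_threshold)
}

#' Bootstrap stability of the rank correlation vs replica sample size
#'
#' For each sample size s: B resamples drawing s replica times with
#' replacement per system, computing per-system means and their Spearman
#' correlation with pk_off; reports mean and sd of rho over the B
#' resamples. Deterministic given `seed`. When a resample produces
#' constant means across systems, its rho is recorded as NA (tie-
#' degenerate, with a warning) and ignored in the summary.
#'
#' @param replica_times Named list: per system, a numeric vector of
#'   replica times.
#' @param pk_off Per-system pk_off, aligned with `names(replica_times)`.
#' @param sizes Sample sizes to probe (default `c(5, 10, 15, 20)`).
#' @param B Resamples per size (default 200).
#' @param seed Integer seed.
#' @return data.frame (size, mean_rho, sd_rho, n_degenerate).
#' @export
bootstrap_rank_stability <- function(replica_times, pk_off,
                                     sizes = c(5, 10, 15, 20), B = 200L,
                                     seed = 1L) {
  stopifnot(length(replica_times) == length(pk_off))
  set.seed(seed)
  out <- lapply(sizes, function(s) {
    rho <- vapply(seq_len(B), function(b) {
      means <- vapply(replica_times, function(tt) {
        mean(sample(tt, size = s, replace = TRUE))
      }, numeric(1))
      if (sd(means) == 0 || sd(pk_off) == 0) return(NA_real_)
      spearman(means, pk_off)
    }, numeric(1))
    ndeg <- sum(is.na(rho))
    if (ndeg > 0) warning("tie-degenerate resamples: rho undefined for ",
                          ndeg, " resample(s)")
    data.frame(size = s, mean_rho = mean(rho, na.rm = TRUE),
               sd_rho = sd(rho, na.rm = TRUE), n_degenerate = ndeg)
  })
  do.call(rbind, out)
}

#' Full ranking report from replica times and experimental kinetics
#'
#' @param replica_df data.frame (system, replica, time, censored).
#' @param kinetics_df data.frame (system, and `pk_off` or `k_off` in
#'   1/min).
#' @param censor_policy Passed to [summarize_replicas()].
#' @param outliers Number of highest-residual systems to drop in the
#'   secondary regression (default 0 = none).
#' @param pkoff_threshold Classification boundary (default 1.5).
#' @return Object of class `ranking_report`: per-system summary table,
#'   spearman, pearson, regression (and `regression_trimmed` when
#'   `outliers > 0`), classification, and the inputs.
#' @export
ranking_report <- function(replica_df, kinetics_df,
                           censor_policy = "cap", outliers = 0L,
                           pkoff_threshold = 1.5) {
  if (is.null(kinetics_df$pk_off)) {
    kinetics_df$pk_off <- pkoff_from_koff(kinetics_df$k_off)
  }
  systems <- unique(replica_df$system)
  summ <- do.call(rbind, lapply(systems, function(s) {
    sub <- replica_df[replica_df$system == s, ]
    st <- summarize_replicas(sub$time, sub$censored, policy = censor_policy)
    data.frame(system = s, mean_time = st$mean, sem = st$sem, n = st$n,
               n_censored = st$n_censored)
  }))
  summ$pk_off <- kinetics_df$pk_off[match(summ$system, kinetics_df$system)]
  if (anyNA(summ$pk_off)) stop("missing experimental kinetics for: ",
                               paste(summ$system[is.na(summ$pk_off)],
                                     collapse = ", "))
  reg <- fit_regression(summ$mean_time, summ$pk_off, ids = as.character(summ$system))
  out <- list(summary = summ,
              spearman = spearman(summ$mean_time, summ$pk_off),
              pearson = pearson(summ$mean_time, summ$pk_off),
              regression = reg,
              classification = classify_by_threshold(summ$mean_time, summ$pk_off,
                                                     pkoff_threshold),
              censor_policy = censor_policy)
  if (outliers > 0L) out$regression_trimmed <- drop_outliers(reg, outliers)
  class(out) <- "ranking_report"
  out
}

#' @export
print.ranking_report <- function(x, ...) {
  cat("ranking_report\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("Spearman rho = %.3f, Pearson r = %.3f\n", x$spearman, x$pearson))
  cat(sprintf("classification: accuracy %.3f, MCC %.3f (time threshold %.3g)\n",
              x$classification$accuracy, x$classification$mcc,
              x$classification$time_threshold))
  invisible(x)
}
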