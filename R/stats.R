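# Evaluation suite: regression metrics, residual diagnostics, bootstrap
# percentile prediction intervals and the paired-t comparison.

#' Regression metrics for predicted vs actual firmness
#'
#' `R^2 = 1 - SS_res / SS_tot` with residuals `actual - predicted`;
#' `RMSE = sqrt(mean(residual^2))`; slope and intercept from the ordinary
#' least-squares regression of predicted on actual (set
#' `reverse = TRUE` for the regression of actual on predicted); bias is the
#' mean residual.
#'
#' @param actual,predicted Equal-length numeric vectors (MPa).
#' @param reverse Regress actual on predicted instead (default `FALSE`).
#' @return List with `r_squared`, `rmse`, `slope`, `intercept`, `bias`, `n`.
#' @export
regression_metrics <- function(actual, predicted, reverse = FALSE) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  if (sd(actual) == 0) stop("constant actual values: R^2 and slope undefined")
  res <- actual - predicted
  ss_res <- sum(res^2)
  ss_tot <- sum((actual - mean(actual))^2)
  fit <- if (reverse) lm(actual ~ predicted) else lm(predicted ~ actual)
  list(r_squared = 1 - ss_res / ss_tot,
       rmse = sqrt(mean(res^2)),
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       bias = mean(res),
       n = length(actual))
}

#' Residual diagnostics
#'
#' Sample skewness of the residuals (type 2, the definition SPSS and SAS
#' report), the Shapiro-Wilk normality p-value, and the slope (with
#' p-value) of the OLS fit of `|residual|` on the predictions, a simple
#' heteroscedasticity measure.
#'
#' @param actual,predicted Equal-length numeric vectors, `n >= 3`.
#' @return List with `skewness`, `shapiro_p`, `hetero_slope`, `hetero_p`,
#'   and `degenerate` (`TRUE` when the residuals have zero variance, in
#'   which case the other entries are `NA`).
#' @export
residual_diagnostics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 3)
  res <- actual - predicted
  if (sd(res) == 0) {
    return(list(skewness = NA_real_, shapiro_p = NA_real_,
                hetero_slope = NA_real_, hetero_p = NA_real_,
                degenerate = TRUE))
  }
  sw <- shapiro.test(res)
  if (sd(predicted) == 0) {
    hs <- NA_real_; hp <- NA_real_   # flat predictions: no spread trend
  } else {
    fit <- summary(lm(abs(res) ~ predicted))
    hs <- unname(fit$coefficients[2, "Estimate"])
    hp <- unname(fit$coefficients[2, "Pr(>|t|)"])
  }
  list(skewness = e1071::skewness(res, type = 2),
       shapiro_p = sw$p.value,
       hetero_slope = hs,
       hetero_p = hp,
       degenerate = FALSE)
}

#' Bootstrap percentile prediction intervals
#'
#' Case-resamples the training rows `B` times, refits the model with
#' `fit_fun` on each resample, predicts every evaluation row with each
#' refitted model, and takes the per-row 2.5th/97.5th percentiles (for
#' `level = 0.95`) across the `B` predictions. These are percentile
#' confidence intervals for the model prediction; `coverage` is the
#' fraction of `reference` values (when supplied) falling inside their
#' interval.
#'
#' @param x_train,y_train Training inputs and targets.
#' @param x_eval Rows at which intervals are computed.
#' @param fit_fun `function(x, y, seed)` returning a fitted model.
#' @param predict_fun `function(model, x)` returning predictions
#'   (default [predict()]).
#' @param B Number of bootstrap refits (default 1000).
#' @param level Nominal level (default 0.95).
#' @param seed Integer base seed; replicate `b` uses `seed + b`.
#' @param reference Optional vector of values (observations or known true
#'   means) against which coverage is computed.
#' @return An object of class `ci_band`: list with `lower`, `upper`,
#'   `predicted` (point predictions from a fit on the full training data),
#'   `nominal_level`, `n_bootstrap`, `mean_width`, `coverage` (`NA` without
#'   a reference) and `n_redrawn` (degenerate resamples redrawn).
#' @export
bootstrap_intervals <- function(x_train, y_train, x_eval, fit_fun,
                                predict_fun = function(m, x) predict(m, x),
                                B = 1000, level = 0.95, seed = 1,
                                reference = NULL) {
  x_train <- as.matrix(x_train); x_eval <- as.matrix(x_eval)
  n <- nrow(x_train)
  stopifnot(B >= 2, n >= 2, level > 0, level < 1)
  preds <- matrix(NA_real_, B, nrow(x_eval))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    idx <- withr::with_seed(seed + b, {
      i <- sample.int(n, replace = TRUE)
      tries <- 0L
      while (length(unique(i)) == 1L && tries < 100L) {
        i <- sample.int(n, replace = TRUE)
        tries <- tries + 1L
      }
      attr(i, "tries") <- tries
      i
    })
    n_redrawn <- n_redrawn + attr(idx, "tries")
    fit <- fit_fun(x_train[idx, , drop = FALSE], y_train[idx], seed + b)
    preds[b, ] <- predict_fun(fit, x_eval)
  }
  alpha <- (1 - level) / 2
  # type 6 matches the usual (B + 1) * alpha order-statistic convention
  lower <- apply(preds, 2, quantile, probs = alpha, type = 6)
  upper <- apply(preds, 2, quantile, probs = 1 - alpha, type = 6)
  full <- fit_fun(x_train, y_train, seed)
  point <- predict_fun(full, x_eval)
  coverage <- if (is.null(reference)) NA_real_ else {
    mean(reference >= lower & reference <= upper)
  }
  structure(list(lower = lower, upper = upper, predicted = point,
                 nominal_level = level, n_bootstrap = B,
                 mean_width = mean(upper - lower), coverage = coverage,
                 n_redrawn = n_redrawn),
            class = "ci_band")
}

#' Paired t-test of actual vs predicted values
#'
#' Standard paired-t quantities on the differences `actual - predicted`
#' with `n - 1` degrees of freedom.
#'
#' @param actual,predicted Equal-length numeric vectors, `n >= 2`.
#' @return List with `mean_diff`, `sd_diff`, `se`, `df`, `t`, `p` and
#'   `zero_variance` (`TRUE` when all differences are identical; with a
#'   non-zero mean difference `p` is reported as 0).
#' @export
paired_t <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2)
  d <- actual - predicted
  n <- length(d)
  if (sd(d) == 0) {
    md <- mean(d)
    return(list(mean_diff = md, sd_diff = 0, se = 0, df = n - 1,
                t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                zero_variance = TRUE))
  }
  tt <- t.test(actual, predicted, paired = TRUE)
  list(mean_diff = mean(d), sd_diff = sd(d), se = sd(d) / sqrt(n),
       df = unname(tt$parameter), t = unname(tt$statistic),
       p = tt$p.value, zero_variance = FALSE)
}

#' Full evaluation report
#'
#' Convenience wrapper combining [regression_metrics()],
#' [residual_diagnostics()] and [paired_t()].
#'
#' @param actual,predicted Equal-length numeric vectors (MPa).
#' @return A list of class `eval_report` with all component fields.
#' @export
evaluation_report <- function(actual, predicted) {
  m <- regression_metrics(actual, predicted)
  d <- residual_diagnostics(actual, predicted)
  t <- paired_t(actual, predicted)
  structure(c(m, d, list(paired_t = t)), class = "eval_report")
}
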