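## Calibration of NRF2 target-gene induction against graded KEAP1 dosage.
##
## The graded-dosage series (relative KEAP1 protein at 100/40/19/5% of wild
## type) shows an inverse relationship between KEAP1 level and target mRNA
## fold-induction. We model it as a power law -- linear in log-log space --
## which is the minimal two-parameter monotone form consistent with the
## printed anchor behaviour, and analytically invertible: an observed
## fold-change maps back to a unique residual KEAP1 activity.

#' Fit a KEAP1 dosage / target-mRNA calibration curve
#'
#' Least-squares fit of `log(mrna_rel)` on `log(keap1_level_pct / 100)`.
#' The intercept is the log fold-change at the 100% (wild-type) anchor and
#' the slope must be negative: the model presumes repression of the target
#' by KEAP1.
#'
#' @param data a data frame of calibration measurements with columns
#'   `keap1_level_pct` (relative KEAP1 protein, percent of wild type, > 0)
#'   and `mrna_rel` (target mRNA fold-change vs wild type, > 0). A column
#'   named `keap1_level` is accepted as an alias. Additional columns
#'   (`gene`, `genotype_label`, `replicate_id`) are carried along.
#' @param gene optional gene label; defaults to the unique value of a
#'   `gene` column when present.
#' @return an object of class `keap1_calibration` with components
#'   `coefficients` (named `intercept`, `slope`), `residual_sd` (log-scale),
#'   `n_points`, `levels`, `gene`, `data` and the underlying `lm` fit.
#' @examples
#' calib <- data.frame(keap1_level_pct = c(100, 40, 19, 5),
#'                     mrna_rel = (100 / c(100, 40, 19, 5))^1)
#' fit_calibration(calib)
#' @export
fit_calibration <- function(data, gene = NULL) {
  data <- as.data.frame(data)
  if (!"keap1_level_pct" %in% names(data) && "keap1_level" %in% names(data)) {
    data$keap1_level_pct <- data$keap1_level
  }
  if (!all(c("keap1_level_pct", "mrna_rel") %in% names(data))) {
    stop("calibration data needs columns `keap1_level_pct` and `mrna_rel`",
         call. = FALSE)
  }
  lev <- data$keap1_level_pct
  mr <- data$mrna_rel
  if (any(!is.finite(lev)) || any(lev <= 0) ||
      any(!is.finite(mr)) || any(mr <= 0)) {
    stop("KEAP1 levels and mRNA fold-changes must be finite and positive",
         call. = FALSE)
  }
  if (length(unique(lev)) < 2L) {
    stop("insufficient data: at least 2 distinct KEAP1 levels are required ",
         "to identify the power law", call. = FALSE)
  }
  if (is.null(gene) && "gene" %in% names(data) &&
      length(unique(data$gene)) == 1L) {
    gene <- as.character(data$gene[[1L]])
  }
  x <- log(lev / 100)
  y <- log(mr)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  slope <- unname(cf[[2L]])
  intercept <- unname(cf[[1L]])
  if (!is.finite(slope) || slope >= 0) {
    stop("fitted slope is non-negative: the data do not show the inverse ",
         "KEAP1-level / mRNA relationship this model presumes", call. = FALSE)
  }
  rsd <- stats::sigma(fit)
  if (!is.finite(rsd)) rsd <- 0  # saturated fit (no residual df)
  structure(
    list(
      coefficients = c(intercept = intercept, slope = slope),
      residual_sd = rsd,
      n_points = length(y),
      levels = sort(unique(lev), decreasing = TRUE),
      gene = gene,
      data = data,
      fit = fit
    ),
    class = "keap1_calibration"
  )
}

#' @export
print.keap1_calibration <- function(x, digits = 4, ...) {
  cat("KEAP1 dosage calibration curve",
      if (!is.null(x$gene)) sprintf(" (%s)", x$gene), "\n", sep = "")
  cat(sprintf("  log(mRNA fold) = %s %+s * log(level / 100%%)\n",
              format(x$coefficients[["intercept"]], digits = digits),
              format(x$coefficients[["slope"]], digits = digits)))
  cat(sprintf("  residual sd (log scale): %s;  %d points over %d levels\n",
              format(x$residual_sd, digits = digits), x$n_points,
              length(x$levels)))
  invisible(x)
}

#' @export
coef.keap1_calibration <- function(object, ...) object$coefficients

#' @export
residuals.keap1_calibration <- function(object, ...) stats::residuals(object$fit)

#' @export
summary.keap1_calibration <- function(object, ...) {
  s <- summary(object$fit)
  out <- list(curve = object, lm_summary = s)
  class(out) <- "summary.keap1_calibration"
  out
}

#' @export
print.summary.keap1_calibration <- function(x, ...) {
  print(x$curve)
  cat("\nUnderlying log-log regression:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' Predicted mRNA fold-change at a given KEAP1 level
#'
#' Forward evaluation of the fitted power law.
#'
#' @param object a `keap1_calibration` fit.
#' @param newdata numeric vector of KEAP1 levels (percent of wild type), or
#'   a data frame with a `keap1_level_pct` column. Defaults to the fitted
#'   levels.
#' @param ... unused.
#' @return numeric vector of predicted fold-changes.
#' @export
predict.keap1_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    lev <- object$data$keap1_level_pct
  } else if (is.data.frame(newdata)) {
    lev <- newdata$keap1_level_pct %||% newdata$keap1_level
    if (is.null(lev)) {
      stop("`newdata` needs a keap1_level_pct column", call. = FALSE)
    }
  } else {
    lev <- newdata
  }
  if (any(!is.finite(lev)) || any(lev <= 0)) {
    stop("KEAP1 levels must be finite and positive", call. = FALSE)
  }
  cf <- object$coefficients
  exp(cf[["intercept"]] + cf[["slope"]] * log(lev / 100))
}

#' @rdname predict.keap1_calibration
#' @param curve a `keap1_calibration` fit.
#' @param keap1_level numeric vector of KEAP1 levels (percent).
#' @export
predict_mrna <- function(curve, keap1_level) {
  predict(curve, newdata = keap1_level)
}

#' Invert the calibration curve to a residual KEAP1 activity
#'
#' Solves the fitted power law for the KEAP1 level producing an observed
#' mRNA fold-change. Solutions above 100% (observations below the baseline
#' fold-change) are clipped to 100% with a warning, since residual activity
#' is reported as a fraction of the wild-type pool.
#'
#' @param curve a `keap1_calibration` fit.
#' @param mrna_observed positive fold-change(s) vs wild type.
#' @return KEAP1 activity level(s) in percent, in (0, 100].
#' @examples
#' calib <- data.frame(keap1_level_pct = c(100, 40, 19, 5),
#'                     mrna_rel = 100 / c(100, 40, 19, 5))
#' invert_activity(fit_calibration(calib), 4.0)  # 25
#' @export
invert_activity <- function(curve, mrna_observed) {
  stopifnot(inherits(curve, "keap1_calibration"))
  if (any(!is.finite(mrna_observed)) || any(mrna_observed <= 0)) {
    stop("observed mRNA fold-changes must be finite and positive",
         call. = FALSE)
  }
  cf <- curve$coefficients
  level <- 100 * exp((log(mrna_observed) - cf[["intercept"]]) / cf[["slope"]])
  if (any(level > 100)) {
    warning("inverted activity above 100% clipped to 100% ",
            "(observation below the baseline fold-change)", call. = FALSE)
    level <- pmin(level, 100)
  }
  level
}

#' @export
plot.keap1_calibration <- function(x, n_grid = 200, ...) {
  d <- x$data
  grid <- exp(seq(log(min(d$keap1_level_pct)), log(max(d$keap1_level_pct)),
                  length.out = n_grid))
  graphics::plot(d$keap1_level_pct, d$mrna_rel, log = "xy",
                 xlab = "KEAP1 level (% of wild type)",
                 ylab = "target mRNA (fold vs wild type)",
                 main = paste0("KEAP1 dosage calibration",
                               if (!is.null(x$gene)) paste0(" (", x$gene, ")")),
                 ...)
  graphics::lines(grid, predict(x, grid), col = "red3", lwd = 2)
  invisible(x)
}

#' Simulate replicate calibration tables from a fitted curve
#'
#' Draws new `mrna_rel` values at the fitted design points from the fitted
#' power law with lognormal residual noise at the fitted `residual_sd`.
#'
#' @param object a `keap1_calibration` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed (the caller's RNG state is restored).
#' @param ... unused.
#' @return a data frame with `nsim` columns, one row per calibration point.
#' @export
simulate.keap1_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  lev <- object$data$keap1_level_pct
  mu <- log(predict(object, lev))
  draw <- function() exp(mu + stats::rnorm(length(mu), 0, object$residual_sd))
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  sims <- as.data.frame(matrix(sims, ncol = nsim))
  names(sims) <- paste0("sim_", seq_len(nsim))
  sims
}

## Closed-form OLS pieces reused by the vectorized bootstrap: with the
## levels fixed by stratified resampling only per-level response means move,
## so slope and intercept are linear in those means.
#' @noRd
calib_design <- function(levels_vec) {
  lv <- sort(unique(levels_vec), decreasing = TRUE)
  x <- log(lv / 100)
  n_l <- as.numeric(table(factor(levels_vec, levels = lv)))
  n <- sum(n_l)
  xbar <- sum(n_l * x) / n
  sxx <- sum(n_l * (x - xbar)^2)
  list(levels = lv, x = x, n_l = n_l, n = n, xbar = xbar, sxx = sxx)
}

#' Estimate residual KEAP1 activity with a bootstrap confidence interval
#'
#' Point estimate: fit the calibration curve, take the geometric mean of
#' the observed replicate fold-changes, and invert. Uncertainty: a
#' nonparametric bootstrap resampling both the calibration points
#' (stratified by dosage level, so every level keeps its replicate count)
#' and the observed replicates, refitting and re-inverting each resample.
#'
#' The interval is an expanded percentile interval: instead of the raw
#' 2.5/97.5% bootstrap quantiles it uses the quantiles at
#' `pnorm(-sqrt(m/(m-1)) * qt(0.975, m-1))` and its complement, where `m`
#' is the number of observed replicates. This corrects the two known
#' small-sample defects of the plain percentile interval (resampling
#' variance shrinkage by `(m-1)/m` and the missing t-correction), which
#' matter at the replicate counts typical of RT-qPCR group sizes.
#'
#' @param points calibration data frame (see [fit_calibration()]).
#' @param observed_replicates numeric vector (length >= 2) of observed mRNA
#'   fold-changes in the condition of interest.
#' @param n_boot number of bootstrap resamples (>= 100; default 2000).
#' @param seed RNG seed; results are reproducible for a fixed seed and the
#'   caller's RNG state is untouched.
#' @param gene,condition_label optional labels carried into the result.
#' @param conf nominal two-sided confidence level (default 0.95).
#' @return an object of class `activity_estimate` with `activity_point`,
#'   `ci_low`, `ci_high` (fractions in \[0, 1\]), `n_boot`, `seed`,
#'   `n_replicates`, `gene`, `condition_label`.
#' @export
estimate_activity_ci <- function(points, observed_replicates,
                                 n_boot = 2000, seed = 1,
                                 gene = NULL, condition_label = NULL,
                                 conf = 0.95) {
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  m <- length(observed_replicates)
  if (m < 2) stop("at least 2 observed replicates are required", call. = FALSE)
  if (any(!is.finite(observed_replicates)) || any(observed_replicates <= 0)) {
    stop("observed replicates must be finite positive fold-changes",
         call. = FALSE)
  }
  curve <- fit_calibration(points, gene = gene)
  obs_log <- log(observed_replicates)
  point_pct <- suppressWarnings(
    invert_activity(curve, exp(mean(obs_log))))

  d <- calib_design(curve$data$keap1_level_pct)
  y_groups <- split(log(curve$data$mrna_rel),
                    factor(curve$data$keap1_level_pct, levels = d$levels))

  boot_once <- function(nb) {
    ## per-level resampled means: nb x L matrix
    gm <- vapply(seq_along(y_groups), function(l) {
      yl <- y_groups[[l]]
      nl <- length(yl)
      rowMeans(matrix(sample(yl, nb * nl, replace = TRUE), nrow = nb))
    }, numeric(nb))
    gm <- matrix(gm, nrow = nb)
    ybar <- as.vector(gm %*% d$n_l) / d$n
    slope <- as.vector(gm %*% (d$n_l * (d$x - d$xbar))) / d$sxx
    intercept <- ybar - slope * d$xbar
    omean <- rowMeans(matrix(sample(obs_log, nb * m, replace = TRUE),
                             nrow = nb))
    act <- exp((omean - intercept) / slope)
    act[slope >= 0] <- NA_real_  # degenerate resample: no inverse relation
    act
  }

  acts <- with_seed(seed, {
    res <- boot_once(n_boot)
    tries <- 0L
    while (anyNA(res) && tries < 10L) {
      idx <- which(is.na(res))
      res[idx] <- boot_once(length(idx))
      tries <- tries + 1L
    }
    res
  })
  if (anyNA(acts)) {
    stop("bootstrap failed: too many degenerate resamples without an ",
         "inverse KEAP1-level/mRNA relationship", call. = FALSE)
  }
  acts <- pmin(acts, 1)  # activity is a fraction of the WT pool

  alpha <- 1 - conf
  z_exp <- sqrt(m / (m - 1)) * stats::qt(1 - alpha / 2, df = m - 1)
  p_lo <- stats::pnorm(-z_exp)
  ci <- unname(stats::quantile(acts, c(p_lo, 1 - p_lo), type = 7))
  point <- min(point_pct / 100, 1)
  structure(
    list(
      activity_point = point,
      ci_low = max(min(ci[1], point), 0),
      ci_high = min(max(ci[2], point), 1),
      n_boot = as.integer(n_boot),
      seed = as.integer(seed),
      n_replicates = m,
      conf = conf,
      gene = gene %||% curve$gene,
      condition_label = condition_label
    ),
    class = "activity_estimate"
  )
}

#' Construct an activity estimate directly
#'
#' For evaluating hypotheses against an externally reported estimate (for
#' instance a published point value with its confidence interval) without
#' re-running the bootstrap.
#'
#' @param activity_point,ci_low,ci_high fractions in \[0, 1\] with
#'   `ci_low <= activity_point <= ci_high`.
#' @param gene,condition_label optional labels.
#' @return an `activity_estimate`.
#' @examples
#' activity_estimate(0.62, 0.49, 0.75)
#' @export
activity_estimate <- function(activity_point, ci_low, ci_high,
                              gene = NULL, condition_label = NULL) {
  a <- check_fraction(activity_point, "activity_point")
  lo <- check_fraction(ci_low, "ci_low")
  hi <- check_fraction(ci_high, "ci_high")
  if (lo > a || a > hi) {
    stop("need ci_low <= activity_point <= ci_high", call. = FALSE)
  }
  structure(
    list(activity_point = a, ci_low = lo, ci_high = hi,
         n_boot = NA_integer_, seed = NA_integer_,
         n_replicates = NA_integer_, conf = 0.95,
         gene = gene, condition_label = condition_label),
    class = "activity_estimate"
  )
}

#' @export
print.activity_estimate <- function(x, ...) {
  lbl <- paste(c(x$gene, x$condition_label), collapse = ", ")
  cat(sprintf("Residual KEAP1 activity%s: %.1f%%  (95%% CI %.1f%% - %.1f%%)\n",
              if (nzchar(lbl)) paste0(" [", lbl, "]") else "",
              100 * x$activity_point, 100 * x$ci_low, 100 * x$ci_high))
  if (!is.na(x$n_boot)) {
    cat(sprintf("  expanded percentile bootstrap, %d resamples, %d replicates, seed %d\n",
                x$n_boot, x$n_replicates, x$seed))
  }
  invisible(x)
}
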