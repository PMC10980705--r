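# ThT plate processing: blank subtraction, sigmoidal T_half fitting,
# aggregation speed, and correlation of structural metrics with kinetics.

#' Construct a ThT fluorescence curve
#'
#' @param times time points in hours, strictly increasing.
#' @param signal numeric vector (one well) or matrix (time x replicate
#'   wells) of fluorescence values (a.u.).
#' @param blanks blank-well values: matrix/vector of the same time length,
#'   or a scalar; NULL when already subtracted.
#' @return object of class \code{"tht_curve"}.
#' @export
tht_curve <- function(times, signal, blanks = NULL) {
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing")
  signal <- as.matrix(signal)
  if (nrow(signal) != length(times))
    stop("signal rows must match time points")
  if (!is.null(blanks) && length(blanks) > 1) {
    blanks <- as.matrix(blanks)
    if (nrow(blanks) != length(times))
      stop("blank rows must match time points")
  }
  structure(list(times = times, signal = signal, blanks = blanks),
            class = "tht_curve")
}

#' Subtract blank wells from a ThT curve
#'
#' The per-timepoint mean of the blank wells (buffer + dye) is subtracted
#' from every replicate.
#'
#' @param curve a \code{\link{tht_curve}} with blanks present.
#' @return blank-subtracted \code{\link{tht_curve}} (blanks consumed).
#' @export
blank_subtract <- function(curve) {
  stopifnot(inherits(curve, "tht_curve"))
  if (is.null(curve$blanks)) stop("curve has no blanks to subtract")
  bl <- if (length(curve$blanks) == 1) {
    rep(as.numeric(curve$blanks), length(curve$times))
  } else {
    rowMeans(as.matrix(curve$blanks))
  }
  curve$signal <- curve$signal - bl
  curve$blanks <- NULL
  curve
}

# Fit one well: 4-parameter logistic with multistart Levenberg-Marquardt.
.fit_well <- function(t, y) {
  fail <- list(baseline = NA_real_, plateau = NA_real_, T_half = NA_real_,
               slope = NA_real_, rss = NA_real_, converged = FALSE)
  amp <- max(y) - min(y)
  if (amp == 0) return(fail)                        # perfectly flat
  noise <- stats::mad(diff(y)) / sqrt(2)
  # flat-curve call: compare the smoothed amplitude to the noise floor
  k <- min(5, length(y))
  ys <- stats::filter(y, rep(1 / k, k))
  amp_s <- diff(range(ys, na.rm = TRUE))
  if (amp_s < 5 * noise) return(fail)               # no aggregation
  half <- min(y) + amp / 2
  i_half <- which(y >= half)[1]
  t_half0 <- if (is.na(i_half)) stats::median(t) else t[i_half]
  span <- diff(range(t))
  starts <- expand.grid(T_half = unique(c(t_half0,
                                          stats::quantile(t, c(.25, .5, .75)))),
                        slope = c(0.5, 2, 8) * 4 / span)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ baseline + (plateau - baseline) / (1 + exp(-slope * (t - T_half))),
        start = list(baseline = min(y), plateau = max(y),
                     T_half = starts$T_half[s], slope = starts$slope[s]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(baseline = unname(cf["baseline"]),
                   plateau = unname(cf["plateau"]),
                   T_half = unname(cf["T_half"]),
                   slope = unname(cf["slope"]), rss = rss, converged = TRUE)
    }
  }
  if (is.null(best)) return(fail)
  # a fitted transition outside the observed window is not a real T_half
  if (best$T_half < min(t) || best$T_half > max(t)) best$in_range <- FALSE
  else best$in_range <- TRUE
  best
}

#' Fit a sigmoidal aggregation curve and extract T_half
#'
#' Least-squares fit of the 4-parameter logistic
#' \deqn{y(t) = baseline + (plateau - baseline) / (1 + e^{-slope (t - T_{1/2})})}
#' with multistart initialisation (Levenberg-Marquardt).  Replicate wells
#' are fitted independently and the reported \code{T_half} is the median
#' across converged wells (set \code{combine = "mean_curve"} to fit the
#' replicate-mean curve instead).  Flat curves -- amplitude below the noise
#' floor -- give \code{converged = FALSE} with undefined \code{T_half}
#' (the "no aggregation" call).
#'
#' @param curve a blank-subtracted \code{\link{tht_curve}} (at least 8 time
#'   points).
#' @param combine \code{"median_well"} (default) or \code{"mean_curve"}.
#' @return object of class \code{"sigmoid_fit"}: baseline, plateau, T_half
#'   (hours), slope (1/h), rss, converged, in_range, and the per-well table
#'   \code{wells}.
#' @export
fit_tht_sigmoid <- function(curve, combine = c("median_well", "mean_curve")) {
  stopifnot(inherits(curve, "tht_curve"))
  combine <- match.arg(combine)
  if (!is.null(curve$blanks))
    stop("subtract blanks before fitting (blank_subtract)")
  t <- curve$times
  if (length(t) < 8) stop("need at least 8 time points for fitting")
  sig <- as.matrix(curve$signal)
  if (combine == "mean_curve") sig <- matrix(rowMeans(sig), ncol = 1)
  wells <- lapply(seq_len(ncol(sig)), function(j) .fit_well(t, sig[, j]))
  wtab <- do.call(rbind, lapply(seq_along(wells), function(j) {
    wl <- wells[[j]]
    data.frame(well = j, baseline = wl$baseline, plateau = wl$plateau,
               T_half = wl$T_half, slope = wl$slope, rss = wl$rss,
               converged = wl$converged,
               in_range = if (is.null(wl$in_range)) NA else wl$in_range)
  }))
  conv <- wtab[wtab$converged, , drop = FALSE]
  if (nrow(conv) == 0) {
    out <- list(baseline = NA_real_, plateau = NA_real_, T_half = NA_real_,
                slope = NA_real_, rss = NA_real_, converged = FALSE,
                in_range = NA, wells = wtab)
  } else {
    out <- list(baseline = stats::median(conv$baseline),
                plateau = stats::median(conv$plateau),
                T_half = stats::median(conv$T_half),
                slope = stats::median(conv$slope),
                rss = sum(conv$rss), converged = TRUE,
                in_range = all(conv$in_range), wells = wtab)
  }
  class(out) <- "sigmoid_fit"
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<sigmoid_fit> no aggregation (flat within noise)\n")
  } else {
    cat(sprintf(
      "<sigmoid_fit> T_half = %.3g h, slope = %.3g /h, amplitude = %.3g (%d wells)\n",
      x$T_half, x$slope, x$plateau - x$baseline, nrow(x$wells)))
    if (!isTRUE(x$in_range))
      cat("  warning: fitted T_half outside observed time range\n")
  }
  invisible(x)
}

#' Aggregation speed from a sigmoid fit
#'
#' Speed is 1/T_half (1/hours); non-aggregating wells (no converged
#' transition) get speed 0 and tie for last place in rankings.
#'
#' @param fit a \code{\link{fit_tht_sigmoid}} result.
#' @return numeric speed in 1/hours.
#' @export
aggregation_speed <- function(fit) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged || is.na(fit$T_half)) return(0)
  1 / fit$T_half
}

#' Correlate a structural metric with aggregation kinetics
#'
#' Spearman (rank) or Pearson correlation across mutants, with average
#' ranks for ties.  \code{use_ranks = TRUE} with \code{method = "pearson"}
#' computes Pearson on ranks (identical to Spearman up to tie handling and
#' provided for the rank-then-correlate reading of the analysis).
#'
#' @param metric,kinetics numeric vectors, aligned by position or by names
#'   when both are named.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param use_ranks replace both inputs by their ranks first.
#' @return object of class \code{"correlation_result"}: method, r, n,
#'   use_ranks.
#' @export
correlate <- function(metric, kinetics, method = c("spearman", "pearson"),
                      use_ranks = FALSE) {
  method <- match.arg(method)
  if (!is.null(names(metric)) && !is.null(names(kinetics))) {
    if (!setequal(names(metric), names(kinetics)))
      stop("metric and kinetics names do not match")
    kinetics <- kinetics[names(metric)]
  }
  if (length(metric) != length(kinetics)) stop("input lengths differ")
  ok <- is.finite(metric) & is.finite(kinetics)
  metric <- metric[ok]; kinetics <- kinetics[ok]
  n <- length(metric)
  if (n < 3) stop("need at least 3 aligned observations")
  if (stats::sd(metric) == 0 || stats::sd(kinetics) == 0)
    stop("zero-variance input")
  if (use_ranks) {
    metric <- rank(metric, ties.method = "average")
    kinetics <- rank(kinetics, ties.method = "average")
  }
  r <- stats::cor(metric, kinetics, method = method)
  structure(list(method = method, r = r, n = n, use_ranks = use_ranks),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s%s r = %.3f (n = %d)\n", x$method,
              if (x$use_ranks) " on ranks" else "", x$r, x$n))
  invisible(x)
}
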