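#' Sort plots by invader dominance
#'
#' Orders the study's plots in non-increasing order of invader relative
#' abundance (summed target-invader cover over the plot's total cover),
#' breaking ties deterministically by transect id then plot id. This sorted
#' sequence is the backbone of the running-average threshold procedure.
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param invaders Invader taxa to cumulate (default: target invader set).
#' @return Data frame with columns \code{plot_id}, \code{transect_id},
#'   \code{group}, \code{invader_relabund} (percent) and
#'   \code{native_richness} (species count), one row per plot, sorted.
#' @export
sort_by_invader <- function(dataset, invaders = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  ra <- invader_abundance(dataset, invaders = invaders)
  nat <- intersect(colnames(dataset$cover), native_species_of(dataset))
  rich <- rowSums(dataset$cover[, nat, drop = FALSE] > 0)
  out <- data.frame(dataset$plots,
                    invader_relabund = ra[dataset$plots$plot_id],
                    native_richness = rich[dataset$plots$plot_id],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$invader_relabund, out$transect_id, out$plot_id), ]
  rownames(out) <- NULL
  out
}

#' Running-average curve over the sorted invasion gradient
#'
#' Slides a window of width \code{bin} over the dominance-sorted plot
#' sequence and records, for each window position, the window means of
#' invader relative abundance (x) and native species richness (y). The bin
#' width defaults to the number of transects in the dataset, mirroring the
#' original bin size of the study design; a non-overlapping block-average
#' variant is available for comparison.
#'
#' @param sorted_plots Data frame from \code{\link{sort_by_invader}} (or any
#'   frame with \code{invader_relabund} and \code{native_richness} columns
#'   already sorted by descending abundance).
#' @param bin Window width in plots (>= 1, <= number of plots).
#' @param window \code{"sliding"} (unit step, the default) or
#'   \code{"block"} (disjoint consecutive blocks).
#' @return Object of class \code{running_average_curve}: data frame with
#'   columns \code{x} (mean invader relative abundance, percent) and
#'   \code{y} (mean native richness), ordered by descending \code{x};
#'   attribute \code{bin} records the window width.
#' @export
running_average_curve <- function(sorted_plots, bin,
                                  window = c("sliding", "block")) {
  window <- match.arg(window)
  x <- sorted_plots$invader_relabund
  y <- sorted_plots$native_richness
  n <- length(x)
  bin <- as.integer(bin)
  if (bin < 1L) stop("'bin' must be at least 1")
  if (bin > n) stop("'bin' (", bin, ") exceeds the number of plots (", n, ")")
  if (window == "sliding") {
    k <- n - bin + 1L
    cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
    xs <- (cx[(bin + 1L):(n + 1L)] - cx[1:k]) / bin
    ys <- (cy[(bin + 1L):(n + 1L)] - cy[1:k]) / bin
  } else {
    starts <- seq(1L, n, by = bin)
    xs <- vapply(starts, function(s) mean(x[s:min(s + bin - 1L, n)]), 0)
    ys <- vapply(starts, function(s) mean(y[s:min(s + bin - 1L, n)]), 0)
  }
  structure(data.frame(x = xs, y = ys),
            bin = bin, window = window,
            class = c("running_average_curve", "data.frame"))
}

#' Fit a polynomial trend to a running-average curve
#'
#' Ordinary least-squares polynomial of windowed native richness on
#' windowed invader relative abundance.
#'
#' @param curve A \code{\link{running_average_curve}} (or data frame with
#'   \code{x}, \code{y}).
#' @param degree Polynomial degree (default 3).
#' @return List with \code{coefficients} (intercept first),
#'   \code{r_squared}, \code{degree} and the underlying \code{lm} fit.
#' @export
fit_polynomial_trend <- function(curve, degree = 3) {
  x <- curve$x; y <- curve$y
  if (length(unique(x)) <= degree)
    stop("need more distinct x values than the polynomial degree")
  fit <- stats::lm(y ~ poly(x, degree, raw = TRUE),
                   data = data.frame(x = x, y = y))
  coefs <- unname(stats::coef(fit))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(coefficients = coefs, r_squared = r2, degree = degree, lm = fit)
}

poly_eval <- function(coefs, x) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

poly_deriv <- function(coefs) {
  if (length(coefs) <= 1L) return(0)
  coefs[-1L] * seq_len(length(coefs) - 1L)
}

#' Locate the invasion threshold on a fitted richness trend
#'
#' Scans the fitted polynomial P over the observed range of windowed invader
#' abundance. In \code{"declining_limb"} mode (the default) the threshold is
#' the smallest abundance, scanning upward from the low-invasion end, at
#' which P' changes sign from non-negative to negative -- the onset of the
#' declining limb of the native-richness hump. In \code{"peak"} mode it is
#' the abundance maximising P. If the fit is monotone declining over the
#' whole range, the minimum observed abundance is returned with
#' \code{flagged = TRUE}.
#'
#' @param curve A \code{\link{running_average_curve}}.
#' @param fit Result of \code{\link{fit_polynomial_trend}} on that curve.
#' @param mode \code{"declining_limb"} or \code{"peak"}.
#' @return List with \code{threshold} (percent invader relative abundance),
#'   \code{mode}, \code{flagged}, and the fit's \code{coefficients},
#'   \code{degree} and \code{r_squared}.
#' @export
detect_threshold <- function(curve, fit, mode = c("declining_limb", "peak")) {
  mode <- match.arg(mode)
  lo <- min(curve$x); hi <- max(curve$x)
  coefs <- fit$coefficients
  dcoefs <- poly_deriv(coefs)
  grid <- seq(lo, hi, length.out = 2001L)
  dP <- poly_eval(dcoefs, grid)
  flagged <- FALSE
  if (mode == "declining_limb") {
    idx <- which(dP[-length(dP)] >= 0 & dP[-1L] < 0)
    if (length(idx)) {
      k <- idx[1L]
      thr <- if (dP[k] == 0) grid[k] else
        stats::uniroot(function(z) poly_eval(dcoefs, z),
                       c(grid[k], grid[k + 1L]))$root
    } else if (all(dP < 0)) {
      thr <- lo; flagged <- TRUE
    } else {
      # non-declining over the whole range: no limb to detect
      thr <- hi; flagged <- TRUE
    }
  } else {
    P <- poly_eval(coefs, grid)
    kmax <- which.max(P)
    if (kmax %in% c(1L, length(P))) {
      thr <- grid[kmax]
      # endpoint maximum without an interior stationary peak
      flagged <- !(kmax > 1L && kmax < length(P))
    } else {
      thr <- stats::optimize(function(z) poly_eval(coefs, z),
                             c(grid[kmax - 1L], grid[kmax + 1L]),
                             maximum = TRUE)$maximum
    }
  }
  if (flagged)
    warning("no interior richness ", if (mode == "peak") "peak" else
      "declining limb", " in the observed range; threshold set to the ",
      "range endpoint")
  list(threshold = thr, mode = mode, flagged = flagged,
       coefficients = coefs, degree = fit$degree, r_squared = fit$r_squared)
}

#' Estimate the invasion threshold of native richness decline
#'
#' The central estimator of the package: sorts plots by invader dominance,
#' forms the running-average (invader relative abundance, native richness)
#' curve with bin width equal to the number of transects, fits a polynomial
#' trend, and locates the invader abundance at which native richness peaks
#' or begins to decline. That abundance is the empirical basis for setting
#' an invasive-species performance standard.
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param invaders Invader taxa to cumulate (default: target invader set).
#' @param bin Window width; default (\code{NULL}) is the transect count.
#' @param degree Polynomial degree of the trend fit (default 3: captures an
#'   asymmetric hump with a declining limb).
#' @param mode Threshold definition: \code{"declining_limb"} (default) or
#'   \code{"peak"}; see \code{\link{detect_threshold}}.
#' @param window Running-average window type; see
#'   \code{\link{running_average_curve}}.
#' @return Object of class \code{invasion_threshold}: the detected
#'   \code{threshold} (percent invader relative abundance), the fitted
#'   polynomial (\code{coefficients}, \code{r_squared}, \code{degree}), the
#'   running-average \code{curve}, the \code{sorted} plot table, \code{bin},
#'   \code{mode} and \code{flagged}. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{plot}.
#' @examples
#' ds <- generate_study(generator_config(n_transects = 10, seed = 3))
#' fit <- invasion_threshold(ds)
#' fit$threshold
#' @export
invasion_threshold <- function(dataset, invaders = NULL, bin = NULL,
                               degree = 3, mode = c("declining_limb", "peak"),
                               window = c("sliding", "block")) {
  mode <- match.arg(mode)
  window <- match.arg(window)
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.null(bin)) bin <- length(unique(dataset$plots$transect_id))
  sorted <- sort_by_invader(dataset, invaders = invaders)
  curve <- running_average_curve(sorted, bin = bin, window = window)
  fit <- fit_polynomial_trend(curve, degree = degree)
  det <- detect_threshold(curve, fit, mode = mode)
  structure(
    list(threshold = det$threshold, mode = mode, flagged = det$flagged,
         coefficients = fit$coefficients, r_squared = fit$r_squared,
         degree = fit$degree, curve = curve, sorted = sorted, bin = bin,
         window = window, lm = fit$lm,
         call = match.call()),
    class = "invasion_threshold"
  )
}

#' @export
print.invasion_threshold <- function(x, ...) {
  cat("Invasion threshold estimate (running-average / polynomial trend)\n")
  cat(sprintf("  threshold: %.2f%% invader relative abundance (%s%s)\n",
              x$threshold, gsub("_", " ", x$mode),
              if (x$flagged) ", flagged: no interior optimum" else ""))
  cat(sprintf("  bin = %d plots, degree-%d fit, R^2 = %.3f, %d curve points\n",
              x$bin, x$degree, x$r_squared, nrow(x$curve)))
  invisible(x)
}

#' @export
summary.invasion_threshold <- function(object, ...) {
  out <- list(threshold = object$threshold, mode = object$mode,
              flagged = object$flagged, bin = object$bin,
              degree = object$degree, r_squared = object$r_squared,
              n_plots = nrow(object$sorted), n_points = nrow(object$curve),
              coefficients = object$coefficients,
              abundance_range = range(object$curve$x),
              richness_range = range(object$curve$y))
  class(out) <- "summary.invasion_threshold"
  out
}

#' @export
print.summary.invasion_threshold <- function(x, ...) {
  cat("Invasion threshold fit\n")
  cat(sprintf("  plots: %d; curve points: %d (bin %d)\n",
              x$n_plots, x$n_points, x$bin))
  cat(sprintf("  windowed invader abundance range: %.2f-%.2f%%\n",
              x$abundance_range[1], x$abundance_range[2]))
  cat(sprintf("  polynomial degree %d, R^2 = %.3f\n", x$degree, x$r_squared))
  cat("  coefficients (ascending powers): ",
      paste(signif(x$coefficients, 5), collapse = ", "), "\n", sep = "")
  cat(sprintf("  threshold (%s): %.2f%%%s\n", gsub("_", " ", x$mode),
              x$threshold, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @export
coef.invasion_threshold <- function(object, ...) {
  stats::setNames(object$coefficients,
                  paste0("x^", seq_along(object$coefficients) - 1L))
}

#' @export
predict.invasion_threshold <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$curve$x
  else if (is.data.frame(newdata)) newdata$x else newdata
  poly_eval(object$coefficients, x)
}

#' @export
fitted.invasion_threshold <- function(object, ...) {
  poly_eval(object$coefficients, object$curve$x)
}

#' @export
residuals.invasion_threshold <- function(object, ...) {
  object$curve$y - fitted(object)
}

#' @export
plot.invasion_threshold <- function(x, ...) {
  graphics::plot(x$curve$x, x$curve$y,
                 xlab = "running-average invader relative abundance (%)",
                 ylab = "running-average native richness (species/plot)",
                 ...)
  xs <- seq(min(x$curve$x), max(x$curve$x), length.out = 200)
  graphics::lines(xs, poly_eval(x$coefficients, xs), col = "forestgreen",
                  lwd = 2)
  graphics::abline(v = x$threshold, col = "red", lty = 2)
  invisible(x)
}

#' Evaluate an invasive-species performance standard
#'
#' Computes, per zone, the cumulative relative abundance of the listed
#' invaders (the sum of their relative abundances: summed invader cover over
#' the zone's total cover) and compares it with the standard. Compliance
#' means cumulative abundance no greater than the standard ("<=", so a zone
#' exactly at the standard passes).
#'
#' @param dataset A \code{\link{study_dataset}}.
#' @param invaders Invader taxa to cumulate (default: the dataset's target
#'   invader set); unknown names are an error.
#' @param standard Performance standard, percent (default 10).
#' @param zones Optional named assignment of plots to zones: either the name
#'   of a plot-metadata column (for example \code{"group"}) or a character
#'   vector of zone labels, one per plot. Default: the whole dataset as one
#'   zone.
#' @return Object of class \code{compliance_report}: data frame with one row
#'   per zone plus an overall row, columns \code{zone},
#'   \code{cumulative_relabund} (percent), \code{standard} and \code{pass}.
#' @examples
#' ds <- generate_study(generator_config(n_transects = 3, seed = 5))
#' evaluate_standard(ds, standard = 10, zones = "group")
#' @export
evaluate_standard <- function(dataset, invaders = NULL, standard = 10,
                              zones = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (is.null(invaders)) invaders <- dataset$target_invader
  if (length(invaders) == 0L) stop("invader set must be non-empty")
  bad <- setdiff(invaders, dataset$species$species)
  if (length(bad)) stop("unknown invader name(s): ", paste(bad, collapse = ", "))
  if (!(standard >= 0 && standard <= 100)) stop("'standard' must be in [0, 100]")
  cov <- dataset$cover
  zone_of <- if (is.null(zones)) rep("all", nrow(cov))
  else if (length(zones) == 1L && zones %in% names(dataset$plots))
    as.character(dataset$plots[[zones]])
  else if (length(zones) == nrow(cov)) as.character(zones)
  else stop("'zones' must name a plot-metadata column or give one label per plot")
  cum_of <- function(rows) {
    sub <- cov[rows, , drop = FALSE]
    tot <- sum(sub)
    if (tot <= 0) stop("zone has zero total cover")
    ti <- intersect(invaders, colnames(sub))
    100 * sum(sub[, ti, drop = FALSE]) / tot
  }
  zl <- sort(unique(zone_of))
  vals <- vapply(zl, function(z) cum_of(zone_of == z), numeric(1))
  out <- data.frame(zone = zl, cumulative_relabund = vals,
                    standard = standard, pass = vals <= standard + 1e-9,
                    stringsAsFactors = FALSE)
  if (length(zl) > 1L) {
    ov <- cum_of(rep(TRUE, nrow(cov)))
    out <- rbind(out, data.frame(zone = "overall", cumulative_relabund = ov,
                                 standard = standard,
                                 pass = ov <= standard + 1e-9))
  }
  rownames(out) <- NULL
  structure(out, class = c("compliance_report", "data.frame"))
}

#' @export
print.compliance_report <- function(x, ...) {
  cat("Invasive-species performance-standard compliance\n")
  y <- as.data.frame(x)
  y$cumulative_relabund <- round(y$cumulative_relabund, 2)
  y$pass <- ifelse(y$pass, "pass", "FAIL")
  print(y, row.names = FALSE)
  invisible(x)
}
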