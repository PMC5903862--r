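# Division kinetics: division-wave histograms and kernel-smoothed
# densities, generation-resolved cell-cycle lengths, and the two-segment
# (broken-stick) change-point regression of cycle length against
# regeneration time or organ size.

#' Histogram and smoothed density of division times
#'
#' @param times Division times in hpi.
#' @param bin_width Histogram bin width in hours.
#' @param bandwidth Gaussian kernel bandwidth in hours for the smoothed
#'   density.
#' @return A list of class `nm_division_histogram`: `breaks`, `counts`,
#'   `density` (grid `x`, values `y`), `n`.
#' @export
division_histogram <- function(times, bin_width = 1, bandwidth = 1) {
  stopifnot(bin_width > 0, bandwidth > 0)
  times <- times[is.finite(times)]
  if (!length(times)) {
    return(structure(list(breaks = numeric(), counts = integer(),
                          density = list(x = numeric(), y = numeric()),
                          n = 0L, bin_width = bin_width),
                     class = "nm_division_histogram"))
  }
  lo <- floor(min(times) / bin_width) * bin_width
  hi <- ceiling(max(times) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.integer(table(cut(times, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  den <- stats::density(times, bw = bandwidth, kernel = "gaussian",
                        from = lo, to = hi, n = 512)
  structure(list(breaks = breaks, counts = counts,
                 density = list(x = den$x, y = den$y),
                 n = length(times), bin_width = bin_width),
            class = "nm_division_histogram")
}

#' Detect division-wave peaks in a smoothed density
#'
#' Local maxima of the kernel-smoothed division density whose prominence
#' (height above the highest saddle separating them from higher ground)
#' is at least `min_prominence` times the global maximum.
#'
#' @param hist An `nm_division_histogram`, or a list with `x` and `y`.
#' @param min_prominence Fraction of the global maximum (default 0.1).
#' @return Numeric vector of peak times (hpi), sorted; empty for flat
#'   densities.
#' @export
detect_wave_peaks <- function(hist, min_prominence = 0.1) {
  den <- if (inherits(hist, "nm_division_histogram")) hist$density else hist
  x <- den$x; y <- den$y
  n <- length(y)
  if (n < 3L || max(y) <= 0 || diff(range(y)) == 0) return(numeric())
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_max)) return(numeric())
  prominence <- vapply(is_max, function(i) {
    h <- y[i]
    # walk outwards until higher ground (or the boundary); the key saddle
    # on each side is the minimum along that walk
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > h)
    sad_l <- if (length(higher_l)) min(left[(max(higher_l)):(i - 1)])
             else min(c(left, h))
    right <- y[(i + 1):n]
    higher_r <- which(right > h)
    sad_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))])
             else min(c(right, h))
    h - max(sad_l, sad_r)
  }, numeric(1))
  keep <- prominence >= min_prominence * max(y)
  sort(x[is_max[keep]])
}

#' Cell-cycle lengths grouped by parent generation
#'
#' @param forests An `nm_forest` or list of them.
#' @param founder_class_filter Optional class filter on the lineage's
#'   founder (e.g. `"S"`).
#' @return A list: `lengths` (named list of per-generation cycle lengths)
#'   and `summary` (data.frame with n, mean, sd, median, iqr per
#'   generation).
#' @export
cycle_lengths_by_generation <- function(forests, founder_class_filter = NULL) {
  forests <- as_forest_list(forests)
  cyc <- do.call(rbind, lapply(forests, cycle_table))
  if (!is.null(founder_class_filter))
    cyc <- cyc[cyc$founder_class %in% founder_class_filter, , drop = FALSE]
  if (!nrow(cyc)) stop("no completed cell cycles", call. = FALSE)
  lengths <- split(cyc$cycle_h, cyc$generation)
  summary <- do.call(rbind, lapply(names(lengths), function(g) {
    v <- lengths[[g]]
    data.frame(generation = as.integer(g), n = length(v),
               mean = mean(v), sd = stats::sd(v),
               median = stats::median(v), iqr = stats::IQR(v))
  }))
  rownames(summary) <- NULL
  list(lengths = lengths, summary = summary)
}

#' Continuous two-segment (broken-stick) least-squares fit
#'
#' Fits `y = a + b1 x` for `x <= c` and `y = a + b1 c + b2 (x - c)` for
#' `x > c`, choosing the change point `c` by exhaustive search over the
#' sorted unique `x` values and the midpoints between them (candidates at
#' the observations themselves allow an exact break at a data point to be
#' recovered exactly), keeping candidates that leave at least `min_points`
#' observations in each segment. The model is
#' continuous at `c` and nests the single straight line (`b2 = b1`), so
#' its residual sum of squares never exceeds the single-line fit's.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_points Minimum observations per segment.
#' @return A list of class `nm_two_segment`: `change_point`, `intercept`,
#'   `slope1`, `slope2`, `sse`, `n1`, `n2`, the single-line comparison
#'   (`line_coef`, `line_sse`), and `degenerate` (TRUE when the broken
#'   stick does not improve on the line, i.e. the change point is
#'   unidentifiable).
#' @export
two_segment_fit <- function(x, y, min_points = 5) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2 * min_points)
    stop("need at least 2 * min_points = ", 2 * min_points,
         " observations, got ", n, call. = FALSE)
  ux <- sort(unique(x))
  if (length(ux) < 3L) stop("need at least 3 distinct x values", call. = FALSE)
  candidates <- sort(unique(c(ux, (ux[-1] + ux[-length(ux)]) / 2)))
  candidates <- candidates[vapply(candidates, function(c0) {
    sum(x <= c0) >= min_points && sum(x > c0) >= min_points
  }, logical(1))]
  if (!length(candidates))
    stop("no candidate change point leaves min_points on both sides",
         call. = FALSE)

  line <- stats::lm.fit(cbind(1, x), y)
  line_sse <- sum(line$residuals^2)

  best <- NULL
  for (c0 in candidates) {
    X <- cbind(1, x, pmax(x - c0, 0))
    fit <- stats::lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(c0 = c0, coef = fit$coefficients, sse = sse)
  }
  a <- unname(best$coef[1]); b1 <- unname(best$coef[2])
  b2 <- b1 + unname(ifelse(is.na(best$coef[3]), 0, best$coef[3]))
  degenerate <- (line_sse - best$sse) <= 1e-9 * max(line_sse, 1e-12)
  structure(list(change_point = best$c0, intercept = a,
                 slope1 = b1, slope2 = b2, sse = best$sse,
                 n1 = sum(x <= best$c0), n2 = sum(x > best$c0),
                 line_coef = unname(line$coefficients), line_sse = line_sse,
                 degenerate = degenerate, n = n),
            class = "nm_two_segment")
}

#' @export
print.nm_two_segment <- function(x, ...) {
  cat(sprintf(paste0("<nm_two_segment> change point %.3f, slopes %.3f -> ",
                     "%.3f, sse %.3f (line %.3f)%s\n"),
              x$change_point, x$slope1, x$slope2, x$sse, x$line_sse,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Predict from a two-segment fit
#'
#' @param object An `nm_two_segment` fit.
#' @param newdata Numeric vector of x values.
#' @param ... Unused.
#' @export
predict.nm_two_segment <- function(object, newdata, ...) {
  object$intercept + object$slope1 * pmin(newdata, object$change_point) +
    object$slope2 * pmax(newdata - object$change_point, 0)
}

#' Simulate from the continuous two-segment model
#'
#' Convenience generator for change-point recovery experiments: draws x
#' uniformly over `xlim` and y from the continuous broken-stick model plus
#' Gaussian noise. Uses the current RNG state.
#'
#' @param n Number of points.
#' @param change_point,intercept,slope1,slope2 Model parameters.
#' @param noise_sd Gaussian noise standard deviation.
#' @param xlim Range of x.
#' @param integer_x Round x to integers (for organ-size covariates).
#' @return A data.frame with columns `x`, `y`.
#' @export
simulate_two_segment <- function(n, change_point, intercept, slope1 = 0,
                                 slope2 = 1, noise_sd = 3,
                                 xlim = c(4, 90), integer_x = FALSE) {
  x <- stats::runif(n, xlim[1], xlim[2])
  if (integer_x) x <- round(x)
  mu <- intercept + slope1 * pmin(x, change_point) +
    slope2 * pmax(x - change_point, 0)
  data.frame(x = x, y = mu + stats::rnorm(n, 0, noise_sd))
}

#' Cycle length paired with regeneration time or organ size
#'
#' Pairs every completed cell cycle with either the cycle's division time
#' (hpi) or the total number of cells alive at the cycle's start, the two
#' covariates of the change-point analyses.
#'
#' @param forests An `nm_forest` or list of them.
#' @param against `"time"` (division time, hpi) or `"size"` (cell count at
#'   cycle start).
#' @param founder_class_filter Optional founder-class filter (e.g. `"S"`).
#' @return A data.frame with columns `x`, `y` (cycle length, h) plus
#'   bookkeeping columns.
#' @export
cycle_covariates <- function(forests, against = c("time", "size"),
                             founder_class_filter = NULL) {
  against <- match.arg(against)
  forests <- as_forest_list(forests)
  out <- do.call(rbind, lapply(forests, function(f) {
    cyc <- cycle_table(f)
    if (!is.null(founder_class_filter))
      cyc <- cyc[cyc$founder_class %in% founder_class_filter, , drop = FALSE]
    if (!nrow(cyc)) return(NULL)
    if (against == "time") {
      cyc$x <- cyc$time_hpi
    } else {
      tr <- as.data.frame(f$tracks)
      counts <- table(tr$time_hpi)
      times <- as.numeric(names(counts))
      cyc$x <- vapply(cyc$birth_time, function(b) {
        i <- which.min(abs(times - b))
        as.numeric(counts[i])
      }, numeric(1))
    }
    cyc$y <- cyc$cycle_h
    cyc
  }))
  if (is.null(out)) stop("no completed cell cycles", call. = FALSE)
  rownames(out) <- NULL
  out
}
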