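# Organ-centered coordinate frame and spatial statistics: quadrants,
# division anisotropy, clone laterality, and division-location summaries.
# Canonical frame: origin at the founder centroid of the first frame,
# +x = posterior, +y = dorsal.

#' Center a track table on the founder centroid
#'
#' Translates all coordinates so that the centroid of the cells present at
#' the first recorded frame is the origin, and flips axes as needed so that
#' +x points posterior and +y dorsal (per the manifest convention). The
#' origin is fixed for the whole recording. Re-centering a centered table
#' is the identity.
#'
#' @param tracks An `nm_tracks` table.
#' @return A centered `nm_tracks` table in the canonical frame.
#' @export
center_tracks <- function(tracks) {
  stopifnot(inherits(tracks, "nm_tracks"))
  manifest <- attr(tracks, "manifest")
  df <- as.data.frame(tracks)
  if (!nrow(df)) stop("cannot center an empty track table", call. = FALSE)
  t0 <- min(df$time_hpi)
  f0 <- df$time_hpi == t0
  if (!any(f0)) stop("first frame has no cells", call. = FALSE)
  df$x_um <- df$x_um - mean(df$x_um[f0])
  df$y_um <- df$y_um - mean(df$y_um[f0])
  if (manifest$axis_posterior == "-x") df$x_um <- -df$x_um
  if (manifest$axis_dorsal == "-y") df$y_um <- -df$y_um
  manifest$axis_posterior <- "+x"
  manifest$axis_dorsal <- "+y"
  track_table(df, manifest)
}

#' Counterclockwise polar angle from the +x axis
#'
#' @param x,y Coordinates relative to the organ center (vectorized).
#' @return Angle in degrees in `[0, 360)`. The origin has no angle and
#'   raises an error.
#' @export
polar_angle <- function(x, y) {
  if (any(x == 0 & y == 0))
    stop("polar angle undefined at the origin", call. = FALSE)
  (atan2(y, x) * 180 / pi) %% 360
}

#' Quadrant of a point in the organ frame
#'
#' The four quadrants are the 90-degree sectors whose bisectors are the
#' compass axes: dorsal is angles `[45, 135)`, anterior `[135, 225)`,
#' ventral `[225, 315)`, posterior the rest (half-open sectors, so a point
#' at exactly 45 degrees is dorsal).
#'
#' @inheritParams polar_angle
#' @return Character vector of quadrant labels.
#' @export
quadrant_of <- function(x, y) {
  a <- polar_angle(x, y)
  out <- rep("posterior", length(a))
  out[a >= 45 & a < 135] <- "dorsal"
  out[a >= 135 & a < 225] <- "anterior"
  out[a >= 225 & a < 315] <- "ventral"
  out
}

#' Quadrant distribution of divisions in a time window
#'
#' @param divisions A `division_table()` data.frame (columns `time_hpi`,
#'   `x_um`, `y_um`).
#' @param window Numeric `c(t0, t1)` in hpi; divisions with
#'   `t0 <= time < t1` are included.
#' @return A list: `n`, per-quadrant fractions, and `polar_fraction`
#'   (dorsal + ventral). Empty windows return `n = 0` with `NA` fractions
#'   and a flag.
#' @export
division_quadrant_distribution <- function(divisions,
                                           window = c(0, Inf)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  d <- divisions[divisions$time_hpi >= window[1] &
                 divisions$time_hpi < window[2], , drop = FALSE]
  quadrants <- c("anterior", "posterior", "dorsal", "ventral")
  if (!nrow(d)) {
    fr <- stats::setNames(rep(NA_real_, 4), quadrants)
    return(list(n = 0L, fractions = fr, polar_fraction = NA_real_,
                empty = TRUE))
  }
  q <- quadrant_of(d$x_um, d$y_um)
  fr <- as.numeric(table(factor(q, levels = quadrants))) / nrow(d)
  names(fr) <- quadrants
  list(n = nrow(d), fractions = fr,
       polar_fraction = unname(fr["dorsal"] + fr["ventral"]),
       empty = FALSE)
}

#' Ipsilateral fraction of founder progeny
#'
#' For each side of the chosen axis, the fraction of progeny alive at
#' `t_assess` whose coordinate sign matches their founder's sign at the
#' first frame. Cells exactly on the midline are excluded and counted.
#'
#' @param forest An `nm_forest` (tracks must be centered).
#' @param axis `"AP"` (x axis; negative = anterior) or `"DV"` (y axis;
#'   positive = dorsal).
#' @param t_assess Assessment time in hpi.
#' @return A data.frame with one row per side: founder count, progeny
#'   count, ipsilateral fraction, and midline exclusions.
#' @export
progeny_laterality <- function(forest, axis = c("AP", "DV"), t_assess = 60) {
  axis <- match.arg(axis)
  coord <- if (axis == "AP") "x_um" else "y_um"
  sides <- if (axis == "AP") c(`-1` = "anterior", `1` = "posterior")
           else c(`-1` = "ventral", `1` = "dorsal")
  tr <- as.data.frame(forest$tracks)
  t0 <- min(tr$time_hpi)
  f0 <- tr[tr$time_hpi == t0 & tr$node_index == 1L, , drop = FALSE]
  founder_side <- sign(f0[[coord]])
  names(founder_side) <- f0$lineage_id
  on_mid <- founder_side == 0
  if (any(on_mid)) {
    warning(sum(on_mid), " founder(s) exactly on the midline excluded",
            call. = FALSE)
    founder_side <- founder_side[!on_mid]
  }
  # frame nearest to t_assess on the grid, not beyond the recording
  times <- sort(unique(tr$time_hpi))
  t_use <- times[which.min(abs(times - min(t_assess, max(times))))]
  alive <- tr[tr$time_hpi == t_use, , drop = FALSE]
  out <- lapply(c(-1, 1), function(s) {
    lins <- as.integer(names(founder_side)[founder_side == s])
    prog <- alive[alive$lineage_id %in% lins, , drop = FALSE]
    mid <- sum(prog[[coord]] == 0)
    prog <- prog[prog[[coord]] != 0, , drop = FALSE]
    data.frame(axis = axis, side = unname(sides[as.character(s)]),
               n_founders = length(lins), n_progeny = nrow(prog),
               n_midline = mid,
               ipsilateral_fraction =
                 if (nrow(prog)) mean(sign(prog[[coord]]) == s) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Radial location of divisions by fate category
#'
#' @param divisions A categorized `division_table()` data.frame.
#' @return A data.frame with one row per category: n, median radial
#'   distance to the organ center, and quartiles.
#' @export
division_location_map <- function(divisions) {
  d <- divisions
  d$radius <- sqrt(d$x_um^2 + d$y_um^2)
  out <- do.call(rbind, lapply(split(d, d$category), function(g) {
    q <- stats::quantile(g$radius, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(category = g$category[1], n = nrow(g),
               q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
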