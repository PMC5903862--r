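# Agent-based simulator of neuromast regeneration. Emits track tables in
# the package dialect together with ground truth (true clone types and
# division categories), so every pipeline stage can be exercised and
# checked end-to-end without microscopy data.
#
# The generator emulates the study conditions: recordings start 4 hpi at a
# 15-min frame interval and last 65-100 h; each organ starts from 4-10
# founder cells (2-3 mantle, 2-7 sustentacular). Sustentacular founders
# divide around 19 +/- 6 h, mantle founders around 27 +/- 5 h with a 14/30
# chance of never dividing; later cycles draw from a ~11 +/- 3 h base
# distribution that lengthens after 47 hpi and beyond 24 cells. Division
# fates (SS/HH/MM/SM) follow base probabilities 0.78/0.16/0.03/0.03,
# spatially modulated: HH near the organ center (after hair-cell onset at
# 48 h, with a dorsoventral bias after 60 h), MM/SM at the periphery and
# away from existing mantle cells.

#' Simulator configuration
#'
#' All parameters of the synthetic regeneration generator. Defaults are
#' the study conditions described above; the spatial-modulation gains are
#' calibrated so that a default cohort's realized division-category
#' marginals match the base probabilities.
#'
#' @param n_experiments Experiments per cohort.
#' @param founders_m,founders_s Integer ranges (inclusive) for mantle and
#'   sustentacular founder counts, drawn uniformly.
#' @param start_hpi,frame_interval_h,duration_range Recording grid:
#'   start (hpi), frame interval (h), and the uniform range of recording
#'   durations (h).
#' @param s_first_division,m_first_division `c(mean, sd)` in hpi of founder
#'   first-division times (normal, truncated above `start_hpi` plus one
#'   frame).
#' @param s_core_fraction,s_core_mean,s_core_sd Sustentacular founder
#'   first divisions are a two-component mixture: a synchronized early
#'   "wave core" (fraction `s_core_fraction`, normal with mean
#'   `s_core_mean` and sd `s_core_sd`) plus late stragglers whose mean and
#'   sd are derived so that the mixture's marginal mean and sd equal
#'   `s_first_division`. The tight core is what makes the first division
#'   wave; a single normal with sd 6 has no discernible wave structure.
#' @param m_nondivision_prob Probability that a mantle founder never
#'   divides.
#' @param m_second_division_prob Probability that a mantle daughter divides
#'   once more (mantle lineages divide at most twice).
#' @param base_cycle `c(mean, sd)` in h of the base cell-cycle length
#'   (normal, truncated at `cycle_min`).
#' @param cycle_min Minimum cycle length (h).
#' @param changepoint_time,slope_time Cycle lengthening after this time
#'   (hpi) at this rate (h per h).
#' @param changepoint_size,slope_size Cycle lengthening beyond this organ
#'   size (cells) at this rate (h per cell).
#' @param lengthening_noise_frac Extra noise on the lengthening term
#'   (sd as a fraction of the term).
#' @param fate_probs Base category probabilities `c(SS, HH, MM, SM)` for
#'   sustentacular divisions.
#' @param hair_onset_hpi No HH divisions before this time.
#' @param dv_bias_start,dv_bias After `dv_bias_start` hpi the HH weight is
#'   redistributed toward the dorsal/ventral sectors at ratio
#'   `(1 + dv_bias) : 1` versus the anterior/posterior sectors (normalized
#'   so the sector-averaged weight, and hence the HH marginal, is
#'   unchanged).
#' @param hh_gain,hh_exponent,hh_r_max,periphery_gain,periphery_exponent,periphery_r_min,mantle_suppression
#'   Spatial fate territories. Hair-cell pairs arise only in the central
#'   disc (`r_norm <= hh_r_max`), with weight
#'   `hh_gain * (1 - r_norm)^hh_exponent`; mantle-producing divisions only
#'   at the outer perimeter (`r_norm >= periphery_r_min`), with weight
#'   `periphery_gain * r_norm^periphery_exponent / (1 + m20 /
#'   mantle_suppression)` where `m20` is the mantle-cell count within
#'   20 µm (mantle production is routed to perimeter sectors lacking
#'   mantle cells). Gains are calibrated so a default cohort's realized
#'   category marginals match `fate_probs`.
#' @param spatial_fates If `FALSE`, fates are drawn from `fate_probs`
#'   independent of position and time (the null model).
#' @param max_generation Hard cap on sustentacular generations.
#' @param daughter_displacement_sd Daughter placement noise per axis (µm).
#' @param walk_sd Per-frame random-walk sd per axis (µm).
#' @param radius_0 Organ radius at founder count `N0` (µm); the radius
#'   grows as `radius_0 * sqrt(N / N0)` to keep areal density constant.
#' @param mantle_rim_frac,mantle_rim_drift Mantle cells drift toward
#'   `mantle_rim_frac` of the organ radius at this per-frame rate.
#' @param hair_center_frac,hair_center_drift Same for hair cells toward
#'   the center.
#' @return A list of class `nm_sim_config`.
#' @export
simulation_config <- function(n_experiments = 15,
                              founders_m = c(2, 3),
                              founders_s = c(2, 7),
                              start_hpi = 4,
                              frame_interval_h = 0.25,
                              duration_range = c(65, 100),
                              s_first_division = c(19, 6),
                              s_core_fraction = 0.8,
                              s_core_mean = 18,
                              s_core_sd = 2.5,
                              m_first_division = c(27, 5),
                              m_nondivision_prob = 14 / 30,
                              m_second_division_prob = 0.07,
                              base_cycle = c(11, 3),
                              cycle_min = 4,
                              changepoint_time = 47,
                              slope_time = 1.0,
                              changepoint_size = 24,
                              slope_size = 1.5,
                              lengthening_noise_frac = 1 / 3,
                              fate_probs = c(SS = 0.78, HH = 0.16,
                                             MM = 0.03, SM = 0.03),
                              hair_onset_hpi = 48,
                              dv_bias_start = 60,
                              dv_bias = 4.0,
                              hh_gain = 4.6,
                              hh_exponent = 2,
                              hh_r_max = 0.55,
                              periphery_gain = 40,
                              periphery_exponent = 2,
                              periphery_r_min = 0.6,
                              mantle_suppression = 2,
                              spatial_fates = TRUE,
                              max_generation = 6,
                              daughter_displacement_sd = 3,
                              walk_sd = 0.4,
                              radius_0 = 20,
                              mantle_rim_frac = 0.85,
                              mantle_rim_drift = 0.05,
                              hair_center_frac = 0.35,
                              hair_center_drift = 0.05) {
  stopifnot(n_experiments >= 1,
            founders_m[1] >= 1, founders_m[2] >= founders_m[1],
            founders_s[1] >= 1, founders_s[2] >= founders_s[1],
            frame_interval_h > 0, all(duration_range > 0),
            cycle_min > 0, walk_sd >= 0, radius_0 > 0,
            s_core_fraction > 0, s_core_fraction < 1, s_core_sd > 0)
  # straggler moments matching the marginal first-division mean and sd
  pi_c <- s_core_fraction
  m2 <- (s_first_division[1] - pi_c * s_core_mean) / (1 - pi_c)
  v2 <- (s_first_division[2]^2 + s_first_division[1]^2 -
           pi_c * (s_core_sd^2 + s_core_mean^2) - (1 - pi_c) * m2^2) /
    (1 - pi_c)
  if (v2 <= 0)
    stop("core component incompatible with the marginal first-division sd",
         call. = FALSE)
  s_straggler_mean <- m2
  s_straggler_sd <- sqrt(v2)
  rm(pi_c, m2, v2)
  fate_probs <- fate_probs / sum(fate_probs)
  if (any(fate_probs < 0)) stop("fate probabilities must be non-negative",
                                call. = FALSE)
  structure(as.list(environment()), class = "nm_sim_config")
}

#' Null variant of a simulator configuration
#'
#' Toggles the spatial (and temporal) fate modulation: with modulation off,
#' division categories are drawn from the base probabilities independent of
#' position and time, preserving the marginal fate frequencies but removing
#' all structure a fate predictor could exploit. Applying the toggle twice
#' returns the original configuration.
#'
#' @param config An `nm_sim_config`.
#' @return The configuration with `spatial_fates` flipped.
#' @export
null_variant <- function(config) {
  stopifnot(inherits(config, "nm_sim_config"))
  config$spatial_fates <- !config$spatial_fates
  config
}

rtrunc_norm <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= lower))
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

# fate-category probabilities for one sustentacular division
division_fate_probs <- function(cfg, r_norm, t, in_dv, m20) {
  p <- cfg$fate_probs
  if (!cfg$spatial_fates) return(p)
  # after dv_bias_start the HH weight is redistributed between the polar
  # (dorsal/ventral) and the anterior/posterior sectors at ratio
  # (1 + dv_bias) : 1, normalized so the sector-averaged factor is 1
  dv_factor <- if (t > cfg$dv_bias_start) {
    2 * (1 + cfg$dv_bias * as.numeric(in_dv)) / (2 + cfg$dv_bias)
  } else 1
  w_hh <- p[["HH"]] * cfg$hh_gain * (1 - r_norm)^cfg$hh_exponent *
    as.numeric(t >= cfg$hair_onset_hpi && r_norm <= cfg$hh_r_max) *
    dv_factor
  per <- cfg$periphery_gain * r_norm^cfg$periphery_exponent *
    as.numeric(r_norm >= cfg$periphery_r_min) /
    (1 + m20 / cfg$mantle_suppression)
  w <- c(SS = p[["SS"]], HH = w_hh,
         MM = p[["MM"]] * per, SM = p[["SM"]] * per)
  w / sum(w)
}

#' Simulate one regeneration experiment
#'
#' Runs the agent-based model on the recording frame grid and returns the
#' emitted track table (which passes `track_table()` validation) together
#' with ground truth. Deterministic for a fixed `(config, seed)`.
#'
#' @param config An `nm_sim_config`.
#' @param seed Integer RNG seed.
#' @param experiment_id Label for the experiment.
#' @return A list of class `nm_sim_experiment`: `tracks` (an `nm_tracks`
#'   with manifest attached), `ground_truth` (list with `divisions`,
#'   `clones`, `founder_classes`, `seed`).
#' @export
generate_experiment <- function(config, seed, experiment_id = "sim01") {
  stopifnot(inherits(config, "nm_sim_config"))
  set.seed(seed)
  cfg <- config
  dt <- cfg$frame_interval_h
  duration <- stats::runif(1, cfg$duration_range[1], cfg$duration_range[2])
  K <- floor(duration / dt)
  times <- cfg$start_hpi + (0:K) * dt

  n_m <- sample(cfg$founders_m[1]:cfg$founders_m[2], 1)
  n_s <- sample(cfg$founders_s[1]:cfg$founders_s[2], 1)
  n_founders <- n_m + n_s
  N0 <- n_founders
  R0 <- cfg$radius_0

  cap <- 256L
  lineage <- integer(cap); node <- integer(cap); class <- character(cap)
  birth_k <- integer(cap); end_k <- integer(cap)
  div_time <- rep(NA_real_, cap); category <- rep(NA_character_, cap)
  X <- matrix(NA_real_, cap, K + 1); Y <- matrix(NA_real_, cap, K + 1)
  n_cells <- 0L

  grow <- function() {
    cap2 <- 2L * cap
    length(lineage) <<- cap2; length(node) <<- cap2
    length(class) <<- cap2; length(birth_k) <<- cap2; length(end_k) <<- cap2
    length(div_time) <<- cap2; length(category) <<- cap2
    X2 <- matrix(NA_real_, cap2, K + 1); X2[1:cap, ] <- X; X <<- X2
    Y2 <- matrix(NA_real_, cap2, K + 1); Y2[1:cap, ] <- Y; Y <<- Y2
    cap <<- cap2
  }
  add_cell <- function(lin, nd, cl, bk, x, y, tdiv, cat) {
    if (n_cells + 1L > cap) grow()
    n_cells <<- n_cells + 1L
    i <- n_cells
    lineage[i] <<- lin; node[i] <<- nd; class[i] <<- cl
    birth_k[i] <<- bk; end_k[i] <<- K
    X[i, bk + 1L] <<- x; Y[i, bk + 1L] <<- y
    div_time[i] <<- tdiv; category[i] <<- cat
    i
  }

  # founders: mantle near the rim, sustentacular within the inner disc
  t_min_div <- cfg$start_hpi + dt
  for (l in seq_len(n_founders)) {
    is_m <- l <= n_m
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- if (is_m) R0 * stats::runif(1, 0.75, 0.95)
           else 0.8 * R0 * sqrt(stats::runif(1))
    tdiv <- if (is_m) {
      if (stats::runif(1) < cfg$m_nondivision_prob) NA_real_
      else rtrunc_norm(1, cfg$m_first_division[1], cfg$m_first_division[2],
                       t_min_div)
    } else if (stats::runif(1) < cfg$s_core_fraction) {
      rtrunc_norm(1, cfg$s_core_mean, cfg$s_core_sd, t_min_div)
    } else {
      rtrunc_norm(1, cfg$s_straggler_mean, cfg$s_straggler_sd, t_min_div)
    }
    add_cell(l, 1L, if (is_m) "M" else "S", 0L,
             rad * cos(ang), rad * sin(ang), tdiv, NA_character_)
  }

  schedule_cycle <- function(t_birth, n_alive) {
    base <- rtrunc_norm(1, cfg$base_cycle[1], cfg$base_cycle[2],
                        cfg$cycle_min)
    lengthen <- cfg$slope_time * max(0, t_birth - cfg$changepoint_time) +
      cfg$slope_size * max(0, n_alive - cfg$changepoint_size)
    if (lengthen > 0)
      lengthen <- max(0, lengthen +
                        stats::rnorm(1, 0, lengthen *
                                          cfg$lengthening_noise_frac))
    t_birth + base + lengthen
  }

  for (k in seq_len(K)) {
    t_now <- times[k + 1L]
    alive <- which(birth_k < k & end_k >= k)
    n_alive <- length(alive)

    # divisions whose scheduled time falls in (t_{k-1}, t_k]
    dividing <- alive[!is.na(div_time[alive]) &
                        div_time[alive] <= t_now &
                        div_time[alive] > times[k]]
    for (i in dividing) {
      px <- X[i, k]; py <- Y[i, k]   # parent position at its last frame
      end_k[i] <- k - 1L
      if (class[i] == "M") {
        cat <- "MM"
      } else {
        pos <- cbind(X[alive, k], Y[alive, k])
        r_all <- sqrt(rowSums(pos^2))
        r_norm <- if (max(r_all) > 0) sqrt(px^2 + py^2) / max(r_all) else 0
        ang <- (atan2(py, px) * 180 / pi) %% 360
        in_dv <- (ang >= 45 & ang < 135) | (ang >= 225 & ang < 315)
        m20 <- sum(class[alive] == "M" &
                     sqrt((X[alive, k] - px)^2 + (Y[alive, k] - py)^2) <= 20 &
                     alive != i)
        pr <- division_fate_probs(cfg, r_norm, times[k], in_dv, m20)
        cat <- sample(names(pr), 1, prob = pr)
      }
      category[i] <- cat
      d_classes <- switch(cat,
                          SS = c("S", "S"), HH = c("H", "H"),
                          MM = c("M", "M"), SM = sample(c("S", "M")))
      gen_d <- node_generation(2L * node[i])
      for (j in 1:2) {
        dx <- px + stats::rnorm(1, 0, cfg$daughter_displacement_sd)
        dy <- py + stats::rnorm(1, 0, cfg$daughter_displacement_sd)
        dcl <- d_classes[j]
        tdiv <- NA_real_
        if (dcl == "S" && gen_d < cfg$max_generation) {
          tdiv <- schedule_cycle(t_now, n_alive + 1L)
        } else if (dcl == "M" && class[i] == "M" && gen_d < 2L &&
                     stats::runif(1) < cfg$m_second_division_prob) {
          tdiv <- t_now + rtrunc_norm(1, cfg$m_first_division[1],
                                      cfg$m_first_division[2], cfg$cycle_min)
        }
        if (!is.na(tdiv) && tdiv > times[K + 1L]) tdiv <- NA_real_
        add_cell(lineage[i], 2L * node[i] + j - 1L, dcl, k, dx, dy,
                 tdiv, NA_character_)
      }
    }

    # movement: random walk with class drifts and containment
    alive <- which(birth_k <= k & end_k >= k)
    R_t <- R0 * sqrt(length(alive) / N0)
    for (i in alive) {
      if (birth_k[i] < k) {
        x <- X[i, k] + stats::rnorm(1, 0, cfg$walk_sd)
        y <- Y[i, k] + stats::rnorm(1, 0, cfg$walk_sd)
      } else {
        x <- X[i, k + 1L]; y <- Y[i, k + 1L]
      }
      r <- sqrt(x^2 + y^2)
      if (r > 0) {
        if (class[i] == "M") {
          r_new <- r + cfg$mantle_rim_drift * (cfg$mantle_rim_frac * R_t - r)
          x <- x * r_new / r; y <- y * r_new / r; r <- r_new
        } else if (class[i] == "H") {
          r_new <- r + cfg$hair_center_drift *
            (cfg$hair_center_frac * R_t - r)
          x <- x * r_new / r; y <- y * r_new / r; r <- r_new
        }
        if (r > R_t) { x <- x * R_t / r; y <- y * R_t / r }
      }
      X[i, k + 1L] <- x; Y[i, k + 1L] <- y
    }
  }

  idx <- seq_len(n_cells)
  rows_per_cell <- end_k[idx] - birth_k[idx] + 1L
  rep_i <- rep(idx, rows_per_cell)
  frame_of <- unlist(lapply(idx, function(i) birth_k[i]:end_k[i]))
  df <- data.frame(
    experiment_id = experiment_id,
    lineage_id = lineage[rep_i],
    node_index = node[rep_i],
    time_hpi = times[frame_of + 1L],
    x_um = X[cbind(rep_i, frame_of + 1L)],
    y_um = Y[cbind(rep_i, frame_of + 1L)],
    z_um = 0,
    cell_class = class[rep_i],
    stringsAsFactors = FALSE)

  manifest <- experiment_manifest(experiment_id,
                                  frame_interval_h = dt,
                                  start_hpi = cfg$start_hpi,
                                  duration_h = K * dt,
                                  founder_count = n_founders)
  tracks <- track_table(df, manifest)

  divided <- idx[!is.na(category[idx])]
  gt_div <- data.frame(experiment_id = experiment_id,
                       lineage_id = lineage[divided],
                       parent_index = node[divided],
                       parent_class = class[divided],
                       time_hpi = times[end_k[divided] + 1L],
                       category = category[divided],
                       stringsAsFactors = FALSE)
  gt_div <- gt_div[order(gt_div$lineage_id, gt_div$parent_index), ,
                   drop = FALSE]
  rownames(gt_div) <- NULL

  has_child <- paste(lineage[idx], 2L * node[idx]) %in%
    paste(lineage[idx], node[idx])
  leaves <- idx[!has_child]
  gt_clones <- do.call(rbind, lapply(seq_len(n_founders), function(l) {
    fc <- if (l <= n_m) "M" else "S"
    data.frame(experiment_id = experiment_id, lineage_id = l,
               founder_class = fc,
               clone_type = clone_type_from_classes(
                 fc, class[leaves[lineage[leaves] == l]]),
               stringsAsFactors = FALSE)
  }))

  structure(list(tracks = tracks,
                 ground_truth = list(divisions = gt_div,
                                     clones = gt_clones,
                                     founder_classes =
                                       c(rep("M", n_m), rep("S", n_s)),
                                     seed = seed)),
            class = "nm_sim_experiment")
}

#' Simulate a cohort of experiments
#'
#' Sub-seeds for the individual experiments are derived from the master
#' seed, so a fixed master seed reproduces the whole cohort.
#'
#' @param config An `nm_sim_config`.
#' @param master_seed Integer master seed.
#' @return A list of class `nm_cohort` of `nm_sim_experiment` objects,
#'   named by experiment id.
#' @export
generate_cohort <- function(config, master_seed = 1) {
  stopifnot(inherits(config, "nm_sim_config"))
  set.seed(master_seed)
  sub_seeds <- sample.int(.Machine$integer.max, config$n_experiments)
  out <- lapply(seq_len(config$n_experiments), function(i) {
    generate_experiment(config, sub_seeds[i], sprintf("sim%02d", i))
  })
  names(out) <- vapply(out, function(e) attr(e$tracks,
                                             "manifest")$experiment_id,
                       character(1))
  class(out) <- "nm_cohort"
  out
}

#' Lineage forests of a simulated cohort
#'
#' Convenience wrapper: centers each experiment's tracks and builds its
#' lineage forest.
#'
#' @param cohort An `nm_cohort` (or list of `nm_sim_experiment`).
#' @return A list of `nm_forest` objects.
#' @export
cohort_forests <- function(cohort) {
  lapply(cohort, function(e) build_forest(center_tracks(e$tracks)))
}
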