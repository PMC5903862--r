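# Fixtures are built in code: compact cell descriptors are expanded into
# track tables on the standard 15-min grid.

default_manifest <- function(experiment_id = "exp1", duration_h = 100,
                             founder_count = 1L) {
  experiment_manifest(experiment_id, frame_interval_h = 0.25,
                      start_hpi = 4, duration_h = duration_h,
                      founder_count = founder_count)
}

# cells: data.frame(lineage, node, t0, t1, x, y, class); each cell sits at
# a fixed position from t0 to t1 inclusive (times on the grid)
make_tracks <- function(cells, manifest = NULL) {
  if (is.null(manifest))
    manifest <- default_manifest(
      founder_count = length(unique(cells$lineage)))
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    ts <- seq(cells$t0[i], cells$t1[i], by = manifest$frame_interval_h)
    data.frame(experiment_id = manifest$experiment_id,
               lineage_id = cells$lineage[i], node_index = cells$node[i],
               time_hpi = ts, x_um = cells$x[i], y_um = cells$y[i],
               z_um = 0, cell_class = cells$class[i],
               stringsAsFactors = FALSE)
  }))
  track_table(rows, manifest)
}

# one founder dividing at 19 into two daughters that live to 40 hpi
simple_division_tracks <- function(d1_class = "S", d2_class = "S") {
  make_tracks(data.frame(
    lineage = c(1, 1, 1), node = c(1, 2, 3),
    t0 = c(4, 19.25, 19.25), t1 = c(19, 40, 40),
    x = c(0, -3, 3), y = c(1, 1, 1),
    class = c("S", d1_class, d2_class)))
}

# independent brute-force recomputation of the 32 features for one cell,
# straight from a state data.frame (organ-frame coordinates), the
# last-division anchor and the manifest
brute_force_features <- function(state, subject_row, anchor_x, anchor_y,
                                 anchor_t, founder_type, founder_count,
                                 time_hpi, node_index,
                                 sentinel = 100) {
  me <- state[subject_row, ]
  r <- sqrt(me$x_um^2 + me$y_um^2)
  r_max <- 0
  for (j in seq_len(nrow(state)))
    r_max <- max(r_max, sqrt(state$x_um[j]^2 + state$y_um[j]^2))
  mins <- c(H = Inf, M = Inf, S = Inf)
  sums <- c(H = 0, M = 0, S = 0)
  ns <- c(H = 0, M = 0, S = 0)
  counts <- matrix(0, 3, 3, dimnames = list(c("H", "M", "S"),
                                            c("10", "20", "30")))
  for (j in seq_len(nrow(state))) {
    if (j == subject_row) next
    cl <- state$cell_class[j]
    dij <- sqrt((state$x_um[j] - me$x_um)^2 + (state$y_um[j] - me$y_um)^2)
    mins[cl] <- min(mins[cl], dij)
    sums[cl] <- sums[cl] + dij
    ns[cl] <- ns[cl] + 1
    for (rad in c(10, 20, 30))
      if (dij <= rad)
        counts[cl, as.character(rad)] <- counts[cl, as.character(rad)] + 1
  }
  avg <- ifelse(ns > 0, sums / pmax(ns, 1), sentinel)
  mn <- ifelse(is.finite(mins), mins, sentinel)
  dot <- me$x_um * anchor_x + me$y_um * anchor_y
  nu <- r * sqrt(anchor_x^2 + anchor_y^2)
  ang <- if (nu == 0) 0 else acos(pmin(1, pmax(-1, dot / nu))) * 180 / pi
  pa <- if (r > 0) (atan2(me$y_um, me$x_um) * 180 / pi) %% 360 else 0
  list(
    absolute_time_hpi = time_hpi,
    absolute_distance_to_center = r,
    average_distance_to_h = unname(avg["H"]),
    average_distance_to_m = unname(avg["M"]),
    average_distance_to_s = unname(avg["S"]),
    cell_generation = floor(log2(node_index)),
    founder_cell_type = founder_type,
    minimum_distance_to_h = unname(mn["H"]),
    minimum_distance_to_m = unname(mn["M"]),
    minimum_distance_to_s = unname(mn["S"]),
    movement_angle_to_last_division = ang,
    movement_direction_compared_to_center =
      sqrt(anchor_x^2 + anchor_y^2) - r,
    movement_distance_since_last_division =
      sqrt((me$x_um - anchor_x)^2 + (me$y_um - anchor_y)^2),
    normalized_distance_to_center = if (r_max > 0) r / r_max else 0,
    number_of_founder_cells = founder_count,
    number_of_h_cells = sum(state$cell_class == "H"),
    number_of_h_cells_10um = unname(counts["H", "10"]),
    number_of_h_cells_20um = unname(counts["H", "20"]),
    number_of_h_cells_30um = unname(counts["H", "30"]),
    number_of_m_cells = sum(state$cell_class == "M"),
    number_of_m_cells_10um = unname(counts["M", "10"]),
    number_of_m_cells_20um = unname(counts["M", "20"]),
    number_of_m_cells_30um = unname(counts["M", "30"]),
    number_of_s_cells = sum(state$cell_class == "S"),
    number_of_s_cells_10um = unname(counts["S", "10"]),
    number_of_s_cells_20um = unname(counts["S", "20"]),
    number_of_s_cells_30um = unname(counts["S", "30"]),
    number_of_total_cells = nrow(state),
    polar_angle = pa,
    time_to_last_division = time_hpi - anchor_t,
    x_coordinate = me$x_um,
    y_coordinate = me$y_um)
}

# small simulated forest set, cached per test run
small_cohort_forests <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_experiments = 4)
      cache <<- cohort_forests(generate_cohort(cfg, master_seed = 101))
    }
    cache
  }
})
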