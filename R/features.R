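# The 32 spatial, neighbourhood and lineage features computed for one cell
# at one timepoint, and the row policies that turn labeled forests into
# training tables for fate prediction.

#' @rdname extract_features
#' @format NULL
#' @export
FEATURE_NAMES <- c(
  "absolute_time_hpi",
  "absolute_distance_to_center",
  "average_distance_to_h", "average_distance_to_m", "average_distance_to_s",
  "cell_generation",
  "founder_cell_type",
  "minimum_distance_to_h", "minimum_distance_to_m", "minimum_distance_to_s",
  "movement_angle_to_last_division",
  "movement_direction_compared_to_center",
  "movement_distance_since_last_division",
  "normalized_distance_to_center",
  "number_of_founder_cells",
  "number_of_h_cells",
  "number_of_h_cells_10um", "number_of_h_cells_20um", "number_of_h_cells_30um",
  "number_of_m_cells",
  "number_of_m_cells_10um", "number_of_m_cells_20um", "number_of_m_cells_30um",
  "number_of_s_cells",
  "number_of_s_cells_10um", "number_of_s_cells_20um", "number_of_s_cells_30um",
  "number_of_total_cells",
  "polar_angle",
  "time_to_last_division",
  "x_coordinate", "y_coordinate")

#' Feature-extraction configuration
#'
#' @param center `"fixed"` (organ frame origin, the registration centroid)
#'   or `"frame_centroid"` (instantaneous centroid of the cells alive at
#'   the frame).
#' @param sentinel_distance Finite distance (µm) reported for
#'   minimum/average distance to a class with no cells present (tree
#'   learners need finite inputs); such rows are flagged.
#' @param angle_vertex Vertex of the movement angle: `"center"` (angle at
#'   the organ center between the current location and the last-division
#'   location) or `"last_division"`.
#' @return A list of class `nm_feature_config`.
#' @export
feature_config <- function(center = c("fixed", "frame_centroid"),
                           sentinel_distance = 100,
                           angle_vertex = c("center", "last_division")) {
  structure(list(center = match.arg(center),
                 sentinel_distance = sentinel_distance,
                 angle_vertex = match.arg(angle_vertex)),
            class = "nm_feature_config")
}

#' All cells alive at one frame
#'
#' @param forest An `nm_forest`.
#' @param time_hpi A frame time on the recording grid.
#' @return A data.frame of the track rows at that frame (position and
#'   class of every cell alive).
#' @export
neuromast_state <- function(forest, time_hpi) {
  tr <- as.data.frame(forest$tracks)
  state <- tr[abs(tr$time_hpi - time_hpi) < 1e-9, , drop = FALSE]
  if (!nrow(state)) stop("no cells alive at ", time_hpi, " hpi", call. = FALSE)
  state
}

# last-division anchor of a cell: the location and time of its birth
# division, or the recording start (founder's first position) for founders
last_division_anchor <- function(forest, lineage_id, node_index) {
  if (node_index == 1L) {
    n <- forest_node(forest, lineage_id, 1L)
    list(time = forest$manifest$start_hpi, x = n$birth_x, y = n$birth_y)
  } else {
    parent <- forest_node(forest, lineage_id, node_index %/% 2L)
    list(time = parent$end_time, x = parent$end_x, y = parent$end_y)
  }
}

#' Extract the 32 features for one cell at one timepoint
#'
#' Distance-to-class features exclude the subject cell. "Last division"
#' is the cell's own birth division (the recording start for founders).
#' `movement_direction_compared_to_center` is the radial distance at the
#' last division minus the radial distance now: positive when the cell has
#' moved toward the center. `normalized_distance_to_center` divides the
#' cell's radial distance by that of the currently furthest cell.
#' `movement_angle_to_last_division` is the angle at the organ center
#' between the vectors to the current and to the last-division location.
#'
#' @param forest An `nm_forest` with centered tracks.
#' @param lineage_id,node_index Cell identity.
#' @param time_hpi Frame time at which to evaluate.
#' @param config An `nm_feature_config`.
#' @return A one-row data.frame with the 32 features plus a
#'   `sentinel_used` flag.
#' @export
extract_features <- function(forest, lineage_id, node_index, time_hpi,
                             config = feature_config()) {
  state <- neuromast_state(forest, time_hpi)
  i <- which(state$lineage_id == lineage_id & state$node_index == node_index)
  if (!length(i))
    stop("cell ", lineage_id, ":", node_index, " is not alive at ",
         time_hpi, " hpi", call. = FALSE)
  cx <- 0; cy <- 0
  if (config$center == "frame_centroid") {
    cx <- mean(state$x_um); cy <- mean(state$y_um)
  }
  px <- state$x_um[i] - cx
  py <- state$y_um[i] - cy
  ox <- state$x_um[-i] - cx
  oy <- state$y_um[-i] - cy
  ocl <- state$cell_class[-i]

  r <- sqrt(px^2 + py^2)
  r_all <- sqrt((state$x_um - cx)^2 + (state$y_um - cy)^2)
  r_max <- max(r_all)

  dists <- sqrt((ox - px)^2 + (oy - py)^2)
  sentinel_used <- FALSE
  class_dist <- function(cl) {
    d <- dists[ocl == cl]
    if (!length(d)) {
      sentinel_used <<- TRUE
      return(c(min = config$sentinel_distance, avg = config$sentinel_distance))
    }
    c(min = min(d), avg = mean(d))
  }
  dh <- class_dist("H"); dm <- class_dist("M"); ds <- class_dist("S")
  count_in <- function(cl, radius) sum(ocl == cl & dists <= radius)

  anchor <- last_division_anchor(forest, lineage_id, node_index)
  ax <- anchor$x - cx; ay <- anchor$y - cy
  move_dist <- sqrt((px - ax)^2 + (py - ay)^2)
  move_dir <- sqrt(ax^2 + ay^2) - r
  if (config$angle_vertex == "center") {
    u <- c(px, py); v <- c(ax, ay)
  } else {
    u <- c(px - ax, py - ay); v <- c(-ax, -ay)
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  move_angle <- if (nu == 0 || nv == 0) 0 else
    acos(min(1, max(-1, sum(u * v) / (nu * nv)))) * 180 / pi

  founder_type <- unname(forest$founder_class[as.character(lineage_id)])

  out <- data.frame(
    absolute_time_hpi = time_hpi,
    absolute_distance_to_center = r,
    average_distance_to_h = unname(dh["avg"]),
    average_distance_to_m = unname(dm["avg"]),
    average_distance_to_s = unname(ds["avg"]),
    cell_generation = node_generation(node_index),
    founder_cell_type = founder_type,
    minimum_distance_to_h = unname(dh["min"]),
    minimum_distance_to_m = unname(dm["min"]),
    minimum_distance_to_s = unname(ds["min"]),
    movement_angle_to_last_division = move_angle,
    movement_direction_compared_to_center = move_dir,
    movement_distance_since_last_division = move_dist,
    normalized_distance_to_center = if (r_max > 0) r / r_max else 0,
    number_of_founder_cells = forest$manifest$founder_count,
    number_of_h_cells = sum(state$cell_class == "H"),
    number_of_h_cells_10um = count_in("H", 10),
    number_of_h_cells_20um = count_in("H", 20),
    number_of_h_cells_30um = count_in("H", 30),
    number_of_m_cells = sum(state$cell_class == "M"),
    number_of_m_cells_10um = count_in("M", 10),
    number_of_m_cells_20um = count_in("M", 20),
    number_of_m_cells_30um = count_in("M", 30),
    number_of_s_cells = sum(state$cell_class == "S"),
    number_of_s_cells_10um = count_in("S", 10),
    number_of_s_cells_20um = count_in("S", 20),
    number_of_s_cells_30um = count_in("S", 30),
    number_of_total_cells = nrow(state),
    polar_angle = if (r > 0) polar_angle(px, py) else 0,
    time_to_last_division = time_hpi - anchor$time,
    x_coordinate = px,
    y_coordinate = py,
    stringsAsFactors = FALSE)
  out$sentinel_used <- sentinel_used
  out
}

# rows selected per entity by the two row policies
policy_rows <- function(forest, task, window) {
  nodes <- forest$nodes
  if (task == "clone") {
    founders <- nodes[nodes$node_index == 1L, , drop = FALSE]
    out <- lapply(seq_len(nrow(founders)), function(i) {
      f <- founders[i, ]
      tr <- forest$tracks
      times <- tr$time_hpi[tr$lineage_id == f$lineage_id &
                           tr$node_index == 1L]
      data.frame(lineage_id = f$lineage_id, node_index = 1L,
                 time_hpi = sort(times))
    })
  } else {
    # division-level tasks concern sustentacular-cell divisions; mantle
    # divisions are invariably self-renewing and are not examples
    d <- forest$divisions[forest$divisions$parent_class == "S", ,
                          drop = FALSE]
    if (!nrow(d)) return(NULL)
    out <- lapply(seq_len(nrow(d)), function(i) {
      tr <- forest$tracks
      times <- sort(tr$time_hpi[tr$lineage_id == d$lineage_id[i] &
                                tr$node_index == d$parent_index[i]])
      times <- utils::tail(times, window)
      data.frame(lineage_id = d$lineage_id[i],
                 node_index = d$parent_index[i],
                 time_hpi = times)
    })
  }
  do.call(rbind, out)
}

#' Build a labeled feature table for fate prediction
#'
#' Row policies follow the two prediction levels: for clone-level tasks,
#' one row per frame of each founder cell from recording start until its
#' first division, labeled with the clone type; for division-level tasks,
#' one row per frame of the dividing cell in a window of `window` frames
#' ending at its division, labeled with the division category.
#'
#' @param forests An `nm_forest` or list of them (tracks centered).
#' @param task `"clone"` or `"division"`.
#' @param window Frames per division (division task only; default 1, the
#'   frame of the division itself).
#' @param config An `nm_feature_config`.
#' @return A data.frame of class `nm_feature_table`: `experiment_id`,
#'   `entity` (one clone or one division), `label`, the 32 features, and
#'   `sentinel_used`.
#' @export
build_feature_table <- function(forests, task = c("clone", "division"),
                                window = 1L, config = feature_config()) {
  task <- match.arg(task)
  forests <- as_forest_list(forests)
  out <- lapply(forests, function(f) {
    rows <- policy_rows(f, task, window)
    if (is.null(rows) || !nrow(rows)) return(NULL)
    if (task == "clone") {
      labels <- clone_table(list(f))
      lab_key <- labels$lineage_id
      lab_val <- labels$clone_type
      entity <- paste0(f$experiment_id, "/", rows$lineage_id)
      label <- lab_val[match(rows$lineage_id, lab_key)]
    } else {
      d <- division_table(list(f))
      key <- paste(d$lineage_id, d$parent_index)
      label <- d$category[match(paste(rows$lineage_id, rows$node_index), key)]
      entity <- paste0(f$experiment_id, "/", rows$lineage_id, ":",
                       rows$node_index)
    }
    feats <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      extract_features(f, rows$lineage_id[i], rows$node_index[i],
                       rows$time_hpi[i], config)
    }))
    cbind(data.frame(experiment_id = f$experiment_id, entity = entity,
                     label = label, stringsAsFactors = FALSE),
          feats)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || !nrow(out))
    stop("row policy selected zero rows", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("nm_feature_table", "data.frame")
  out
}
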