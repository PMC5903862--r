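# Track-table and manifest I/O: the on-disk dialect every other module
# consumes. One row per cell per frame; heap-encoded identities
# (founder = node 1, daughters of node n = 2n and 2n+1).

TRACK_COLUMNS <- c("experiment_id", "lineage_id", "node_index", "time_hpi",
                   "x_um", "y_um", "z_um", "cell_class")

CELL_CLASSES <- c("S", "M", "H", "U")

#' Create an experiment manifest
#'
#' A manifest records the acquisition parameters of one time-lapse
#' experiment: frame interval, recording start (hours post injury),
#' duration, the world-axis convention, and the number of founder cells
#' that survived ablation.
#'
#' @param experiment_id Character label, unique within a cohort.
#' @param frame_interval_h Frame interval in hours (15-min default).
#' @param start_hpi Recording start in hours post injury.
#' @param duration_h Recording span in hours.
#' @param axis_posterior Which world direction is posterior: `"+x"` or `"-x"`.
#' @param axis_dorsal Which world direction is dorsal: `"+y"` or `"-y"`.
#' @param founder_count Number of founder cells at recording start.
#' @return A list of class `nm_manifest`.
#' @export
experiment_manifest <- function(experiment_id,
                                frame_interval_h = 0.25,
                                start_hpi = 4.0,
                                duration_h = 100,
                                axis_posterior = "+x",
                                axis_dorsal = "+y",
                                founder_count = 1L) {
  stopifnot(is.character(experiment_id), length(experiment_id) == 1L)
  if (!is.numeric(frame_interval_h) || frame_interval_h <= 0)
    stop("frame_interval_h must be a positive number", call. = FALSE)
  if (!is.numeric(duration_h) || duration_h <= 0)
    stop("duration_h must be a positive number", call. = FALSE)
  if (!axis_posterior %in% c("+x", "-x"))
    stop("axis_posterior must be \"+x\" or \"-x\"", call. = FALSE)
  if (!axis_dorsal %in% c("+y", "-y"))
    stop("axis_dorsal must be \"+y\" or \"-y\"", call. = FALSE)
  founder_count <- as.integer(founder_count)
  if (is.na(founder_count) || founder_count < 1L)
    stop("founder_count must be >= 1", call. = FALSE)
  structure(list(experiment_id = experiment_id,
                 frame_interval_h = as.numeric(frame_interval_h),
                 start_hpi = as.numeric(start_hpi),
                 duration_h = as.numeric(duration_h),
                 axis_posterior = axis_posterior,
                 axis_dorsal = axis_dorsal,
                 founder_count = founder_count),
            class = "nm_manifest")
}

#' Read / write an experiment manifest (YAML)
#'
#' @param path File path.
#' @return `read_manifest()` returns an `nm_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  do.call(experiment_manifest, y)
}

#' @rdname read_manifest
#' @param manifest An `nm_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "nm_manifest"))
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' Construct and validate a track table
#'
#' A track table holds one row per cell per frame with the columns
#' `experiment_id`, `lineage_id`, `node_index`, `time_hpi`, `x_um`, `y_um`,
#' `z_um`, `cell_class`. Validation enforces the dialect invariants:
#' unique (experiment, lineage, node, time) keys, times on the manifest
#' frame grid, and the allowed class-transition set (S may become M or H,
#' U may resolve to any class, hair cells are terminal).
#'
#' @param df A data.frame with the track columns (missing `z_um` is filled
#'   with 0).
#' @param manifest The experiment's `nm_manifest`.
#' @return A validated data.frame of class `nm_tracks`, sorted by
#'   (lineage_id, node_index, time_hpi), with the manifest attached as an
#'   attribute.
#' @export
track_table <- function(df, manifest) {
  stopifnot(is.data.frame(df), inherits(manifest, "nm_manifest"))
  if (!"z_um" %in% names(df) && nrow(df) >= 0) df$z_um <- 0
  missing <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing))
    stop("track table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[TRACK_COLUMNS]
  df$experiment_id <- as.character(df$experiment_id)
  df$lineage_id <- as.integer(df$lineage_id)
  df$node_index <- as.integer(df$node_index)
  for (col in c("time_hpi", "x_um", "y_um", "z_um"))
    df[[col]] <- as.numeric(df[[col]])
  df$cell_class <- as.character(df$cell_class)
  df <- df[order(df$lineage_id, df$node_index, df$time_hpi), , drop = FALSE]
  rownames(df) <- NULL
  validate_tracks(df, manifest)
  structure(df, manifest = manifest, class = c("nm_tracks", "data.frame"))
}

#' @rdname track_table
#' @export
validate_tracks <- function(df, manifest) {
  if (nrow(df) == 0L) return(invisible(TRUE))
  if (anyNA(df[c("lineage_id", "node_index", "time_hpi", "x_um", "y_um")]))
    stop("track table contains missing values in key or coordinate columns",
         call. = FALSE)
  bad_class <- which(!df$cell_class %in% CELL_CLASSES)
  if (length(bad_class))
    stop("invalid cell_class ", dQuote(df$cell_class[bad_class[1]]),
         " at row ", bad_class[1], call. = FALSE)
  if (any(df$lineage_id < 1L) || any(df$node_index < 1L))
    stop("lineage_id and node_index must be positive integers", call. = FALSE)

  key <- paste(df$experiment_id, df$lineage_id, df$node_index, df$time_hpi,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (experiment, lineage, node, time) at row ", dup[1], ": ",
         "lineage ", df$lineage_id[dup[1]], " node ", df$node_index[dup[1]],
         " time ", df$time_hpi[dup[1]], call. = FALSE)

  phase <- (df$time_hpi - manifest$start_hpi) / manifest$frame_interval_h
  off <- which(abs(phase - round(phase)) > 1e-6)
  if (length(off))
    stop("time_hpi off the frame grid at row ", off[1], " (time ",
         df$time_hpi[off[1]], ")", call. = FALSE)

  # class transitions per cell (input assumed sorted by time within cell)
  cell <- paste(df$experiment_id, df$lineage_id, df$node_index, sep = "\r")
  ord <- order(cell, df$time_hpi)
  cls <- df$cell_class[ord]
  same_cell <- cell[ord][-1] == cell[ord][-length(ord)]
  from <- cls[-length(cls)][same_cell]
  to <- cls[-1][same_cell]
  allowed <- from == to |
    (from == "S" & to %in% c("M", "H")) |
    (from == "U" & to %in% c("S", "M", "H"))
  if (any(!allowed)) {
    i <- which(!allowed)[1]
    stop("forbidden class transition ", from[i], " -> ", to[i],
         " (hair cells are terminal; mantle cells do not revert)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a track table from delimited text
#'
#' @param path CSV file with the documented header.
#' @param manifest The experiment's `nm_manifest`.
#' @return A validated `nm_tracks` table.
#' @export
read_tracks <- function(path, manifest) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(experiment_id = "character"))
  track_table(df, manifest)
}

#' Write a track table to delimited text
#'
#' Rows are emitted in (lineage_id, node_index, time_hpi) order with a fixed
#' column order, so writing is deterministic and `write_tracks()` followed by
#' `read_tracks()` round-trips byte-identically.
#'
#' @param tracks An `nm_tracks` table.
#' @param path Output file path.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "nm_tracks"))
  df <- as.data.frame(tracks)[TRACK_COLUMNS]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write track table to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

#' @export
print.nm_tracks <- function(x, ...) {
  m <- attr(x, "manifest")
  cat(sprintf("<nm_tracks> %s: %d rows, %d lineages, %.2f-%.2f hpi\n",
              m$experiment_id, nrow(x), length(unique(x$lineage_id)),
              if (nrow(x)) min(x$time_hpi) else NA_real_,
              if (nrow(x)) max(x$time_hpi) else NA_real_))
  invisible(x)
}
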