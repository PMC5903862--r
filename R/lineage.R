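# Lineage reconstruction from heap-encoded track identities.
# Founder = node 1; daughters of node n are nodes 2n and 2n+1; the
# generation of node n is floor(log2(n)). Division time is the parent's
# last recorded frame.

node_generation <- function(node_index) as.integer(floor(log2(node_index)))

#' Reconstruct the lineage forest of one experiment
#'
#' Groups track rows into per-cell nodes, checks the heap encoding (an
#' internal node has both daughters `2n` and `2n+1`, an orphan `k > 1`
#' without parent `floor(k/2)` is an error), and derives one division event
#' per internal node, timed and located at the parent's last recorded frame.
#'
#' @param tracks A validated `nm_tracks` table (one experiment).
#' @param max_division_displacement Sanity gate, µm: warn if a daughter's
#'   first position lies further than this from the parent's last position.
#' @return A list of class `nm_forest` with elements `experiment_id`,
#'   `nodes` (one row per cell), `divisions` (one row per division),
#'   `tracks`, and `manifest`.
#' @export
build_forest <- function(tracks, max_division_displacement = 15) {
  stopifnot(inherits(tracks, "nm_tracks"))
  manifest <- attr(tracks, "manifest")
  df <- as.data.frame(tracks)
  if (nrow(df) == 0L) stop("empty track table", call. = FALSE)
  df <- df[order(df$lineage_id, df$node_index, df$time_hpi), , drop = FALSE]

  cell <- paste(df$lineage_id, df$node_index, sep = ":")
  first <- !duplicated(cell)
  last <- !duplicated(cell, fromLast = TRUE)
  nodes <- data.frame(
    lineage_id = df$lineage_id[first],
    node_index = df$node_index[first],
    birth_time = df$time_hpi[first],
    end_time = df$time_hpi[last],
    birth_x = df$x_um[first], birth_y = df$y_um[first],
    end_x = df$x_um[last], end_y = df$y_um[last],
    final_class = df$cell_class[last],
    n_points = as.vector(table(factor(cell, levels = cell[first]))),
    stringsAsFactors = FALSE
  )
  nodes$generation <- node_generation(nodes$node_index)

  key <- paste(nodes$lineage_id, nodes$node_index)
  has <- function(lin, idx) paste(lin, idx) %in% key

  non_founder <- nodes$node_index > 1L
  orphan <- non_founder & !has(nodes$lineage_id, nodes$node_index %/% 2L)
  if (any(orphan)) {
    i <- which(orphan)[1]
    stop("orphan node: lineage ", nodes$lineage_id[i], " node ",
         nodes$node_index[i], " has no parent ", nodes$node_index[i] %/% 2L,
         call. = FALSE)
  }
  left <- has(nodes$lineage_id, 2L * nodes$node_index)
  right <- has(nodes$lineage_id, 2L * nodes$node_index + 1L)
  if (any(left != right)) {
    i <- which(left != right)[1]
    stop("single-daughter division: lineage ", nodes$lineage_id[i], " node ",
         nodes$node_index[i], " has only one of daughters ",
         2L * nodes$node_index[i], ", ", 2L * nodes$node_index[i] + 1L,
         call. = FALSE)
  }
  nodes$is_internal <- left

  # founder class is the founder's class at its first recorded frame
  founder_class <- df$cell_class[first][nodes$node_index == 1L]
  names(founder_class) <- nodes$lineage_id[nodes$node_index == 1L]

  internal <- nodes[nodes$is_internal, , drop = FALSE]
  divisions <- data.frame(
    lineage_id = internal$lineage_id,
    parent_index = internal$node_index,
    time_hpi = internal$end_time,
    x_um = internal$end_x, y_um = internal$end_y,
    generation = internal$generation,
    daughter1 = 2L * internal$node_index,
    daughter2 = 2L * internal$node_index + 1L,
    parent_class = internal$final_class,
    stringsAsFactors = FALSE
  )
  divisions <- divisions[order(divisions$lineage_id, divisions$parent_index), ,
                         drop = FALSE]
  rownames(divisions) <- NULL

  if (nrow(divisions)) {
    dkey <- paste(nodes$lineage_id, nodes$node_index)
    for (d in c("daughter1", "daughter2")) {
      j <- match(paste(divisions$lineage_id, divisions[[d]]), dkey)
      disp <- sqrt((nodes$birth_x[j] - divisions$x_um)^2 +
                   (nodes$birth_y[j] - divisions$y_um)^2)
      far <- which(disp > max_division_displacement)
      if (length(far))
        warning("daughter appears ", round(disp[far[1]], 1),
                " um from parent's last position (lineage ",
                divisions$lineage_id[far[1]], " node ",
                divisions[[d]][far[1]], ")", call. = FALSE)
    }
    # daughters must appear once the parent track has ended
    j1 <- match(paste(divisions$lineage_id, divisions$daughter1), dkey)
    if (any(nodes$birth_time[j1] <= divisions$time_hpi - 1e-9))
      stop("daughter track starts before its parent's track ends",
           call. = FALSE)
  }

  structure(list(experiment_id = df$experiment_id[1],
                 nodes = nodes,
                 divisions = divisions,
                 founder_class = founder_class,
                 tracks = tracks,
                 manifest = manifest),
            class = "nm_forest")
}

#' @export
print.nm_forest <- function(x, ...) {
  cat(sprintf("<nm_forest> %s: %d lineages, %d cells, %d divisions\n",
              x$experiment_id, length(x$founder_class), nrow(x$nodes),
              nrow(x$divisions)))
  invisible(x)
}

forest_node <- function(forest, lineage_id, node_index) {
  i <- which(forest$nodes$lineage_id == lineage_id &
             forest$nodes$node_index == node_index)
  if (!length(i))
    stop("no node ", node_index, " in lineage ", lineage_id, call. = FALSE)
  forest$nodes[i, , drop = FALSE]
}

#' Time of a founder cell's first division
#'
#' @param forest An `nm_forest`.
#' @param lineage_id Founder (lineage) identifier.
#' @return Division time in hpi (the founder track's last frame), or `NA`
#'   if the founder never divides.
#' @export
first_division_time <- function(forest, lineage_id) {
  n <- forest_node(forest, lineage_id, 1L)
  if (!n$is_internal) return(NA_real_)
  n$end_time
}

#' Cell-cycle length of one cell
#'
#' For a dividing non-founder cell, the time from its birth (first frame) to
#' its own division; for a dividing founder, the time from recording start.
#' `NA` for cells that never divide.
#'
#' @inheritParams first_division_time
#' @param node_index Heap index of the cell.
#' @return Length in hours, or `NA`.
#' @export
cycle_length <- function(forest, lineage_id, node_index) {
  n <- forest_node(forest, lineage_id, node_index)
  if (!n$is_internal) return(NA_real_)
  start <- if (node_index == 1L) forest$manifest$start_hpi else n$birth_time
  n$end_time - start
}

#' All completed cell cycles of a forest
#'
#' One row per division: parent identity, generation, founder class of the
#' lineage, division time, and cycle length (founder cycles measured from
#' recording start).
#'
#' @param forest An `nm_forest`.
#' @return A data.frame.
#' @export
cycle_table <- function(forest) {
  d <- forest$divisions
  if (!nrow(d)) {
    return(data.frame(experiment_id = character(), lineage_id = integer(),
                      parent_index = integer(), generation = integer(),
                      founder_class = character(), time_hpi = numeric(),
                      birth_time = numeric(), cycle_h = numeric(),
                      stringsAsFactors = FALSE))
  }
  j <- match(paste(d$lineage_id, d$parent_index),
             paste(forest$nodes$lineage_id, forest$nodes$node_index))
  birth <- ifelse(d$parent_index == 1L, forest$manifest$start_hpi,
                  forest$nodes$birth_time[j])
  data.frame(experiment_id = forest$experiment_id,
             lineage_id = d$lineage_id,
             parent_index = d$parent_index,
             generation = d$generation,
             founder_class = unname(
               forest$founder_class[as.character(d$lineage_id)]),
             time_hpi = d$time_hpi,
             birth_time = birth,
             cycle_h = d$time_hpi - birth,
             stringsAsFactors = FALSE)
}

#' Export one lineage as a Newick string
#'
#' Node labels are `lineage_node` (underscore, since `:` introduces branch
#' lengths in Newick); branch lengths are cell lifetimes in hours (founder
#' lifetime measured from recording start).
#'
#' @inheritParams first_division_time
#' @return A Newick string terminated by `;`.
#' @export
as_newick <- function(forest, lineage_id) {
  nodes <- forest$nodes[forest$nodes$lineage_id == lineage_id, , drop = FALSE]
  if (!nrow(nodes)) stop("no lineage ", lineage_id, call. = FALSE)
  key <- nodes$node_index
  rec <- function(idx) {
    i <- match(idx, key)
    start <- if (idx == 1L) forest$manifest$start_hpi else nodes$birth_time[i]
    len <- nodes$end_time[i] - start
    lab <- paste0(lineage_id, "_", idx)
    if (nodes$is_internal[i]) {
      paste0("(", rec(2L * idx), ",", rec(2L * idx + 1L), ")",
             lab, ":", format(len, digits = 10))
    } else {
      paste0(lab, ":", format(len, digits = 10))
    }
  }
  paste0(rec(1L), ";")
}
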