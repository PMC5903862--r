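# Clone and division classification: clone types by the final cell classes
# a founder's progeny reach, division categories by both daughters' fates
# at their own next division or at the end of the recording.

CLONE_TYPES <- c("S", "SM", "SH", "SHM", "M", "OTHER")
DIVISION_CATEGORIES <- c("SS", "HH", "MM", "SM", "OTHER")

clone_type_from_classes <- function(founder_class, leaf_classes) {
  set <- sort(unique(leaf_classes))
  if (founder_class == "M") {
    if (identical(set, "M")) return("M")
    return("OTHER")
  }
  if (identical(set, "S")) return("S")
  if (identical(set, c("M", "S"))) return("SM")
  if (identical(set, c("H", "S"))) return("SH")
  if (identical(set, c("H", "M", "S"))) return("SHM")
  "OTHER"
}

#' Classify one clone by its final composition
#'
#' The clone of a founder is its set of leaf cells at the last recorded
#' timepoint. Sustentacular-founder clones are typed S, SM, SH or SHM by
#' the cell classes present; mantle-founder clones containing only mantle
#' cells are typed M. Any other composition is retained as OTHER and
#' flagged, so anomalies in real data stay visible.
#'
#' @param forest An `nm_forest`.
#' @param lineage_id Founder identifier.
#' @return A one-row data.frame: founder class, member count (leaves),
#'   clone type, and a flag for unexpected compositions.
#' @export
clone_type <- function(forest, lineage_id) {
  nodes <- forest$nodes[forest$nodes$lineage_id == lineage_id, , drop = FALSE]
  if (!nrow(nodes)) stop("no lineage ", lineage_id, call. = FALSE)
  leaves <- nodes[!nodes$is_internal, , drop = FALSE]
  fc <- unname(forest$founder_class[as.character(lineage_id)])
  type <- clone_type_from_classes(fc, leaves$final_class)
  data.frame(experiment_id = forest$experiment_id,
             lineage_id = lineage_id,
             founder_class = fc,
             n_members = nrow(leaves),
             clone_type = type,
             flagged = type == "OTHER",
             stringsAsFactors = FALSE)
}

#' Clone table of one or more forests
#'
#' @param forests An `nm_forest` or list of them.
#' @return A data.frame with one row per founder.
#' @export
clone_table <- function(forests) {
  forests <- as_forest_list(forests)
  do.call(rbind, lapply(forests, function(f) {
    do.call(rbind, lapply(as.integer(names(f$founder_class)),
                          function(l) clone_type(f, l)))
  }))
}

division_daughter_fate <- function(forest, lineage_id, daughter_index) {
  n <- forest_node(forest, lineage_id, daughter_index)
  # fate at the daughter's own next division, or at the end of the
  # recording if it never divides; either way this is the class at the
  # daughter's last recorded frame
  n$final_class
}

#' Categorize one division by its daughters' fates
#'
#' A division is SS, HH or MM when both daughters share that fate, SM when
#' the daughters' fates are one sustentacular and one mantle cell, and
#' OTHER for any other pair.
#'
#' @param forest An `nm_forest`.
#' @param lineage_id Lineage of the dividing cell.
#' @param parent_index Heap index of the dividing cell.
#' @return Category string.
#' @export
categorize_division <- function(forest, lineage_id, parent_index) {
  f1 <- division_daughter_fate(forest, lineage_id, 2L * parent_index)
  f2 <- division_daughter_fate(forest, lineage_id, 2L * parent_index + 1L)
  pair <- sort(c(f1, f2))
  if (identical(pair, c("S", "S"))) return("SS")
  if (identical(pair, c("H", "H"))) return("HH")
  if (identical(pair, c("M", "M"))) return("MM")
  if (identical(pair, c("M", "S"))) return("SM")
  "OTHER"
}

#' All divisions of one or more forests, with categories
#'
#' @param forests An `nm_forest` or list of them.
#' @return A data.frame: one row per division with time, location,
#'   generation, the dividing cell's class, and the fate category.
#' @export
division_table <- function(forests) {
  forests <- as_forest_list(forests)
  out <- lapply(forests, function(f) {
    d <- f$divisions
    if (!nrow(d)) return(NULL)
    d$category <- vapply(seq_len(nrow(d)), function(i) {
      categorize_division(f, d$lineage_id[i], d$parent_index[i])
    }, character(1))
    d$experiment_id <- f$experiment_id
    d$founder_class <- unname(f$founder_class[as.character(d$lineage_id)])
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(lineage_id = integer(), parent_index = integer(),
                      time_hpi = numeric(), x_um = numeric(), y_um = numeric(),
                      generation = integer(), daughter1 = integer(),
                      daughter2 = integer(), parent_class = character(),
                      category = character(), experiment_id = character(),
                      founder_class = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Division-category proportions by dividing-cell class
#'
#' @param forests An `nm_forest` or list of them (or a precomputed
#'   `division_table()` data.frame).
#' @return A data.frame: for each dividing-cell class and category, count
#'   and fraction (fractions sum to 1 within each class); plus the fraction
#'   of symmetric divisions (SS + HH + MM).
#' @export
division_summary <- function(forests) {
  d <- if (is.data.frame(forests)) forests else division_table(forests)
  if (!nrow(d)) stop("no divisions to summarize", call. = FALSE)
  out <- do.call(rbind, lapply(split(d, d$parent_class), function(g) {
    counts <- table(factor(g$category, levels = DIVISION_CATEGORIES))
    data.frame(parent_class = g$parent_class[1],
               category = names(counts),
               n = as.integer(counts),
               fraction = as.numeric(counts) / nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  sym <- vapply(split(out, out$parent_class), function(g) {
    sum(g$fraction[g$category %in% c("SS", "HH", "MM")])
  }, numeric(1))
  attr(out, "symmetric_fraction") <- sym
  out
}

#' Cell counts and class proportions over time
#'
#' @param forests An `nm_forest` or list of them.
#' @param classes Classes to report (default S, M, H).
#' @return A data.frame with one row per experiment and frame: per-class
#'   counts, total, and per-class fractions.
#' @export
cell_count_timecourse <- function(forests, classes = c("S", "M", "H")) {
  forests <- as_forest_list(forests)
  out <- lapply(forests, function(f) {
    tr <- as.data.frame(f$tracks)
    times <- sort(unique(tr$time_hpi))
    tab <- table(factor(tr$time_hpi), factor(tr$cell_class, levels = classes))
    res <- data.frame(experiment_id = f$experiment_id,
                      time_hpi = as.numeric(rownames(tab)),
                      stringsAsFactors = FALSE)
    for (cl in classes) res[[paste0("n_", cl)]] <- as.integer(tab[, cl])
    res$total <- as.integer(rowSums(tab))
    for (cl in classes)
      res[[paste0("frac_", cl)]] <-
        ifelse(res$total > 0, res[[paste0("n_", cl)]] / res$total, NA_real_)
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

as_forest_list <- function(forests) {
  if (inherits(forests, "nm_forest")) return(list(forests))
  stopifnot(is.list(forests), all(vapply(forests, inherits, logical(1),
                                         "nm_forest")))
  forests
}
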