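#' Construct a cell polygon
#'
#' A cell is a simple, counter-clockwise polygon in the plane of the tissue
#' (coordinates in micrometres; y increases from the proximal base to the
#' distal tip). Each vertex carries a stable junction identifier shared with
#' the neighbouring cells that meet at that wall junction, which is what
#' makes adjacency and landmark matching across time points possible.
#'
#' @param label Positive integer cell label.
#' @param vertices An n x 2 numeric matrix of vertex coordinates (x, y),
#'   n >= 3, counter-clockwise. Clockwise input is reversed with a warning.
#' @param junction_ids Integer vector of stable vertex identifiers, same
#'   length and order as the rows of `vertices`, unique within the cell.
#' @return An object of class `cell_polygon`.
#' @export
cell_polygon <- function(label, vertices, junction_ids) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  label <- as.integer(label)
  junction_ids <- as.integer(junction_ids)
  if (length(label) != 1 || is.na(label) || label < 1) {
    stop("label must be a single positive integer", call. = FALSE)
  }
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("geometry error: cell ", label, " needs >= 3 two-column vertices",
         call. = FALSE)
  }
  if (!all(is.finite(vertices))) {
    stop("geometry error: cell ", label, " has non-finite vertices",
         call. = FALSE)
  }
  if (length(junction_ids) != nrow(vertices) || anyDuplicated(junction_ids)) {
    stop("cell ", label, ": junction_ids must be unique and match vertices",
         call. = FALSE)
  }
  a <- signed_area(vertices)
  if (a < 0) {
    warning("cell ", label, " supplied clockwise; reversing", call. = FALSE)
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
    junction_ids <- rev(junction_ids)
    a <- -a
  }
  if (a == 0 || !is_simple_polygon(vertices)) {
    stop("geometry error: cell ", label, " is not a simple CCW polygon",
         call. = FALSE)
  }
  structure(
    list(label = label, vertices = vertices, junction_ids = junction_ids),
    class = "cell_polygon"
  )
}

#' @export
print.cell_polygon <- function(x, ...) {
  cat("<cell_polygon> label", x$label, "|", nrow(x$vertices), "vertices | area",
      format(signed_area(x$vertices), digits = 5), "um^2\n")
  invisible(x)
}

#' Construct a tissue snapshot
#'
#' One labelled segmentation of the tissue at a single imaging time point.
#'
#' @param cells List of [cell_polygon()] objects with unique labels.
#' @param time_h Hours since the first image (>= 0).
#' @return An object of class `tissue_snapshot`.
#' @export
tissue_snapshot <- function(cells, time_h = 0) {
  stopifnot(is.list(cells), length(cells) > 0)
  labels <- vapply(cells, function(c) c$label, integer(1))
  if (anyDuplicated(labels)) {
    stop("label collision: ", paste(labels[duplicated(labels)], collapse = ", "),
         call. = FALSE)
  }
  if (time_h < 0) stop("time_h must be >= 0", call. = FALSE)
  names(cells) <- labels
  structure(list(time_h = as.numeric(time_h), cells = cells),
            class = "tissue_snapshot")
}

#' @export
print.tissue_snapshot <- function(x, ...) {
  cat("<tissue_snapshot> t =", x$time_h, "h |", length(x$cells), "cells\n")
  invisible(x)
}

#' Cell labels of a snapshot
#' @param snapshot A [tissue_snapshot()].
#' @return Integer vector of labels.
#' @export
cell_labels <- function(snapshot) {
  unname(vapply(snapshot$cells, function(c) c$label, integer(1)))
}

#' Per-cell centroid and area table
#'
#' @param snapshot A [tissue_snapshot()].
#' @return A tibble with columns `label`, `x`, `y` (centroid, um) and
#'   `area` (um^2).
#' @export
cell_centroids <- function(snapshot) {
  n <- length(snapshot$cells)
  lab <- integer(n); x <- numeric(n); y <- numeric(n); area <- numeric(n)
  for (i in seq_len(n)) {
    c <- snapshot$cells[[i]]
    ct <- polygon_centroid(c$vertices)
    lab[i] <- c$label; x[i] <- ct[1]; y[i] <- ct[2]
    area[i] <- signed_area(c$vertices)
  }
  tibble::tibble(label = lab, x = x, y = y, area = area)
}

#' Cell adjacency from shared wall junctions
#'
#' Two cells are adjacent iff they share at least two junction identifiers,
#' i.e. at least one wall segment.
#'
#' @param snapshot A [tissue_snapshot()].
#' @return A tibble with columns `from`, `to` (labels, `from < to`), one row
#'   per adjacent pair.
#' @export
cell_adjacency <- function(snapshot) {
  jt <- dplyr::bind_rows(lapply(snapshot$cells, function(c) {
    tibble::tibble(junction = c$junction_ids, label = c$label)
  }))
  pairs <- dplyr::inner_join(jt, jt, by = "junction",
                             relationship = "many-to-many")
  pairs <- dplyr::filter(pairs, .data$label.x < .data$label.y)
  pairs <- dplyr::count(pairs, .data$label.x, .data$label.y)
  pairs <- dplyr::filter(pairs, .data$n >= 2)
  tibble::tibble(from = pairs$label.x, to = pairs$label.y)
}

# igraph view of the adjacency, weighted by centroid-to-centroid distance.
#' @noRd
adjacency_graph <- function(snapshot) {
  adj <- cell_adjacency(snapshot)
  cen <- cell_centroids(snapshot)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(adj$from), to = as.character(adj$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(cen$label))
  )
  i <- match(as.character(adj$from), cen$label)
  j <- match(as.character(adj$to), cen$label)
  w <- sqrt((cen$x[i] - cen$x[j])^2 + (cen$y[i] - cen$y[j])^2)
  igraph::E(g)$weight <- w
  g
}

#' Construct a parent map
#'
#' Lineage assignment over one (or one composed) imaging interval: each cell
#' label at the later time point maps to its ancestor's label at the earlier
#' time point. Cells that did not divide map to themselves in simulated data
#' and to their tracked ancestor in general.
#'
#' @param child,parent Equal-length integer vectors.
#' @param t_early,t_late Interval endpoints in hours, `t_early < t_late`.
#' @return A tibble of class `parent_map` with columns `child`, `parent` and
#'   attributes `t_early`, `t_late`.
#' @export
parent_map <- function(child, parent, t_early, t_late) {
  child <- as.integer(child); parent <- as.integer(parent)
  stopifnot(length(child) == length(parent))
  if (t_early >= t_late) stop("t_early must be < t_late", call. = FALSE)
  dup <- unique(child[duplicated(child)])
  if (length(dup)) {
    sub <- split(parent[child %in% dup], child[child %in% dup])
    bad <- names(sub)[vapply(sub, function(p) length(unique(p)) > 1, logical(1))]
    if (length(bad)) {
      stop("ambiguous parentage for child label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    keep <- !duplicated(child)
    child <- child[keep]; parent <- parent[keep]
  }
  out <- tibble::tibble(child = child, parent = parent)
  attr(out, "t_early") <- as.numeric(t_early)
  attr(out, "t_late") <- as.numeric(t_late)
  class(out) <- c("parent_map", class(out))
  out
}

#' Construct a per-cell heat map table
#'
#' The tabular form of a painted tissue heat map: one scalar per cell label,
#' plus the display range used when rendering (values are stored unclipped;
#' clipping happens only at render time).
#'
#' @param label Integer cell labels.
#' @param value Finite numeric values, one per label.
#' @param quantity Name of the mapped quantity.
#' @param render_range Length-2 numeric, `min < max`.
#' @return A tibble of class `heatmap_tbl`.
#' @export
heatmap_tbl <- function(label, value, quantity = "value",
                        render_range = NULL) {
  label <- as.integer(label)
  value <- as.numeric(value)
  stopifnot(length(label) == length(value))
  if (length(value) && !all(is.finite(value))) {
    stop("heat map values must be finite", call. = FALSE)
  }
  if (anyDuplicated(label)) stop("label collision in heat map", call. = FALSE)
  if (is.null(render_range)) {
    render_range <- if (length(value)) range(value) else c(0, 1)
    if (render_range[1] == render_range[2]) {
      render_range <- render_range + c(-0.5, 0.5)
    }
  }
  if (render_range[1] >= render_range[2]) {
    stop("render_range must satisfy min < max", call. = FALSE)
  }
  out <- tibble::tibble(label = label, value = value)
  attr(out, "quantity") <- quantity
  attr(out, "render_range") <- as.numeric(render_range)
  class(out) <- c("heatmap_tbl", class(out))
  out
}

#' Construct a tissue time series
#'
#' @param snapshots Time-ordered list of [tissue_snapshot()] objects.
#' @param intervals List of [parent_map()] objects, one per consecutive
#'   snapshot pair, with matching interval endpoints.
#' @return An object of class `tissue_series`.
#' @export
tissue_series <- function(snapshots, intervals) {
  stopifnot(is.list(snapshots), is.list(intervals))
  if (length(intervals) != length(snapshots) - 1) {
    stop("incomplete series: need one parent map per consecutive snapshot pair",
         call. = FALSE)
  }
  times <- vapply(snapshots, function(s) s$time_h, numeric(1))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("snapshots must be strictly time-ordered", call. = FALSE)
  }
  for (i in seq_along(intervals)) {
    pm <- intervals[[i]]
    if (!isTRUE(all.equal(attr(pm, "t_early"), times[i])) ||
        !isTRUE(all.equal(attr(pm, "t_late"), times[i + 1]))) {
      stop("interval mismatch: parent map ", i,
           " does not span snapshot times ", times[i], "-", times[i + 1],
           call. = FALSE)
    }
  }
  structure(list(snapshots = snapshots, intervals = intervals),
            class = "tissue_series")
}

#' @export
print.tissue_series <- function(x, ...) {
  times <- vapply(x$snapshots, function(s) s$time_h, numeric(1))
  ncell <- vapply(x$snapshots, function(s) length(s$cells), integer(1))
  cat("<tissue_series>", length(times), "snapshots at t = {",
      paste(times, collapse = ", "), "} h; cells:",
      paste(ncell, collapse = " -> "), "\n")
  invisible(x)
}

#' Snapshot times of a series
#' @param series A [tissue_series()].
#' @return Numeric vector of times in hours.
#' @export
series_times <- function(series) {
  vapply(series$snapshots, function(s) s$time_h, numeric(1))
}

#' @noRd
snapshot_at <- function(series, time_h) {
  times <- series_times(series)
  i <- which(abs(times - time_h) < 1e-9)
  if (length(i) != 1) {
    stop("no snapshot at t = ", time_h, " h (have ",
         paste(times, collapse = ", "), ")", call. = FALSE)
  }
  series$snapshots[[i]]
}

#' Consistency report for a tissue series
#'
#' Cross-checks lineage maps against snapshots, mirroring the parent-label
#' correspondence checks done during manual lineage curation: children whose
#' recorded parent label is absent from the earlier snapshot (`orphan_child`),
#' earlier cells with no tracked children (`lost_cell`), and heat-map labels
#' absent from the snapshot they decorate (`unknown_heat_label`).
#'
#' @param series A [tissue_series()].
#' @param heatmaps Optional named list of [heatmap_tbl()] objects to check;
#'   each is checked against the final snapshot.
#' @return A tibble with columns `type`, `interval`, `label`. Zero rows iff
#'   the series is consistent.
#' @export
validate_series <- function(series, heatmaps = NULL) {
  out <- list()
  for (i in seq_along(series$intervals)) {
    pm <- series$intervals[[i]]
    early <- cell_labels(series$snapshots[[i]])
    late <- cell_labels(series$snapshots[[i + 1]])
    orphans <- unique(pm$parent[!(pm$parent %in% early)])
    orphan_children <- pm$child[!(pm$parent %in% early)]
    lost <- setdiff(early, pm$parent)
    unknown_children <- setdiff(pm$child, late)
    untracked_late <- setdiff(late, pm$child)
    out[[length(out) + 1]] <- tibble::tibble(
      type = c(rep("orphan_child", length(orphan_children)),
               rep("lost_cell", length(lost)),
               rep("unknown_child", length(unknown_children)),
               rep("untracked_cell", length(untracked_late))),
      interval = i,
      label = c(orphan_children, lost, unknown_children, untracked_late)
    )
  }
  if (!is.null(heatmaps)) {
    final_labels <- cell_labels(series$snapshots[[length(series$snapshots)]])
    for (nm in names(heatmaps)) {
      bad <- setdiff(heatmaps[[nm]]$label, final_labels)
      out[[length(out) + 1]] <- tibble::tibble(
        type = rep("unknown_heat_label", length(bad)),
        interval = NA_integer_, label = bad
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(type = character(), interval = integer(),
                          label = integer())
  }
  res
}
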