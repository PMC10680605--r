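# Readers and writers for the flat tissue-series formats:
#   *.cells            line-oriented snapshot records (one cell = three lines)
#   *.heat.csv         "Label,Value" per-cell heat maps
#   parents_*.csv      "Label,Parent" lineage maps
# All CSVs are comma-separated with a header row, '.' decimal separator and
# no quoting. Coordinates are written with 17 significant digits so that a
# write -> read round trip reproduces them to well below 1e-9 um.

#' Write a tissue snapshot to a `.cells` file
#'
#' The format is line-oriented: a header line, a `time` line, then for each
#' cell a triple of lines `cell <label>`, `junctions <id ...>`,
#' `vertices <x y x y ...>` (counter-clockwise).
#'
#' @param snapshot A [tissue_snapshot()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cells_file <- function(snapshot, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# tissue snapshot v1",
               paste("time", format(snapshot$time_h, digits = 17))), con)
  labs <- sort(cell_labels(snapshot))
  for (lab in labs) {
    cl <- snapshot$cells[[as.character(lab)]]
    writeLines(c(
      paste("cell", cl$label),
      paste("junctions", paste(cl$junction_ids, collapse = " ")),
      paste("vertices",
            paste(sprintf("%.17g", t(cl$vertices)), collapse = " "))
    ), con)
  }
  invisible(path)
}

#' Read a tissue snapshot from a `.cells` file
#'
#' @param path File written by [write_cells_file()].
#' @return A [tissue_snapshot()].
#' @export
read_cells_file <- function(path) {
  if (!file.exists(path)) stop("incomplete series: missing ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  time_h <- 0
  tl <- grep("^time ", lines)
  if (length(tl)) {
    time_h <- as.numeric(sub("^time ", "", lines[tl[1]]))
    lines <- lines[-tl]
  }
  starts <- grep("^cell ", lines)
  cells <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i <- starts[k]
    lab <- as.integer(sub("^cell ", "", lines[i]))
    if (i + 2 > length(lines) ||
        !startsWith(lines[i + 1], "junctions ") ||
        !startsWith(lines[i + 2], "vertices ")) {
      stop("malformed cell record for label ", lab, " in ", path, call. = FALSE)
    }
    jids <- as.integer(strsplit(sub("^junctions ", "", lines[i + 1]), " +")[[1]])
    coords <- as.numeric(strsplit(sub("^vertices ", "", lines[i + 2]), " +")[[1]])
    if (length(coords) %% 2 != 0) {
      stop("geometry error: odd coordinate count for label ", lab, call. = FALSE)
    }
    v <- matrix(coords, ncol = 2, byrow = TRUE)
    cells[[k]] <- cell_polygon(lab, v, jids)
  }
  tissue_snapshot(cells, time_h)
}

#' Read / write per-cell heat map CSVs
#'
#' The CSV dialect is `Label,Value` with a header row; [write_heatmap_csv()]
#' emits one row per label in ascending label order.
#'
#' @param path CSV file path.
#' @param quantity Quantity name attached to the returned table.
#' @param render_range Optional display range for the returned table.
#' @return [read_heatmap_csv()]: a [heatmap_tbl()]. An empty file (header
#'   only) yields an empty table, not an error.
#' @export
read_heatmap_csv <- function(path, quantity = "value", render_range = NULL) {
  lines <- readLines(path)
  if (length(lines) <= 1) {
    return(heatmap_tbl(integer(), numeric(), quantity,
                       render_range %||% c(0, 1)))
  }
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_len <- which(lengths(parts) != 2)
  if (length(bad_len)) {
    stop("parse error at line ", bad_len[1] + 1, " of ", path, call. = FALSE)
  }
  m <- do.call(rbind, parts)
  val <- suppressWarnings(as.numeric(m[, 2]))
  lab <- suppressWarnings(as.integer(m[, 1]))
  if (anyNA(val) || anyNA(lab)) {
    bad <- which(is.na(val) | is.na(lab))[1]
    stop("parse error: non-numeric entry at line ", bad + 1, " of ", path,
         call. = FALSE)
  }
  heatmap_tbl(lab, val, quantity, render_range)
}

#' @param table A [heatmap_tbl()].
#' @rdname read_heatmap_csv
#' @export
write_heatmap_csv <- function(table, path) {
  ord <- order(table$label)
  writeLines(c("Label,Value",
               sprintf("%d,%.17g", table$label[ord], table$value[ord])),
             path)
  invisible(path)
}

#' Read / write lineage parent-map CSVs
#'
#' The CSV dialect is `Label,Parent` with a header row: one row per
#' later-time-point cell, mapping it to its ancestor's label at the earlier
#' time point. A child listed twice with different parents is an
#' "ambiguous parentage" error.
#'
#' @param path CSV file path.
#' @param t_early,t_late Interval endpoints (hours) attached to the map.
#' @return [read_parent_csv()]: a [parent_map()].
#' @export
read_parent_csv <- function(path, t_early = 0, t_late = 24) {
  lines <- readLines(path)
  if (length(lines) <= 1) {
    return(parent_map(integer(), integer(), t_early, t_late))
  }
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  m <- do.call(rbind, parts)
  child <- suppressWarnings(as.integer(m[, 1]))
  parent <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(child) || anyNA(parent)) {
    bad <- which(is.na(child) | is.na(parent))[1]
    stop("parse error: non-integer entry at line ", bad + 1, " of ", path,
         call. = FALSE)
  }
  parent_map(child, parent, t_early, t_late)
}

#' @param map A [parent_map()].
#' @rdname read_parent_csv
#' @export
write_parent_csv <- function(map, path) {
  ord <- order(map$child)
  writeLines(c("Label,Parent",
               sprintf("%d,%d", map$child[ord], map$parent[ord])),
             path)
  invisible(path)
}

#' @noRd
series_file_names <- function(times) {
  snap <- sprintf("T%03d.cells", round(times))
  par <- sprintf("parents_T%03d_T%03d.csv",
                 round(times[-length(times)]), round(times[-1]))
  list(snapshots = snap, parents = par)
}

#' Write a tissue series to a directory
#'
#' Lays out one `T<time>.cells` snapshot file per time point and one
#' `parents_T<early>_T<late>.csv` per interval.
#'
#' @param series A [tissue_series()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tissue_series <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- series_file_names(series_times(series))
  for (i in seq_along(series$snapshots)) {
    write_cells_file(series$snapshots[[i]], file.path(dir, nm$snapshots[i]))
  }
  for (i in seq_along(series$intervals)) {
    write_parent_csv(series$intervals[[i]], file.path(dir, nm$parents[i]))
  }
  invisible(dir)
}

#' Read a tissue series from a directory
#'
#' Expects the layout written by [write_tissue_series()]: snapshot files
#' `T000.cells`, `T024.cells`, ... and parent CSVs
#' `parents_T000_T024.csv`, ... The assembled series is validated: every
#' interval's parents must exist in the earlier snapshot and children in the
#' later one.
#'
#' @param dir Directory path.
#' @return A validated [tissue_series()].
#' @export
read_tissue_series <- function(dir) {
  snaps <- sort(list.files(dir, pattern = "^T[0-9]+\\.cells$"))
  if (length(snaps) < 2) {
    stop("incomplete series: need >= 2 snapshot files in ", dir, call. = FALSE)
  }
  times <- as.numeric(sub("^T([0-9]+)\\.cells$", "\\1", snaps))
  ord <- order(times)
  snaps <- snaps[ord]; times <- times[ord]
  snapshots <- lapply(file.path(dir, snaps), read_cells_file)
  nm <- series_file_names(times)
  intervals <- vector("list", length(times) - 1)
  for (i in seq_len(length(times) - 1)) {
    p <- file.path(dir, nm$parents[i])
    if (!file.exists(p)) stop("incomplete series: missing ", p, call. = FALSE)
    intervals[[i]] <- read_parent_csv(p, times[i], times[i + 1])
  }
  series <- tissue_series(snapshots, intervals)
  rep <- validate_series(series)
  bad <- rep[rep$type %in% c("orphan_child", "unknown_child"), ]
  if (nrow(bad)) {
    stop("inconsistent series: ", nrow(bad), " lineage mismatches, first: ",
         bad$type[1], " label ", bad$label[1], " (interval ", bad$interval[1],
         ")", call. = FALSE)
  }
  series
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
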