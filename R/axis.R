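# Proximal-distal axis machinery: graph distance fields from source cells,
# smoothed per-cell axis directions from the distance gradient, and the
# ratio of growth along vs across the axis.

#' Graph distance field from source cells
#'
#' Shortest-path distance of every cell from the nearest source cell in the
#' cell-adjacency graph, with edge weights equal to Euclidean
#' centroid-to-centroid distances. Used to define a proximal-distal
#' coordinate by seeding the distal tip cells.
#'
#' @param snapshot A [tissue_snapshot()].
#' @param sources Integer labels of source cells (distance 0).
#' @return A tibble `label`, `d` (um; `Inf` for cells disconnected from all
#'   sources, with a warning).
#' @export
cell_distance_field <- function(snapshot, sources) {
  labs <- cell_labels(snapshot)
  sources <- as.integer(sources)
  if (!length(sources)) stop("sources must be nonempty", call. = FALSE)
  if (!all(sources %in% labs)) {
    stop("unknown source label(s): ",
         paste(setdiff(sources, labs), collapse = ", "), call. = FALSE)
  }
  g <- adjacency_graph(snapshot)
  dm <- igraph::distances(g, v = as.character(sources),
                          to = as.character(labs))
  d <- apply(dm, 2, min)
  if (any(!is.finite(d))) {
    warning(sum(!is.finite(d)), " cell(s) disconnected from all sources",
            call. = FALSE)
  }
  tibble::tibble(label = labs, d = unname(d))
}

#' Default axis sources: the distal-most cell row
#'
#' Picks the cells whose centroids lie within half a typical cell diameter
#' of the distal (maximum-y) extreme, mirroring the manual selection of tip
#' cells when seeding a distance heat map.
#'
#' @param snapshot A [tissue_snapshot()].
#' @return Integer labels.
#' @export
distal_sources <- function(snapshot) {
  cen <- cell_centroids(snapshot)
  h <- sqrt(stats::median(cen$area))
  cen$label[cen$y > max(cen$y) - h / 2]
}

#' Per-cell axis directions from a distance field
#'
#' Estimates each cell's axis as the unit gradient of the distance field by
#' a least-squares plane fit of (centroid, d) over the cell and its
#' neighbours, then applies `smooth_passes` rounds of neighbourhood
#' averaging of the directions (sign-aligned before averaging, optionally
#' weighted by cell area) and renormalises. Cells with fewer than two
#' neighbours inherit the nearest neighbour's axis and are flagged.
#'
#' @param snapshot A [tissue_snapshot()].
#' @param distances Tibble `label`, `d` from [cell_distance_field()]
#'   (distances must be finite).
#' @param smooth_passes Number of averaging rounds (default 1).
#' @param weight_by_area Weight neighbours by cell area when smoothing.
#' @return A tibble `label`, `ax`, `ay` (unit axis), `d`, `flagged`.
#' @export
axis_from_distance <- function(snapshot, distances, smooth_passes = 1,
                               weight_by_area = TRUE) {
  cen <- cell_centroids(snapshot)
  tb <- dplyr::inner_join(cen, distances, by = "label")
  if (nrow(tb) != nrow(cen)) stop("distances must cover every cell", call. = FALSE)
  if (any(!is.finite(tb$d))) stop("distances must be finite", call. = FALSE)
  adj <- cell_adjacency(snapshot)
  nbrs <- split(c(adj$to, adj$from), c(adj$from, adj$to))
  n <- nrow(tb)
  ax <- numeric(n); ay <- numeric(n); flagged <- logical(n)
  for (i in seq_len(n)) {
    lab <- tb$label[i]
    nb <- nbrs[[as.character(lab)]]
    idx <- c(i, match(nb, tb$label))
    if (length(idx) < 3) { flagged[i] <- TRUE; next }
    x <- tb$x[idx]; y <- tb$y[idx]; d <- tb$d[idx]
    xx <- cbind(1, x - mean(x), y - mean(y))
    beta <- tryCatch(qr.solve(xx, d), error = function(e) NULL)
    if (is.null(beta) || (beta[2]^2 + beta[3]^2) < 1e-24) {
      flagged[i] <- TRUE; next
    }
    nv <- c(beta[2], beta[3]) / sqrt(beta[2]^2 + beta[3]^2)
    ax[i] <- nv[1]; ay[i] <- nv[2]
  }
  # flagged cells inherit the nearest non-flagged cell's axis
  if (any(flagged)) {
    good <- which(!flagged)
    if (!length(good)) stop("no cell has an estimable axis", call. = FALSE)
    for (i in which(flagged)) {
      j <- good[which.min((tb$x[good] - tb$x[i])^2 + (tb$y[good] - tb$y[i])^2)]
      ax[i] <- ax[j]; ay[i] <- ay[j]
    }
  }
  wts <- if (weight_by_area) tb$area else rep(1, n)
  for (pass in seq_len(smooth_passes)) {
    nax <- ax; nay <- ay
    for (i in seq_len(n)) {
      nb <- nbrs[[as.character(tb$label[i])]]
      idx <- c(i, match(nb, tb$label))
      sgn <- sign(ax[idx] * ax[i] + ay[idx] * ay[i])
      sgn[sgn == 0] <- 1
      vx <- sum(wts[idx] * sgn * ax[idx])
      vy <- sum(wts[idx] * sgn * ay[idx])
      nrm <- sqrt(vx^2 + vy^2)
      if (nrm > 0) { nax[i] <- vx / nrm; nay[i] <- vy / nrm }
    }
    ax <- nax; ay <- nay
  }
  # orient so the axis points along increasing d
  for (i in seq_len(n)) {
    nb <- nbrs[[as.character(tb$label[i])]]
    idx <- match(nb, tb$label)
    if (!length(idx)) next
    dd <- tb$d[idx] - tb$d[i]
    dx <- tb$x[idx] - tb$x[i]; dy <- tb$y[idx] - tb$y[i]
    if (sum(dd * (dx * ax[i] + dy * ay[i])) < 0) {
      ax[i] <- -ax[i]; ay[i] <- -ay[i]
    }
  }
  tibble::tibble(label = tb$label, ax = ax, ay = ay, d = tb$d,
                 flagged = flagged)
}

#' Growth ratio along vs across an axis
#'
#' For a growth tensor C = F'F and unit axis a, the ratio of growth
#' parallel to the axis to growth perpendicular to it is
#' `sqrt(a' C a) / sqrt(ap' C ap)` with `ap` the axis rotated 90
#' degrees. A value of 1 means equal growth along both axes; values below 1
#' (more growth across than along) are preserved — the conventional display
#' floor of 1 is a render choice, not a data transformation.
#'
#' @param tensor A `growth_tensor` (or a 2x2 matrix taken as C).
#' @param axis Length-2 axis vector (normalised internally).
#' @return The ratio r > 0.
#' @export
pd_growth_ratio <- function(tensor, axis) {
  cc <- if (inherits(tensor, "growth_tensor")) tensor$C else as.matrix(tensor)
  a <- axis / sqrt(sum(axis^2))
  ap <- c(-a[2], a[1])
  sqrt((a %*% cc %*% a)[1] / (ap %*% cc %*% ap)[1])
}

#' Per-lineage PD/ML growth-ratio heat map
#'
#' Combines per-lineage growth tensors with a per-cell axis field into the
#' proximal-distal over medial-lateral growth ratio map. The default
#' display range is 1 to 1.7 (1 = equal growth along both axes); stored
#' values are unclipped, and `floor = TRUE` optionally floors at 1 like the
#' display convention.
#'
#' @param tensors Tibble from [growth_tensors()].
#' @param axis Tibble from [axis_from_distance()] keyed by the same labels.
#' @param floor Floor ratios at 1 (default `FALSE`).
#' @param render_range Display range, default `c(1, 1.7)`.
#' @return A [heatmap_tbl()].
#' @export
pd_ratio_map <- function(tensors, axis, floor = FALSE,
                         render_range = c(1, 1.7)) {
  tb <- dplyr::inner_join(tensors, axis, by = "label")
  r <- vapply(seq_len(nrow(tb)), function(i) {
    f <- matrix(c(tb$f11[i], tb$f21[i], tb$f12[i], tb$f22[i]), 2, 2)
    pd_growth_ratio(crossprod(f), c(tb$ax[i], tb$ay[i]))
  }, numeric(1))
  if (floor) r <- pmax(r, 1)
  heatmap_tbl(tb$label, r, "pd_ml_growth_ratio", render_range)
}
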