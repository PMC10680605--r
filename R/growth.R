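# Areal growth quantification: per-lineage growth ratios, growth heat maps,
# least-squares deformation tensors (principal directions of growth) and
# subcellular growth via artificial subdivision of single cells.

#' Polygon area of a cell
#'
#' Shoelace area of the cell's boundary polygon, in um^2.
#'
#' @param cell A [cell_polygon()].
#' @return Positive area.
#' @export
polygon_area <- function(cell) {
  a <- signed_area(cell$vertices)
  if (a <= 0 || !is_simple_polygon(cell$vertices)) {
    stop("geometry error: cell ", cell$label, " is not simple CCW",
         call. = FALSE)
  }
  a
}

#' Per-cell area heat map of a snapshot
#'
#' @param snapshot A [tissue_snapshot()].
#' @param render_range Display range, default `c(0, 4000)` um^2 as used for
#'   epidermal cell-area maps.
#' @return A [heatmap_tbl()] of areas.
#' @export
cell_area_map <- function(snapshot, render_range = c(0, 4000)) {
  cen <- cell_centroids(snapshot)
  heatmap_tbl(cen$label, cen$area, "cell_area", render_range)
}

#' @noRd
composed_map_for_span <- function(series, t0, t1) {
  times <- series_times(series)
  i0 <- which(abs(times - t0) < 1e-9)
  i1 <- which(abs(times - t1) < 1e-9)
  if (length(i0) != 1 || length(i1) != 1 || i0 >= i1) {
    stop("no span ", t0, " -> ", t1, " h in series", call. = FALSE)
  }
  compose_parent_maps(series$intervals[i0:(i1 - 1)])
}

#' Areal growth ratio of one lineage
#'
#' The growth ratio G of an ancestor over a span is the summed area of all
#' its descendants at the later time divided by the ancestor's area at the
#' earlier time. Over multi-interval spans the per-interval parent maps are
#' composed first, so G telescopes: the cumulative ratio equals the product
#' of the per-interval lineage ratios.
#'
#' @param series A [tissue_series()].
#' @param t0,t1 Span endpoints in hours (must be snapshot times).
#' @param ancestor Ancestor label at `t0`.
#' @return The ratio G > 0.
#' @export
lineage_growth_ratio <- function(series, t0, t1, ancestor) {
  pm <- composed_map_for_span(series, t0, t1)
  kids <- pm$child[pm$parent == ancestor]
  if (!length(kids)) stop("no lineage for ancestor ", ancestor, call. = FALSE)
  early <- snapshot_at(series, t0)
  late <- snapshot_at(series, t1)
  a0 <- polygon_area(early$cells[[as.character(ancestor)]])
  a1 <- sum(vapply(as.character(kids),
                   function(k) polygon_area(late$cells[[k]]), numeric(1)))
  a1 / a0
}

#' Per-lineage growth heat map over a span
#'
#' Computes the lineage growth ratio for every ancestor tracked over the
#' span and projects it onto one snapshot's labels: onto the later time
#' point for single 24 h intervals (each descendant carries its lineage's
#' ratio) and onto the earlier time point for multi-interval cumulative
#' spans, matching how per-interval and cumulative maps are displayed.
#' Default display ranges are 1-3 for 24 h intervals and 1-10 for longer
#' spans.
#'
#' @param series A [tissue_series()].
#' @param t0,t1 Span endpoints in hours.
#' @param project `"auto"` (the convention above), `"earlier"` or
#'   `"later"`.
#' @param render_range Display range; `NULL` picks the span default.
#' @return A [heatmap_tbl()] of growth ratios.
#' @export
growth_map <- function(series, t0, t1, project = c("auto", "earlier", "later"),
                       render_range = NULL) {
  project <- match.arg(project)
  single <- isTRUE(all.equal(t1 - t0, 24))
  if (project == "auto") project <- if (single) "later" else "earlier"
  if (is.null(render_range)) render_range <- if (single) c(1, 3) else c(1, 10)

  pm <- composed_map_for_span(series, t0, t1)
  early <- snapshot_at(series, t0)
  late <- snapshot_at(series, t1)
  a0 <- cell_centroids(early); a1 <- cell_centroids(late)
  tb <- dplyr::left_join(
    tibble::tibble(child = pm$child, parent = pm$parent),
    tibble::tibble(child = a1$label, area1 = a1$area), by = "child")
  per_anc <- dplyr::summarise(dplyr::group_by(tb, .data$parent),
                              a_late = sum(.data$area1), .groups = "drop")
  per_anc <- dplyr::left_join(per_anc,
                              tibble::tibble(parent = a0$label, a_early = a0$area),
                              by = "parent")
  per_anc <- dplyr::filter(per_anc, is.finite(.data$a_early))
  per_anc$g <- per_anc$a_late / per_anc$a_early
  if (project == "earlier") {
    heatmap_tbl(per_anc$parent, per_anc$g, "growth_ratio", render_range)
  } else {
    tb2 <- dplyr::inner_join(tb, per_anc[, c("parent", "g")], by = "parent")
    heatmap_tbl(tb2$child, tb2$g, "growth_ratio", render_range)
  }
}

#' Least-squares deformation tensor from matched landmarks
#'
#' Fits the affine map `p_late ~ F p_early + t` minimising the summed
#' squared landmark residuals, and derives the growth tensor C = F'F whose
#' eigenstructure gives the principal stretches s1 >= s2 (square roots of
#' the eigenvalues of C) and the principal direction of growth `theta_max`
#' (angle of the s1 eigenvector, mod pi). The fit is exact when the true
#' map is affine; rotations contribute no stretch.
#'
#' @param early,late n x 2 matrices of matched landmark coordinates,
#'   n >= 3, not collinear.
#' @return An object of class `growth_tensor`: fields `F`, `C`, `s1`, `s2`,
#'   `theta_max` (radians in `[0, pi)`), `isotropic` flag and `n_points`.
#' @export
fit_deformation <- function(early, late) {
  early <- as.matrix(early); late <- as.matrix(late)
  n <- nrow(early)
  if (n < 3 || nrow(late) != n) {
    stop("underdetermined: need >= 3 matched landmarks", call. = FALSE)
  }
  p <- sweep(early, 2, colMeans(early))
  q <- sweep(late, 2, colMeans(late))
  ppt <- crossprod(p)                  # 2x2
  if (abs(det(ppt)) < 1e-12 * max(sum(p^2), 1)^2) {
    stop("underdetermined: landmarks are collinear", call. = FALSE)
  }
  f <- t(solve(ppt, crossprod(p, q)))  # F = Q'P (P'P)^{-1}
  if (det(f) <= 0) stop("degenerate deformation: det F <= 0", call. = FALSE)
  cc <- crossprod(f)                   # C = F'F
  ev <- eigen(cc, symmetric = TRUE)
  s1 <- sqrt(ev$values[1]); s2 <- sqrt(ev$values[2])
  iso <- (s1 - s2) < 1e-9 * s1
  theta <- if (iso) 0 else atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  structure(list(F = f, C = cc, s1 = s1, s2 = s2, theta_max = theta,
                 isotropic = iso, n_points = n,
                 translation = colMeans(late) - as.numeric(f %*% colMeans(early))),
            class = "growth_tensor")
}

#' @export
print.growth_tensor <- function(x, ...) {
  cat("<growth_tensor> s1 =", format(x$s1, digits = 5),
      "s2 =", format(x$s2, digits = 5),
      "theta_max =", format(x$theta_max, digits = 4), "rad",
      if (x$isotropic) "(isotropic)" else "", "| n =", x$n_points, "\n")
  invisible(x)
}

#' Growth anisotropy of a deformation tensor
#'
#' Ratio of growth along the principal direction to growth perpendicular to
#' it, `s1 / s2 >= 1`; 1 means isotropic growth.
#'
#' @param tensor A `growth_tensor`.
#' @return The ratio s1/s2.
#' @export
anisotropy <- function(tensor) {
  tensor$s1 / tensor$s2
}

#' @noRd
lineage_landmarks <- function(series, t0, t1, ancestor) {
  pm <- composed_map_for_span(series, t0, t1)
  kids <- pm$child[pm$parent == ancestor]
  if (!length(kids)) stop("no lineage for ancestor ", ancestor, call. = FALSE)
  early <- snapshot_at(series, t0)$cells[[as.character(ancestor)]]
  if (is.null(early)) stop("no lineage for ancestor ", ancestor, call. = FALSE)
  late_cells <- snapshot_at(series, t1)$cells[as.character(kids)]
  late_j <- unlist(lapply(late_cells, function(c) c$junction_ids))
  late_v <- do.call(rbind, lapply(late_cells, function(c) c$vertices))
  keep <- !duplicated(late_j)
  late_j <- late_j[keep]; late_v <- late_v[keep, , drop = FALSE]
  shared <- intersect(early$junction_ids, late_j)
  if (length(shared) < 3) return(NULL)
  list(early = early$vertices[match(shared, early$junction_ids), , drop = FALSE],
       late = late_v[match(shared, late_j), , drop = FALSE],
       junctions = shared)
}

#' Per-lineage deformation tensors over a span
#'
#' For each ancestor, matches the junctions of its outer boundary that
#' persist between the two time points (walls created by divisions inside
#' the lineage do not exist at the earlier time and are excluded), and fits
#' the least-squares deformation tensor. Lineages with fewer than three
#' matchable or non-collinear landmarks are dropped.
#'
#' @param series A [tissue_series()].
#' @param t0,t1 Span endpoints in hours.
#' @return A tibble with one row per fitted lineage: `label`, the four
#'   components of F (`f11`, `f12`, `f21`, `f22`), `s1`, `s2`, `theta_max`,
#'   `anisotropy`, `isotropic`, `n_points`.
#' @export
growth_tensors <- function(series, t0, t1) {
  pm <- composed_map_for_span(series, t0, t1)
  ancestors <- sort(unique(pm$parent))
  rows <- lapply(ancestors, function(a) {
    lm <- lineage_landmarks(series, t0, t1, a)
    if (is.null(lm)) return(NULL)
    gt <- tryCatch(fit_deformation(lm$early, lm$late), error = function(e) NULL)
    if (is.null(gt)) return(NULL)
    tibble::tibble(label = a,
                   f11 = gt$F[1, 1], f12 = gt$F[1, 2],
                   f21 = gt$F[2, 1], f22 = gt$F[2, 2],
                   s1 = gt$s1, s2 = gt$s2, theta_max = gt$theta_max,
                   anisotropy = gt$s1 / gt$s2, isotropic = gt$isotropic,
                   n_points = gt$n_points)
  })
  dplyr::bind_rows(rows)
}

#' Subcellular growth by artificial subdivision
#'
#' Splits a single tracked cell (typically a giant cell) into regions along
#' chords between matched wall junctions present at both time points, and
#' reports each region's areal growth ratio. The area-weighted mean of the
#' region ratios equals the whole-cell ratio by construction.
#'
#' @param early,late The same cell's [cell_polygon()] at the two time
#'   points (matched junction ids).
#' @param chords List of length-2 integer vectors of junction ids; each
#'   chord must connect junctions present in both polygons.
#' @return A tibble with one row per region: `region`, `area_early`,
#'   `area_late`, `ratio`.
#' @export
subdivide_and_grow <- function(early, late, chords) {
  for (ch in chords) {
    if (!all(ch %in% early$junction_ids) || !all(ch %in% late$junction_ids)) {
      stop("unmatched landmarks: chord ", paste(ch, collapse = "-"),
           " not present at both time points", call. = FALSE)
    }
  }
  split_regions <- function(cell) {
    regions <- list(list(v = cell$vertices, j = cell$junction_ids))
    for (ch in chords) {
      hit <- which(vapply(regions, function(r) all(ch %in% r$j), logical(1)))
      if (length(hit) != 1) {
        stop("chord ", paste(ch, collapse = "-"),
             " does not split a single region", call. = FALSE)
      }
      r <- regions[[hit]]
      i1 <- match(ch[1], r$j); i2 <- match(ch[2], r$j)
      if (i1 > i2) { tmp <- i1; i1 <- i2; i2 <- tmp }
      idx_a <- i1:i2
      idx_b <- c(i2:length(r$j), 1:i1)
      regions[[hit]] <- list(v = r$v[idx_a, , drop = FALSE], j = r$j[idx_a])
      regions[[length(regions) + 1]] <-
        list(v = r$v[idx_b, , drop = FALSE], j = r$j[idx_b])
    }
    regions
  }
  re <- split_regions(early)
  rl <- split_regions(late)
  if (length(re) != length(rl)) {
    stop("subdivision produced different region counts", call. = FALSE)
  }
  # the two polygons may start at different cyclic offsets: match regions
  # across time points by shared junction membership
  ord <- vapply(re, function(r) {
    which.max(vapply(rl, function(s) length(intersect(r$j, s$j)), numeric(1)))
  }, integer(1))
  if (anyDuplicated(ord)) {
    stop("could not match subdivision regions across time points", call. = FALSE)
  }
  rl <- rl[ord]
  tibble::tibble(
    region = seq_along(re),
    area_early = vapply(re, function(r) abs(signed_area(r$v)), numeric(1)),
    area_late = vapply(rl, function(r) abs(signed_area(r$v)), numeric(1))
  ) |>
    dplyr::mutate(ratio = .data$area_late / .data$area_early)
}
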