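# Organ contour shape analysis: boundary tracing from binary masks,
# size/pose normalisation, aligned mean shapes, the shape-variability
# statistic S2 and within-flower area SDs.

#' Trace the boundary contour of a binary mask
#'
#' Extracts the ordered boundary of the largest foreground component of a
#' binary mask (Moore-neighbour tracing via `EBImage::ocontour`), returned
#' counter-clockwise in x-right / y-up coordinates. Multiple components
#' keep the largest with a warning; an empty mask is an error.
#'
#' @param mask A numeric/logical matrix (rows = y, columns = x; nonzero =
#'   foreground) or path to a PNG file.
#' @param min_area Minimum component area in pixels (default 100).
#' @return An n x 2 matrix of boundary pixel coordinates, CCW.
#' @export
trace_contour <- function(mask, min_area = 100) {
  if (is.character(mask)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG masks requires the 'png' package", call. = FALSE)
    }
    img <- png::readPNG(mask)
    if (length(dim(img)) == 3) img <- img[, , 1]
    mask <- img
  }
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("trace_contour requires the 'EBImage' package", call. = FALSE)
  }
  bin <- (as.matrix(mask) != 0) * 1
  if (!any(bin > 0)) stop("no object: mask is empty", call. = FALSE)
  lab <- EBImage::bwlabel(bin)
  sizes <- table(lab[lab > 0])
  if (length(sizes) > 1) {
    warning("mask has ", length(sizes), " components; keeping the largest",
            call. = FALSE)
  }
  biggest <- as.integer(names(sizes)[which.max(sizes)])
  if (max(sizes) < min_area) {
    stop("no object: largest component below ", min_area, " px", call. = FALSE)
  }
  comp <- (lab == biggest) * 1
  oc <- EBImage::ocontour(comp)[[1]]
  # EBImage indexes (row, col) from 0; map to x = col, y = row
  v <- cbind(oc[, 1], oc[, 2]) + 1
  v <- v[!duplicated(v), , drop = FALSE]
  if (signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  v
}

#' @noRd
resample_closed <- function(v, n_points) {
  vc <- rbind(v, v[1, ])
  seg <- sqrt(diff(vc[, 1])^2 + diff(vc[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n_points + 1)[-(n_points + 1)]
  x <- stats::approx(cum, vc[, 1], xout = s)$y
  y <- stats::approx(cum, vc[, 2], xout = s)$y
  cbind(x, y)
}

#' Normalise a contour for shape comparison
#'
#' Resamples the closed contour to `n_points` equal-arclength points,
#' centres the centroid at the origin, scales to unit enclosed area, and
#' fixes pose: the principal axis is aligned to +y with the wider half
#' (greater second moment of x) proximal (negative y), and reflection is
#' fixed so the third moment of x is nonnegative. Similarity-transformed
#' copies of a shape therefore normalise to identical point sets.
#'
#' @param contour An n x 2 matrix of ordered boundary points (open or
#'   closed; at least 32 points recommended).
#' @param n_points Number of resampled points (default 200).
#' @return An `n_points` x 2 matrix, CCW, unit area.
#' @export
normalize_contour <- function(contour, n_points = 200) {
  v <- as.matrix(contour)
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  stopifnot(nrow(v) >= 3)
  if (signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  # pose from exact area moments of the input polygon, so the result is
  # invariant to similarity transforms and to cyclic shifts of the input
  v <- sweep(v, 2, polygon_centroid(v))
  v <- v / sqrt(signed_area(v))
  ev <- eigen(polygon_covariance(v), symmetric = TRUE)
  major <- ev$vectors[, 1]
  rot <- rbind(c(major[2], -major[1]), c(major[1], major[2]))  # major -> +y
  v <- v %*% t(rot)
  if (second_x_moment(v, upper = TRUE) > second_x_moment(v, upper = FALSE)) {
    v <- -v    # wider half must sit at negative y (180 deg rotation: still CCW)
  }
  if (third_x_moment(v) < 0) {
    v[, 1] <- -v[, 1]
    v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  }
  # canonical start: vertex nearest the distal tip (max y), so the
  # resampling phase does not depend on where the input list started
  start <- which.max(v[, 2])
  v <- rbind(v[start:nrow(v), , drop = FALSE],
             v[seq_len(start - 1), , drop = FALSE])
  v <- resample_closed(v, n_points)
  v <- sweep(v, 2, polygon_centroid(v))
  v / sqrt(signed_area(v))
}

# second area moment of x over the half plane below/above the centroid,
# approximated over boundary points (adequate for pose disambiguation)
#' @noRd
second_x_moment <- function(v, upper) {
  sel <- if (upper) v[, 2] > 0 else v[, 2] < 0
  if (!any(sel)) return(0)
  sum(v[sel, 1]^2)
}

#' @noRd
third_x_moment <- function(v) sum(v[, 1]^3)

#' @noRd
cyclic_align <- function(v, ref) {
  n <- nrow(v)
  best <- NULL; best_ss <- Inf; best_shift <- 0L; best_rev <- FALSE
  for (rev_dir in c(FALSE, TRUE)) {
    w <- if (rev_dir) v[rev(seq_len(n)), , drop = FALSE] else v
    # cross-correlation via explicit shift search (n is a few hundred)
    for (s in 0:(n - 1)) {
      idx <- ((seq_len(n) - 1 + s) %% n) + 1
      ss <- sum((w[idx, ] - ref)^2)
      if (ss < best_ss) {
        best_ss <- ss; best <- w[idx, , drop = FALSE]
        best_shift <- s; best_rev <- rev_dir
      }
    }
  }
  list(points = best, ss = best_ss, shift = best_shift, reversed = best_rev)
}

#' Aligned mean shape of normalised contours
#'
#' Point-wise mean after optimising each contour's cyclic start offset (and
#' traversal direction) against the running mean, iterated until the mean
#' moves less than `tol` (default 1e-8) or `max_iter` rounds.
#'
#' @param contours List of normalised contours (equal `n_points`).
#' @param max_iter Maximum alignment iterations (default 100).
#' @param tol Convergence threshold on the mean displacement.
#' @return A list of class `mean_shape`: `mean` (n x 2 matrix), `aligned`
#'   (list of aligned contours), `iterations`, `converged`.
#' @export
mean_shape <- function(contours, max_iter = 100, tol = 1e-8) {
  stopifnot(length(contours) >= 2)
  n <- nrow(contours[[1]])
  stopifnot(all(vapply(contours, nrow, integer(1)) == n))
  # permutation-invariant starting reference: the shortest-perimeter contour
  per <- vapply(contours, function(v) {
    sum(sqrt(rowSums((rbind(v[-1, ], v[1, ]) - v)^2)))
  }, numeric(1))
  m <- contours[[which.min(per)]]
  aligned <- contours
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    aligned <- lapply(contours, function(v) cyclic_align(v, m)$points)
    new_m <- Reduce(`+`, aligned) / length(aligned)
    delta <- sqrt(mean((new_m - m)^2))
    m <- new_m
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("mean_shape did not converge in ", max_iter,
                          " iterations", call. = FALSE)
  structure(list(mean = m, aligned = aligned, iterations = it,
                 converged = converged),
            class = "mean_shape")
}

#' Shape variability statistic S2
#'
#' Each contour's deviation is its mean squared point distance to the
#' aligned mean shape of the set (after size normalisation, so similarity
#' copies contribute zero); S2 is the mean deviation across contours.
#'
#' @param contours List of contours; normalised with [normalize_contour()]
#'   first unless `normalize = FALSE`.
#' @param n_points Resampling resolution when normalising.
#' @param normalize Normalise inputs (default `TRUE`).
#' @return An object of class `shape_variability`: `S2`, tibble
#'   `deviations` (`contour`, `deviation`), and the `mean_shape` fit.
#' @export
shape_variability <- function(contours, n_points = 200, normalize = TRUE) {
  stopifnot(length(contours) >= 2)
  if (normalize) contours <- lapply(contours, normalize_contour, n_points)
  ms <- mean_shape(contours)
  dev <- vapply(ms$aligned, function(v) mean(rowSums((v - ms$mean)^2)),
                numeric(1))
  nm <- names(contours) %||% as.character(seq_along(contours))
  structure(list(S2 = mean(dev),
                 deviations = tibble::tibble(contour = nm, deviation = dev),
                 mean_shape = ms),
            class = "shape_variability")
}

#' @export
print.shape_variability <- function(x, ...) {
  cat("<shape_variability> S2 =", format(x$S2, digits = 6), "over",
      nrow(x$deviations), "contours\n")
  invisible(x)
}

#' Within-flower standard deviation of sepal areas
#'
#' For each flower, the sample SD (n - 1 denominator) of its sepal areas;
#' the group summary is the mean of the per-flower SDs with its standard
#' error. Flowers with a single sepal are excluded with a warning.
#'
#' @param data A data frame with one row per sepal.
#' @param flower,area Column names (strings) for the flower id and sepal
#'   area.
#' @return An object of class `flower_area_sd` with `per_flower` tibble
#'   (`flower`, `n`, `sd_area`), `mean_sd`, `sem`, `n_flowers`.
#' @export
within_flower_area_sd <- function(data, flower = "flower", area = "area") {
  tb <- tibble::tibble(flower = data[[flower]], area = data[[area]])
  per <- dplyr::summarise(dplyr::group_by(tb, .data$flower),
                          n = dplyr::n(),
                          sd_area = stats::sd(.data$area), .groups = "drop")
  dropped <- per$flower[per$n < 2]
  if (length(dropped)) {
    warning("excluding flower(s) with a single sepal: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    per <- per[per$n >= 2, ]
  }
  if (!nrow(per)) stop("no flower has >= 2 sepals", call. = FALSE)
  structure(list(per_flower = per,
                 mean_sd = mean(per$sd_area),
                 sem = stats::sd(per$sd_area) / sqrt(nrow(per)),
                 n_flowers = nrow(per)),
            class = "flower_area_sd")
}

#' @export
print.flower_area_sd <- function(x, ...) {
  cat("<flower_area_sd>", x$n_flowers, "flowers; mean within-flower SD =",
      format(x$mean_sd, digits = 5), "+/-", format(x$sem, digits = 4),
      "(SEM)\n")
  invisible(x)
}
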