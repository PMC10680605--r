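# Areal growth, deformation tensors, artificial subdivision.

test_that("polygon_area matches closed forms and a fan-triangulation oracle", {
  sq <- cell_polygon(1, rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), 1:4)
  expect_equal(polygon_area(sq), 1)
  tri <- cell_polygon(2, rbind(c(0, 0), c(2, 0), c(0, 2)), 1:3)
  expect_equal(polygon_area(tri), 2)

  set.seed(1)
  for (i in 1:20) {
    pts <- matrix(rnorm(24), 12, 2)
    hull <- rev(grDevices::chull(pts))          # chull is clockwise
    v <- pts[hull, , drop = FALSE]              # random convex polygon, CCW
    n <- nrow(v)
    cp <- cell_polygon(3, v, seq_len(n))
    fan <- sum(vapply(2:(n - 1), function(k) {
      0.5 * abs((v[k, 1] - v[1, 1]) * (v[k + 1, 2] - v[1, 2]) -
                  (v[k + 1, 1] - v[1, 1]) * (v[k, 2] - v[1, 2]))
    }, numeric(1)))
    expect_equal(polygon_area(cp), fan, tolerance = 1e-12)
  }
})

test_that("lineage growth ratios: closed forms and telescoping identity", {
  ser <- division_series()   # uniform area doubling with one division
  expect_equal(lineage_growth_ratio(ser, 0, 24, 1), 2, tolerance = 1e-12)
  expect_equal(lineage_growth_ratio(ser, 0, 24, 2), 2, tolerance = 1e-12)
  expect_error(lineage_growth_ratio(ser, 0, 24, 99), "no lineage")

  sim <- simulate_series(sim_config(grid = c(5, 4), n_steps = 3, seed = 3))
  times <- series_times(sim)
  comp <- compose_parent_maps(sim$intervals)
  area_of <- function(snap, labs) {
    sum(vapply(as.character(labs),
               function(l) polygon_area(snap$cells[[l]]), numeric(1)))
  }
  for (anc in unique(comp$parent)) {
    cum <- lineage_growth_ratio(sim, 0, 72, anc)
    prod3 <- 1
    cur <- anc
    for (i in 1:3) {
      pm <- sim$intervals[[i]]
      nxt <- pm$child[pm$parent %in% cur]
      prod3 <- prod3 * area_of(sim$snapshots[[i + 1]], nxt) /
        area_of(sim$snapshots[[i]], cur)
      cur <- nxt
    }
    expect_equal(cum, prod3, tolerance = 1e-10)
  }
})

test_that("growth_map projects per convention and matches per-lineage calls", {
  ser <- division_series()
  later <- growth_map(ser, 0, 24)                 # 24 h: later time point
  expect_setequal(later$label, c(1L, 3L, 4L))
  expect_equal(attr(later, "render_range"), c(1, 3))
  earlier <- growth_map(ser, 0, 24, project = "earlier")
  expect_setequal(earlier$label, c(1L, 2L))
  expect_equal(unname(earlier$value), c(2, 2), tolerance = 1e-12)

  sim <- simulate_series(sim_config(grid = c(5, 4), n_steps = 3, seed = 5))
  gm <- growth_map(sim, 0, 72, project = "earlier")
  expect_equal(attr(gm, "render_range"), c(1, 10))
  for (k in seq_len(nrow(gm))) {
    expect_equal(gm$value[k],
                 lineage_growth_ratio(sim, 0, 72, gm$label[k]),
                 tolerance = 1e-12)
  }

  # stationary series: all ratios 1
  still <- tissue_series(list(two_cell_snapshot(0), two_cell_snapshot(24)),
                         list(parent_map(c(1L, 2L), c(1L, 2L), 0, 24)))
  expect_equal(growth_map(still, 0, 24)$value, c(1, 1), tolerance = 1e-12)
})

test_that("fit_deformation recovers pure stretches, rotations and random affines", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  gt <- fit_deformation(sq, sq %*% diag(c(2, 1)))
  expect_equal(gt$s1, 2, tolerance = 1e-12)
  expect_equal(gt$s2, 1, tolerance = 1e-12)
  expect_equal(gt$theta_max, 0, tolerance = 1e-12)
  expect_equal(anisotropy(gt), 2, tolerance = 1e-12)

  th <- 30 * pi / 180
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  gr <- fit_deformation(sq, sq %*% t(rot))
  expect_equal(gr$s1, 1, tolerance = 1e-12)
  expect_equal(gr$s2, 1, tolerance = 1e-12)
  expect_true(gr$isotropic)
  expect_equal(gr$theta_max, 0)   # tie-break at isotropy

  set.seed(2)
  for (i in 1:200) {
    f <- matrix(rnorm(4, sd = 0.8), 2, 2) + diag(2)
    if (det(f) <= 0.05) next
    p <- matrix(rnorm(12), 6, 2)
    t0 <- rnorm(2)
    q <- p %*% t(f) + rep(t0, each = 6)
    fit <- fit_deformation(p, q)
    expect_lt(max(abs(fit$F - f)), 1e-8)
    sv <- svd(f)$d
    expect_equal(anisotropy(fit), sv[1] / sv[2], tolerance = 1e-10)
  }
})

test_that("fit_deformation rejects degenerate input", {
  line <- cbind(1:4, 2 * (1:4))
  expect_error(fit_deformation(line, line), "collinear")
  expect_error(fit_deformation(line[1:2, ], line[1:2, ]), "underdetermined")
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  refl <- sq %*% diag(c(-1, 1))
  expect_error(fit_deformation(sq, refl), "degenerate deformation")
})

test_that("deformation is invariant under a common rigid motion", {
  set.seed(3)
  p <- matrix(rnorm(16), 8, 2)
  f <- rbind(c(1.5, 0.3), c(-0.1, 0.9))
  q <- p %*% t(f)
  base <- fit_deformation(p, q)
  phi <- 0.7
  r <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  moved <- fit_deformation(p %*% t(r) + 2, q %*% t(r) - 1)
  expect_equal(moved$s1, base$s1, tolerance = 1e-10)
  expect_equal(moved$s2, base$s2, tolerance = 1e-10)
  expect_equal(anisotropy(moved), anisotropy(base), tolerance = 1e-10)
})

test_that("stretch error decreases with landmark count under noise", {
  set.seed(4)
  f <- diag(c(1.8, 1.1))
  med_err <- sapply(c(4, 8, 16), function(n) {
    median(replicate(120, {
      p <- matrix(rnorm(2 * n, sd = 2), n, 2)
      q <- p %*% t(f) + matrix(rnorm(2 * n, sd = 0.1), n, 2)
      fit <- tryCatch(fit_deformation(p, q), error = function(e) NULL)
      if (is.null(fit)) return(NA)
      abs(fit$s1 - 1.8)
    }, simplify = TRUE), na.rm = TRUE)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("per-lineage tensors on simulated data have positive stretches", {
  sim <- simulate_series(sim_config(grid = c(5, 4), n_steps = 2, seed = 6))
  tens <- growth_tensors(sim, 0, 48)
  expect_tibble(tens)
  expect_gt(nrow(tens), 5)
  expect_true(all(tens$s1 >= tens$s2))
  expect_true(all(tens$s2 > 0))
  expect_true(all(tens$theta_max >= 0 & tens$theta_max < pi))
})

test_that("subdivide_and_grow: uniform scaling, localised growth, conservation", {
  early <- cell_polygon(1, rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1),
                                 c(0, 0.5)), c(1, 2, 3, 4, 5))
  # uniform doubling of area
  k <- sqrt(2)
  late <- cell_polygon(1, k * early$vertices, early$junction_ids)
  res <- subdivide_and_grow(early, late, list(c(5, 2)))
  expect_equal(res$ratio, c(2, 2), tolerance = 1e-12)

  # growth confined to the distal (high-y) half
  stretch_top <- early$vertices
  stretch_top[, 2] <- ifelse(stretch_top[, 2] > 0.5, 1.5 * stretch_top[, 2],
                             stretch_top[, 2])
  late2 <- cell_polygon(1, stretch_top, early$junction_ids)
  # chord between junctions 5 (0, 0.5) and 2 (2, 0) splits lower from upper
  res2 <- subdivide_and_grow(early, late2, list(c(5, 2)))
  expect_equal(nrow(res2), 2)
  expect_gt(max(res2$ratio), min(res2$ratio))

  # area-weighted mean of region ratios equals the whole-cell ratio
  whole <- polygon_area(late2) / polygon_area(early)
  expect_equal(sum(res2$ratio * res2$area_early) / sum(res2$area_early),
               whole, tolerance = 1e-9)

  expect_error(subdivide_and_grow(early, late, list(c(1, 99))),
               "unmatched landmarks")
})

test_that("subdivision regions match across cyclically rotated time points", {
  early <- cell_polygon(1, rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)), 1:4)
  # same cell at the later time, vertex list cyclically rotated and widened
  vlate <- rbind(c(2.9, 1), c(0, 1), c(0, 0), c(2.9, 0))
  late <- cell_polygon(1, vlate, c(3, 4, 1, 2))
  res <- subdivide_and_grow(early, late, list(c(1, 3)))
  expect_equal(nrow(res), 2)
  whole <- polygon_area(late) / polygon_area(early)
  expect_equal(sum(res$ratio * res$area_early) / sum(res$area_early), whole,
               tolerance = 1e-9)
})
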