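# Distance fields, axis estimation, PD/ML growth ratios.

test_that("distance field on a chain and trivial sources", {
  snap <- chain_snapshot()
  d <- cell_distance_field(snap, sources = 1)
  expect_equal(d$d[order(d$label)], c(0, 1, 2))
  d_all <- cell_distance_field(snap, sources = 1:3)
  expect_equal(d_all$d, rep(0, 3))
  expect_error(cell_distance_field(snap, integer()), "nonempty")
  expect_error(cell_distance_field(snap, 99), "unknown source")
})

test_that("distance field equals a naive O(V^2) Dijkstra oracle", {
  naive_dijkstra <- function(snap, sources) {
    cen <- cell_centroids(snap)
    adj <- cell_adjacency(snap)
    n <- nrow(cen)
    w <- matrix(Inf, n, n)
    for (k in seq_len(nrow(adj))) {
      i <- match(adj$from[k], cen$label); j <- match(adj$to[k], cen$label)
      w[i, j] <- w[j, i] <-
        sqrt((cen$x[i] - cen$x[j])^2 + (cen$y[i] - cen$y[j])^2)
    }
    d <- rep(Inf, n)
    d[match(sources, cen$label)] <- 0
    done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, d))
      if (!is.finite(d[u])) break
      done[u] <- TRUE
      for (v in seq_len(n)) {
        if (!done[v] && is.finite(w[u, v]) && d[u] + w[u, v] < d[v]) {
          d[v] <- d[u] + w[u, v]
        }
      }
    }
    tibble::tibble(label = cen$label, d = d)
  }
  set.seed(10)
  for (i in 1:10) {
    snap <- make_initial_tissue(c(sample(3:6, 1), sample(3:6, 1)),
                                jitter = 0.25, seed = NULL)
    srcs <- sample(cell_labels(snap), sample(1:2, 1))
    mine <- cell_distance_field(snap, srcs)
    oracle <- naive_dijkstra(snap, srcs)
    expect_equal(mine$d[order(mine$label)], oracle$d[order(oracle$label)],
                 tolerance = 1e-10)
  }
})

test_that("distance fields satisfy the triangle inequality along edges", {
  snap <- make_initial_tissue(c(5, 5), jitter = 0.2, seed = 12)
  d <- cell_distance_field(snap, sources = distal_sources(snap))
  cen <- cell_centroids(snap)
  adj <- cell_adjacency(snap)
  for (k in seq_len(nrow(adj))) {
    i <- match(adj$from[k], cen$label); j <- match(adj$to[k], cen$label)
    w <- sqrt((cen$x[i] - cen$x[j])^2 + (cen$y[i] - cen$y[j])^2)
    expect_lte(abs(d$d[i] - d$d[j]), w + 1e-9)
  }
})

test_that("axis recovery from exact planar gradients", {
  snap <- make_initial_tissue(c(6, 5), jitter = 0.1, seed = 2)
  cen <- cell_centroids(snap)
  for (passes in c(0, 2)) {
    ax_y <- axis_from_distance(snap, tibble::tibble(label = cen$label,
                                                    d = cen$y),
                               smooth_passes = passes)
    expect_equal(ax_y$ax, rep(0, nrow(ax_y)), tolerance = 1e-9)
    expect_equal(abs(ax_y$ay), rep(1, nrow(ax_y)), tolerance = 1e-9)
    # oriented along increasing d
    expect_true(all(ax_y$ay > 0))
  }
  ax_x <- axis_from_distance(snap, tibble::tibble(label = cen$label,
                                                  d = cen$x))
  expect_equal(abs(ax_x$ax), rep(1, nrow(ax_x)), tolerance = 1e-9)
  expect_true(all(ax_x$ax > 0))
})

test_that("smoothing reduces angular error on noisy gradients", {
  snap <- make_initial_tissue(c(8, 6), jitter = 0.1, seed = 3)
  cen <- cell_centroids(snap)
  set.seed(99)
  errs <- replicate(20, {
    d <- tibble::tibble(label = cen$label, d = cen$y + rnorm(nrow(cen), sd = 3))
    ang_err <- function(passes) {
      ax <- axis_from_distance(snap, d, smooth_passes = passes)
      median(abs(atan2(ax$ax, ax$ay)))
    }
    c(raw = ang_err(0), smooth = ang_err(2))
  })
  expect_lt(median(errs["smooth", ]), median(errs["raw", ]))
})

test_that("pd_growth_ratio closed forms and reciprocal identity", {
  expect_equal(pd_growth_ratio(4 * diag(2), c(1, 0)), 1)
  expect_equal(pd_growth_ratio(4 * diag(2), c(0.3, 0.8)), 1)
  cc <- diag(c(4, 1))
  expect_equal(pd_growth_ratio(cc, c(1, 0)), 2)
  expect_equal(pd_growth_ratio(cc, c(0, 1)), 0.5)
  a45 <- c(1, 1) / sqrt(2)
  expect_equal(pd_growth_ratio(cc, a45), 1, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    f <- matrix(rnorm(4), 2, 2) + diag(2)
    if (det(f) <= 0) next
    cmat <- crossprod(f)
    a <- rnorm(2); a <- a / sqrt(sum(a^2))
    ap <- c(-a[2], a[1])
    expect_equal(pd_growth_ratio(cmat, a) * pd_growth_ratio(cmat, ap), 1,
                 tolerance = 1e-12)
  }
})

test_that("the ratio is maximised at theta_max with value s1/s2", {
  set.seed(6)
  for (i in 1:10) {
    f <- matrix(rnorm(4, sd = 0.5), 2, 2) + diag(2)
    if (det(f) <= 0.05) next
    p <- matrix(rnorm(16), 8, 2)
    gt <- fit_deformation(p, p %*% t(f))
    angles <- seq(0, pi, length.out = 2001)
    vals <- vapply(angles, function(th) {
      pd_growth_ratio(gt, c(cos(th), sin(th)))
    }, numeric(1))
    best <- angles[which.max(vals)]
    ref <- stats::optimize(function(th) pd_growth_ratio(gt, c(cos(th), sin(th))),
                           c(best - 0.01, best + 0.01), maximum = TRUE,
                           tol = 1e-10)
    expect_equal(ref$objective, anisotropy(gt), tolerance = 1e-6)
    dtheta <- min(abs(best - gt$theta_max), pi - abs(best - gt$theta_max))
    expect_lt(dtheta, 0.01)
  }
})

test_that("pd_ratio_map joins tensors with axes and optionally floors", {
  sim <- simulate_series(sim_config(grid = c(5, 4), n_steps = 2, seed = 7))
  tens <- growth_tensors(sim, 0, 48)
  snap <- sim$snapshots[[1]]
  d <- cell_distance_field(snap, distal_sources(snap))
  ax <- axis_from_distance(snap, d)
  pm <- pd_ratio_map(tens, ax)
  expect_equal(attr(pm, "render_range"), c(1, 1.7))
  expect_true(all(pm$value > 0))
  flo <- pd_ratio_map(tens, ax, floor = TRUE)
  expect_true(all(flo$value >= 1))
  expect_equal(pmax(pm$value, 1), flo$value)
})
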