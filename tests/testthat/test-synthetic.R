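# Synthetic growing-tissue simulator.

test_that("initial lattice tiles the rectangle and is deterministic", {
  snap <- make_initial_tissue(c(2, 2), jitter = 0, seed = 1, spacing = 10)
  cen <- cell_centroids(snap)
  expect_equal(nrow(cen), 4)
  expect_equal(cen$area, rep(100, 4))
  expect_equal(sum(cen$area), 400)  # union = bounding rectangle

  a <- make_initial_tissue(c(5, 4), jitter = 0.3, seed = 7)
  b <- make_initial_tissue(c(5, 4), jitter = 0.3, seed = 7)
  expect_identical(a, b)

  # jittered cells stay simple and CCW, and still tile the rectangle
  big <- make_initial_tissue(c(10, 6), jitter = 0.3, seed = 3, spacing = 10)
  areas <- cell_centroids(big)$area
  expect_true(all(areas > 0))
  expect_equal(sum(areas), 10 * 6 * 100, tolerance = 1e-9)
})

test_that("growth field reduces to the band and respects symmetry", {
  snap <- make_initial_tissue(c(6, 4), jitter = 0, seed = 1)
  cfg0 <- sim_config(band_peak = 0, noise_sd = 0, grid = c(6, 4))
  f <- sample_growth_field(snap, cfg0, 0)
  expect_equal(unname(f$g), rep(1, length(f$g)))

  # noise-free: cells at equal y have identical g
  cfgb <- sim_config(noise_sd = 0, grid = c(6, 4))
  fb <- sample_growth_field(snap, cfgb, 0)
  cen <- cell_centroids(snap)
  for (yy in unique(cen$y)) {
    gs <- fb$g[as.character(cen$label[cen$y == yy])]
    expect_lt(diff(range(gs)), 1e-12)
  }
  # the band is basipetal: its centre row decreases with the step index
  f0 <- sample_growth_field(snap, cfgb, 0)
  f3 <- sample_growth_field(snap, cfgb, 3)
  peak_y <- function(f) cen$y[which.max(f$g[as.character(cen$label)])]
  expect_gt(peak_y(f0), peak_y(f3))
})

test_that("noise has the configured marginal SD and temporal persistence", {
  snap <- make_initial_tissue(c(5, 4), jitter = 0, seed = 1)
  cfg <- sim_config(grid = c(5, 4), noise_sd = 0.25, persistence = 1)
  set.seed(42)
  draws <- replicate(300, {
    f1 <- sample_growth_field(snap, cfg, 0)
    f2 <- sample_growth_field(snap, cfg, 1, prev_noise = f1$noise)
    c(f1$noise[[1]], f2$noise[[1]], f1$noise[[5]])
  })
  # rho = 1: noise carried over unchanged
  expect_equal(cor(draws[1, ], draws[2, ]), 1, tolerance = 1e-12)
  expect_equal(sd(draws[1, ]), 0.25, tolerance = 0.12)

  cfg5 <- sim_config(grid = c(5, 4), noise_sd = 0.25, persistence = 0.5)
  set.seed(43)
  d5 <- replicate(400, {
    f1 <- sample_growth_field(snap, cfg5, 0)
    f2 <- sample_growth_field(snap, cfg5, 1, prev_noise = f1$noise)
    c(f1$noise[[3]], f2$noise[[3]])
  })
  expect_equal(cor(d5[1, ], d5[2, ]), 0.5, tolerance = 0.1)
})

test_that("stationary step is the identity up to labels and daughters conserve area", {
  snap <- make_initial_tissue(c(3, 3), jitter = 0.1, seed = 5)
  cfg <- sim_config(grid = c(3, 3), band_peak = 0, noise_sd = 0, kappa = 1e-6)
  f <- sample_growth_field(snap, cfg, 0)
  set.seed(1)
  r <- step_tissue(snap, f, cfg)
  expect_setequal(cell_labels(r$snapshot), cell_labels(snap))
  expect_equal(nrow(r$parent_map), length(snap$cells))
  expect_identical(r$parent_map$child, r$parent_map$parent)
  for (lab in as.character(cell_labels(snap))) {
    expect_equal(r$snapshot$cells[[lab]]$vertices, snap$cells[[lab]]$vertices,
                 tolerance = 1e-9)
  }

  # force one division: the two daughters' areas sum to the parent's
  cfg2 <- sim_config(grid = c(3, 3), band_peak = 0, noise_sd = 0,
                     a_div = 99, kappa = 1)  # threshold just under 100 um^2
  set.seed(2)
  r2 <- step_tissue(snap, f, cfg2)
  pm <- r2$parent_map
  div_parents <- unique(pm$parent[duplicated(pm$parent)])
  expect_gt(length(div_parents), 0)
  a_new <- cell_centroids(r2$snapshot)
  for (p in div_parents) {
    kids <- pm$child[pm$parent == p]
    expect_length(kids, 2)
    a_parent <- sepaldyn:::signed_area(snap$cells[[as.character(p)]]$vertices)
    expect_equal(sum(a_new$area[a_new$label %in% kids]), a_parent,
                 tolerance = 1e-9)
  }
})

test_that("realised growth tracks the target field (smooth-field contract)", {
  errs <- sapply(1:3, function(s) {
    cfg <- sim_config(seed = s, corr_len = 2, noise_sd = 0.2)
    set.seed(cfg$seed)
    snap <- make_initial_tissue(cfg$grid, cfg$jitter, NULL, cfg$spacing)
    f <- sample_growth_field(snap, cfg, 0)
    r <- step_tissue(snap, f, cfg)
    a0 <- cell_centroids(snap)
    a1 <- cell_centroids(r$snapshot)
    pm <- r$parent_map
    late <- tapply(a1$area[match(pm$child, a1$label)], pm$parent, sum)
    realised <- late[as.character(a0$label)] / a0$area
    median(abs(realised / f$g[as.character(a0$label)] - 1))
  })
  expect_lt(median(errs), 0.05)
})

test_that("simulated series are deterministic, consistent and 24 h spaced", {
  cfg <- sim_config(grid = c(6, 5), n_steps = 3, seed = 9)
  s1 <- simulate_series(cfg)
  s2 <- simulate_series(cfg)
  expect_identical(s1, s2)
  expect_equal(series_times(s1), c(0, 24, 48, 72))
  expect_equal(nrow(validate_series(s1)), 0)
})

test_that("giant cells never divide and high kappa divides more", {
  cfg <- sim_config(grid = c(6, 5), n_steps = 3, seed = 4, p_giant = 0.3,
                    kappa = 3)
  ser <- simulate_series(cfg)
  giants <- attr(ser, "giant_labels")
  expect_gt(length(giants), 0)
  counts <- daughter_counts(compose_parent_maps(ser$intervals))
  expect_true(all(counts$value[counts$label %in% giants] == 1))
  expect_gte(count_nondividing(counts), length(giants))

  lo <- simulate_series(sim_config(grid = c(6, 5), n_steps = 3, seed = 4,
                                   kappa = 0.2))
  hi <- simulate_series(sim_config(grid = c(6, 5), n_steps = 3, seed = 4,
                                   kappa = 3))
  n_div <- function(s) {
    sum(vapply(s$intervals, function(pm) sum(duplicated(pm$parent)),
               integer(1)))
  }
  expect_gt(n_div(hi), n_div(lo))
})

test_that("banded growth is faster mid-band than off-band", {
  ser <- simulate_series(sim_config(grid = c(10, 5), n_steps = 1, seed = 6,
                                    noise_sd = 0))
  gm <- growth_map(ser, 0, 24, project = "earlier")
  cen <- cell_centroids(ser$snapshots[[1]])
  tb <- dplyr::inner_join(gm, cen, by = "label")
  band <- tb$value[tb$y > 80]          # distal rows, where the band starts
  off <- tb$value[tb$y < 30]
  expect_gt(mean(band), mean(off))
})
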