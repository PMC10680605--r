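# Wasserstein distances, PCoA, Kendall tau, ANOVA + Tukey letters.

test_that("wasserstein_1d closed forms and equal-size sorted formula", {
  expect_equal(wasserstein_1d(0, 1), 1)
  expect_equal(wasserstein_1d(c(3, 1, 2), c(2, 3, 1)), 0)
  expect_equal(wasserstein_1d(c(0, 1), c(0, 2)), 0.5)
  # unequal sizes: CDF-integration against a fine common grid
  a <- c(0, 1); b <- c(0, 1, 2)
  qa <- quantile(a, probs = (1:6000 - 0.5) / 6000, type = 1)
  qb <- quantile(b, probs = (1:6000 - 0.5) / 6000, type = 1)
  expect_equal(wasserstein_1d(a, b), mean(abs(qa - qb)), tolerance = 1e-3)
})

test_that("wasserstein_1d is a metric (transport oracle on small samples)", {
  # order-1 transport cost oracle via assignment over sorted replication
  lp_oracle <- function(a, b) {
    n <- length(a) * length(b)
    ar <- rep(sort(a), each = length(b))
    br <- rep(sort(b), times = length(a))
    mean(abs(sort(ar) - sort(br)))
  }
  set.seed(9)
  for (i in 1:30) {
    a <- round(rnorm(sample(2:6, 1)), 2)
    b <- round(rnorm(sample(2:6, 1)), 2)
    cc <- round(rnorm(sample(2:6, 1)), 2)
    dab <- wasserstein_1d(a, b)
    expect_equal(dab, lp_oracle(a, b), tolerance = 1e-10)
    expect_equal(dab, wasserstein_1d(b, a), tolerance = 1e-12)
    expect_lte(dab, wasserstein_1d(a, cc) + wasserstein_1d(cc, b) + 1e-12)
  }
})

test_that("pcoa reconstructs planar configurations and reports eigenvalues", {
  set.seed(10)
  pts <- matrix(rnorm(8), 4, 2)
  d <- as.matrix(dist(pts))
  fit <- pcoa(d, k = 2)
  rec <- as.matrix(dist(as.matrix(fit$points[, c("axis1", "axis2")])))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_true(all(diff(fit$eigenvalues) <= 1e-9))

  # agrees with classical scaling in stats as an independent cross-check
  cs <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(as.matrix(fit$points[, 2:3])), abs(cs$points),
               tolerance = 1e-8, ignore_attr = TRUE)

  # collinear points: second eigenvalue ~ 0
  line <- cbind(c(0, 1, 2.5), 0)
  f2 <- pcoa(as.matrix(dist(line)), k = 2)
  expect_lt(abs(f2$eigenvalues[2]), 1e-8)

  # permutation of rows permutes coordinates identically
  p <- c(3, 1, 4, 2)
  fp <- pcoa(d[p, p], k = 2)
  expect_equal(abs(as.matrix(fp$points[, 2:3])),
               abs(as.matrix(fit$points[p, 2:3])),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("kendall tau-b matches brute-force enumeration with ties", {
  brute_tau_b <- function(x, y) {
    n <- length(x); conc <- 0; disc <- 0; tx <- 0; ty <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
    n0 <- n * (n - 1) / 2
    (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
  }
  expect_equal(kendall_tau(1:3, 1:3)$statistic, 1)
  expect_equal(kendall_tau(1:3, 3:1)$statistic, -1)
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(kendall_tau(x, y)$statistic, brute_tau_b(x, y),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- x + sample(0:3, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    mine <- kendall_tau(x, y)
    expect_equal(mine$statistic, brute_tau_b(x, y), tolerance = 1e-12)
    # cross-check the statistic against the stock implementation
    expect_equal(mine$statistic,
                 unname(cor.test(x, y, method = "kendall",
                                 exact = FALSE)$estimate),
                 tolerance = 1e-10)
  }
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "constant")
})

test_that("kendall p-values: exact enumeration small n, normal approx large n", {
  res <- kendall_tau(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$method, "exact permutation")
  # untied exact p matches cor.test's exact computation
  ct <- cor.test(1:5, c(2, 1, 4, 3, 5), method = "kendall", exact = TRUE)
  expect_equal(res$p.value, ct$p.value, tolerance = 1e-10)

  set.seed(12)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  res2 <- kendall_tau(x, y)
  expect_equal(res2$method, "normal approximation")
  ct2 <- cor.test(x, y, method = "kendall", exact = FALSE, continuity = FALSE)
  expect_equal(res2$p.value, ct2$p.value, tolerance = 1e-6)
})

test_that("anova_tukey: identical groups share a letter, separated groups do not", {
  same <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                         group = rep(c("g1", "g2"), each = 3))
  fit <- anova_tukey(same)
  expect_equal(fit$f, 0)
  expect_equal(length(unique(fit$letters$letters)), 1)

  apart <- tibble::tibble(value = c(0, 0.1, -0.1, 10, 10.1, 9.9),
                          group = rep(c("lo", "hi"), each = 3))
  fit2 <- anova_tukey(apart)
  expect_lt(fit2$p, 1e-6)
  expect_false(any(strsplit(fit2$letters$letters[1], "")[[1]] %in%
                     strsplit(fit2$letters$letters[2], "")[[1]]))

  flat <- tibble::tibble(value = rep(c(1, 2), each = 2),
                         group = rep(c("a", "b"), each = 2))
  flat$value <- rep(c(1, 1, 2, 2))
  expect_error(anova_tukey(flat), "degenerate")
})

test_that("letter displays are valid w.r.t. the significance graph (<=5 groups)", {
  valid_letters <- function(letters_tb, tukey, alpha = 0.05) {
    sig <- strsplit(tukey$pair[tukey$p.adj < alpha], "-", fixed = TRUE)
    lset <- strsplit(letters_tb$letters, "")
    names(lset) <- letters_tb$group
    # no letter joins a significantly different pair
    for (p in sig) {
      if (length(intersect(lset[[p[1]]], lset[[p[2]]]))) return(FALSE)
    }
    # every non-significant pair shares a letter
    gr <- letters_tb$group
    for (i in seq_along(gr)) for (j in seq_along(gr)) {
      if (i >= j) next
      is_sig <- any(vapply(sig, function(p) setequal(p, gr[c(i, j)]),
                           logical(1)))
      if (!is_sig && !length(intersect(lset[[gr[i]]], lset[[gr[j]]]))) {
        return(FALSE)
      }
    }
    TRUE
  }
  set.seed(13)
  for (i in 1:25) {
    k <- sample(3:5, 1)
    means <- sample(0:6, k, replace = TRUE)
    df <- tibble::tibble(
      group = rep(paste0("g", 1:k), each = 6),
      value = rep(means, each = 6) + rnorm(6 * k, sd = 1))
    fit <- anova_tukey(df)
    expect_true(valid_letters(fit$letters, fit$tukey))
  }
})

test_that("tidiers return one-row glances and tidy tables", {
  df <- tibble::tibble(value = c(rnorm(5), rnorm(5, 4)),
                       group = rep(c("a", "b"), each = 5))
  fit <- anova_tukey(df)
  expect_tibble(tidy(fit))
  expect_equal(nrow(glance(fit)), 1)
  p <- pcoa(as.matrix(dist(matrix(rnorm(10), 5, 2))))
  expect_tibble(tidy(p))
  expect_equal(nrow(glance(p)), 1)
})
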