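# Distribution-comparison statistics: exact 1-d Wasserstein distances,
# principal coordinate analysis of a distance matrix, Kendall rank
# correlation with tie correction, and one-way ANOVA with Tukey HSD and
# compact letter display.

#' Exact 1-d Wasserstein distance between two samples
#'
#' Order-p Wasserstein distance between the empirical distributions,
#' computed exactly by integrating the difference of the two quantile
#' functions over the merged probability grid (reduces to the mean absolute
#' difference of sorted values for equal sample sizes at order 1).
#'
#' @param a,b Nonempty numeric samples.
#' @param order Wasserstein order p (default 1).
#' @return The distance (same units as the samples).
#' @export
wasserstein_1d <- function(a, b, order = 1) {
  stopifnot(length(a) > 0, length(b) > 0, order >= 1)
  a <- sort(a); b <- sort(b)
  na <- length(a); nb <- length(b)
  p <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  dp <- diff(c(0, p))
  # quantile function value on the interval ending at p[i]
  qa <- a[ceiling(p * na - 1e-12)]
  qb <- b[ceiling(p * nb - 1e-12)]
  sum(abs(qa - qb)^order * dp)^(1 / order)
}

#' Pairwise Wasserstein distance matrix
#'
#' @param samples Named list of numeric samples.
#' @param order Wasserstein order (default 1).
#' @return A symmetric matrix with zero diagonal.
#' @export
wasserstein_matrix <- function(samples, order = 1) {
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(names(samples), names(samples)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- d[j, i] <- wasserstein_1d(samples[[i]],
                                                      samples[[j]], order)
    }
  }
  d
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centres the squared distance matrix and eigendecomposes it,
#' keeping the top `k` positive-eigenvalue axes. Negative eigenvalues
#' (non-Euclidean structure) are reported, never clipped away silently.
#'
#' @param d A symmetric distance matrix (or `dist`).
#' @param k Number of axes to keep (default 2).
#' @return An object of class `pcoa_fit`: `points` tibble (`sample`,
#'   `axis1`, `axis2`, ...), `eigenvalues` (all, descending), `k`.
#' @export
pcoa <- function(d, k = 2) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(n >= 2, isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
  jj <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * jj %*% (dm^2) %*% jj
  ev <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(ev$values > max(ev$values[1], 0) * 1e-12)
  if (!length(pos) || ev$values[1] <= 0) {
    stop("no positive structure in the distance matrix", call. = FALSE)
  }
  k_use <- min(k, length(pos))
  pts <- ev$vectors[, seq_len(k_use), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(k_use)]), k_use)
  nm <- rownames(dm) %||% as.character(seq_len(n))
  colnames(pts) <- paste0("axis", seq_len(k_use))
  structure(list(points = dplyr::bind_cols(tibble::tibble(sample = nm),
                                           tibble::as_tibble(pts)),
                 eigenvalues = ev$values, k = k_use),
            class = "pcoa_fit")
}

#' @export
print.pcoa_fit <- function(x, ...) {
  ev <- x$eigenvalues
  rel <- ev[seq_len(x$k)] / sum(ev[ev > 0])
  cat("<pcoa_fit>", nrow(x$points), "samples,", x$k, "axes (",
      paste(sprintf("%.1f%%", 100 * rel), collapse = ", "),
      "of positive inertia)\n")
  invisible(x)
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Tau-b from concordant/discordant pair counts with the standard tie
#' corrections. The p-value is computed by exact permutation enumeration
#' for n <= 8 and by the normal approximation (with tie-corrected variance)
#' otherwise.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, neither constant.
#' @return A tibble with `statistic` (tau-b), `p.value`, `method`, `n`.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("tau undefined: constant sample", call. = FALSE)
  }
  tau <- tau_b_stat(x, y)
  if (n <= 8) {
    perms <- all_permutations(n)
    taus <- apply(perms, 1, function(p) tau_b_stat(x, y[p]))
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
    method <- "exact permutation"
  } else {
    # tie-corrected normal approximation on the S statistic
    cd <- concordance_counts(x, y)
    s <- cd$concordant - cd$discordant
    tx <- table(x); ty <- table(y)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- s / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble::tibble(statistic = tau, p.value = p, method = method, n = n)
}

#' @noRd
concordance_counts <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  list(concordant = sum(s > 0), discordant = sum(s < 0),
       tied_x = sum(dx[up] == 0), tied_y = sum(dy[up] == 0))
}

#' @noRd
tau_b_stat <- function(x, y) {
  cd <- concordance_counts(x, y)
  n <- length(x)
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(table(x), 2)); n2 <- sum(choose(table(y), 2))
  (cd$concordant - cd$discordant) / sqrt((n0 - n1) * (n0 - n2))
}

#' @noRd
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits `value ~ group`, runs Tukey's honest significant difference test on
#' all pairs, and assigns compact letters: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param data Data frame with one row per observation.
#' @param value,group Column names (strings).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `anova_tukey`: `f`, `p`, `tukey` tibble
#'   (`pair`, `diff`, `p.adj`), `letters` tibble (`group`, `mean`,
#'   `letters`), `alpha`.
#' @export
anova_tukey <- function(data, value = "value", group = "group",
                        alpha = 0.05) {
  df <- data.frame(value = as.numeric(data[[value]]),
                   group = factor(data[[group]]))
  stopifnot(nlevels(df$group) >= 2, all(table(df$group) >= 2))
  if (sum(tapply(df$value, df$group, stats::var)) == 0) {
    stop("degenerate: zero within-group variance in every group",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- tibble::tibble(pair = rownames(tk), diff = tk[, "diff"],
                          p.adj = tk[, "p adj"])
  means <- sort(tapply(df$value, df$group, mean), decreasing = TRUE)
  sig_pairs <- do.call(rbind, strsplit(tukey$pair[tukey$p.adj < alpha], "-",
                                       fixed = TRUE))
  letters_tb <- compact_letters(names(means), sig_pairs)
  letters_tb <- dplyr::left_join(
    letters_tb, tibble::tibble(group = names(means), mean = as.numeric(means)),
    by = "group")[, c("group", "mean", "letters")]
  structure(list(f = f, p = p, tukey = tukey, letters = letters_tb,
                 alpha = alpha, fit = fit),
            class = "anova_tukey")
}

# Insert-and-absorb compact letter display. `groups` are ordered (by
# decreasing mean); sig is a 2-column matrix of significantly different
# pairs (or NULL).
#' @noRd
compact_letters <- function(groups, sig) {
  cols <- list(groups)                 # start: everyone shares one letter
  if (!is.null(sig) && nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      a <- sig[r, 1]; b <- sig[r, 2]
      for (ci in rev(seq_along(cols))) {
        col <- cols[[ci]]
        if (a %in% col && b %in% col) {
          cols[[ci]] <- setdiff(col, a)
          cols[[length(cols) + 1]] <- setdiff(col, b)
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(cols))
      for (i in seq_along(cols)) {
        for (j in seq_along(cols)) {
          if (i != j && keep[j] &&
              all(cols[[i]] %in% cols[[j]]) &&
              (length(cols[[i]]) < length(cols[[j]]) || i > j)) {
            keep[i] <- FALSE; break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order columns by the best-ranked group they contain, then letter them
  first_rank <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first_rank)]
  lab <- vapply(groups, function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
           collapse = "")
  }, character(1))
  tibble::tibble(group = groups, letters = unname(lab))
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("<anova_tukey> F =", format(x$f, digits = 5),
      ", p =", format.pval(x$p, digits = 4), "\n")
  print(x$letters)
  invisible(x)
}
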