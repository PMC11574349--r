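# Statistical layer: pooled two-sample t-test, one-way ANOVA with Tukey HSD,
# exact noncentral-t sample size, and cross-embryo series averaging by
# modified Akima interpolation.

#' Pooled two-sample unpaired t-test
#'
#' Student's t with pooled variance and df = n_a + n_b - 2. Degenerate
#' zero-variance inputs are handled explicitly: equal means give t = 0,
#' p = 1; unequal means give p = 0 flagged `degenerate`.
#'
#' @param a,b numeric samples (>= 2 values each).
#' @return list(t, df, p, meanDiff, degenerate).
#' @examples
#' ttestPooled(c(0.23, 0.25, 0.17), c(0.84, 0.80, 1.14))$p  # 0.003
#' @export
ttestPooled <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  df <- length(a) + length(b) - 2L
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  md <- mean(a) - mean(b)
  if (sp2 <= 0) {
    if (md == 0)
      return(list(t = 0, df = df, p = 1, meanDiff = 0, degenerate = TRUE))
    return(list(t = sign(md) * Inf, df = df, p = 0, meanDiff = md,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       meanDiff = md, degenerate = FALSE)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups named (or unnamed) list of numeric vectors, k >= 2 groups
#'   with >= 2 values each.
#' @return list(F, dfBetween, dfWithin, pAnova, pairwise =
#'   data.frame(groupI, groupJ, meanDiff, pAdj)).
#' @export
anovaTukey <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(value = unlist(groups, use.names = FALSE),
                  group = factor(rep(names(groups),
                                     vapply(groups, length, 0L)),
                                 levels = names(groups)))
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  list(F = an[["F value"]][1], dfBetween = an[["Df"]][1],
       dfWithin = an[["Df"]][2], pAnova = an[["Pr(>F)"]][1],
       pairwise = data.frame(groupI = vapply(pairs, `[`, "", 2),
                             groupJ = vapply(pairs, `[`, "", 1),
                             meanDiff = -unname(tk[, "diff"]),
                             pAdj = unname(tk[, "p adj"]),
                             row.names = NULL))
}

#' Exact power of the two-sided two-sample t-test
#'
#' Noncentral-t power at level `alpha` for `n` per group, effect
#' |mu0 - mu1| / sd, with noncentrality delta * sqrt(n / 2) and
#' df = 2n - 2.
#'
#' @param n per-group sample size (>= 2).
#' @param delta standardized effect size |mu0 - mu1| / sd.
#' @param alpha significance level.
#' @return Power in [0, 1].
#' @export
powerTwoT <- function(n, delta, alpha = 0.05) {
  stopifnot(n >= 2, delta > 0)
  ncp <- delta * sqrt(n / 2)
  df <- 2 * n - 2
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
}

#' Minimal sample size for a two-sample t-test
#'
#' Smallest integer n per group whose exact noncentral-t power reaches the
#' requested power at the given significance level.
#'
#' @param mu0,mu1 the two group means (must differ).
#' @param sd common standard deviation (> 0).
#' @param power requested power.
#' @param alpha significance level.
#' @return list(nPerGroup, achievedPower).
#' @export
sampleSizeTwoT <- function(mu0, mu1, sd, power = 0.80, alpha = 0.05) {
  stopifnot(sd > 0, alpha > 0, alpha < power, power < 1)
  if (mu0 == mu1) stop("effect size is zero; no finite sample size exists")
  delta <- abs(mu0 - mu1) / sd
  for (n in 2:1000000) {
    pw <- powerTwoT(n, delta, alpha)
    if (pw >= power)
      return(list(nPerGroup = n, achievedPower = pw))
  }
  stop("sample size search exceeded 1e6")
}

#' Modified Akima cubic Hermite interpolation
#'
#' One-dimensional piecewise-cubic interpolation with the modified Akima
#' slope weights w = |delta_{i+1} - delta_i| + |delta_{i+1} + delta_i| / 2,
#' which damp the overshoot of the original Akima scheme near flat regions.
#'
#' @param x strictly increasing sample positions.
#' @param y sample values.
#' @param xout query positions within range(x).
#' @return Interpolated values at `xout`.
#' @export
makima <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n, all(diff(x) > 0),
            all(xout >= x[1] - 1e-12), all(xout <= x[n] + 1e-12))
  if (n == 2) {  # linear
    d <- (y[2] - y[1]) / (x[2] - x[1])
    return(y[1] + d * (xout - x[1]))
  }
  delta <- diff(y) / diff(x)                   # n - 1 interval slopes
  dd <- c(2 * delta[1] - delta[2],
          delta,
          2 * delta[n - 1] - delta[n - 2])
  dd <- c(2 * dd[1] - dd[2], dd, 2 * dd[length(dd)] - dd[length(dd) - 1])
  # dd[i + 2] == delta_i; knot i uses delta_{i-2}..delta_{i+1}
  s <- numeric(n)
  for (i in seq_len(n)) {
    d0 <- dd[i]; d1 <- dd[i + 1]; d2 <- dd[i + 2]; d3 <- dd[i + 3]
    w1 <- abs(d3 - d2) + abs(d3 + d2) / 2
    w2 <- abs(d1 - d0) + abs(d1 + d0) / 2
    s[i] <- if (w1 + w2 == 0) 0 else (w1 * d1 + w2 * d2) / (w1 + w2)
  }
  idx <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  h <- x[idx + 1L] - x[idx]
  tt <- (xout - x[idx]) / h
  h00 <- (1 + 2 * tt) * (1 - tt)^2
  h10 <- tt * (1 - tt)^2
  h01 <- tt^2 * (3 - 2 * tt)
  h11 <- tt^2 * (tt - 1)
  h00 * y[idx] + h10 * h * s[idx] + h01 * y[idx + 1L] + h11 * h * s[idx + 1L]
}

#' Average several time series on a common grid
#'
#' Resamples each series by modified Akima interpolation onto a common time
#' grid restricted to the interval covered by all series, then reports the
#' per-grid-point mean and standard error of the mean. This is how
#' normalized focus-count curves from several embryos are averaged.
#'
#' @param series list of data.frames/lists with elements (t, value), each
#'   with >= 4 points.
#' @param gridStepMin grid step in minutes; default: median time step across
#'   all series.
#' @return data.frame(gridTimeMin, mean, sem, nSeries).
#' @export
akimaAverage <- function(series, gridStepMin = NULL) {
  stopifnot(length(series) >= 2)
  tt <- lapply(series, function(s) as.numeric(s[[1]]))
  vv <- lapply(series, function(s) as.numeric(s[[2]]))
  if (any(vapply(tt, length, 0L) < 4))
    stop("every series needs at least 4 points")
  lo <- max(vapply(tt, min, 0)); hi <- min(vapply(tt, max, 0))
  if (hi <= lo) stop("series share no common time interval")
  if (is.null(gridStepMin))
    gridStepMin <- stats::median(unlist(lapply(tt, diff)))
  grid <- seq(lo, hi, by = gridStepMin)
  m <- vapply(seq_along(series), function(i) makima(tt[[i]], vv[[i]], grid),
              numeric(length(grid)))
  m <- matrix(m, nrow = length(grid))
  data.frame(gridTimeMin = grid,
             mean = rowMeans(m),
             sem = apply(m, 1, stats::sd) / sqrt(length(series)),
             nSeries = length(series))
}
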