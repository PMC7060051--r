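# Self-contained statistics used throughout the pipeline: rank correlation,
# signed-rank / rank-sum tests with z statistics, effect sizes, percentile
# bootstrap intervals, and Hartigan's dip test with a Monte-Carlo uniform null.
#
# These are implemented here (rather than wrapping stats::cor.test and
# stats::wilcox.test) because the reported quantities include normal-theory z
# values with continuity correction, exact small-sample enumeration, and a
# simulation-based dip p-value; the base-R equivalents serve as independent
# cross-checks in the test suite.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. For `n < 10` the two-sided
#' p-value is computed by exact enumeration over all permutations of one
#' variable's ranks; otherwise the usual t approximation is used.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho`, `p`, `n`, and `method`. `rho` is `NA` with a
#'   `degenerate = TRUE` flag when either input is constant.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE,
                method = "spearman"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < 10) {
    perms <- .permutations(n)
    rho_null <- as.vector(stats::cor(rx, matrix(ry[perms], nrow = n)))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "spearman-exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    method <- "spearman-t"
  }
  list(rho = rho, p = min(p, 1), n = n, degenerate = FALSE, method = method)
}

# all permutations of 1..n as an n x n! index matrix (n <= 9)
.permutations <- function(n) {
  if (n > 9) stop("exact permutation enumeration limited to n <= 9")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    idx <- c(seq_len(n)[-k])
    block <- matrix(idx[sub], nrow = n - 1L)
    out[, col + seq_len(ncol(sub))] <- rbind(rep(k, ncol(sub)), block)
    col <- col + ncol(sub)
  }
  out
}

#' Wilcoxon signed-rank and rank-sum tests
#'
#' Two-sided tests reporting both the p-value and the z statistic from the
#' normal approximation with tie correction and continuity correction. For the
#' paired (signed-rank) test with `n <= 12` non-zero differences the p-value is
#' replaced by exact enumeration over all sign assignments.
#'
#' @param a,b numeric samples; for `paired = TRUE` they must have equal length
#'   (`b` may be omitted to test `a` against zero).
#' @param paired logical; signed-rank test on `a - b` when `TRUE`, rank-sum
#'   test otherwise.
#' @return list with `p`, `z`, `statistic`, `n`, `method`, and a `degenerate`
#'   flag (all differences zero).
#' @export
wilcoxon_tests <- function(a, b = NULL, paired = TRUE) {
  if (paired) {
    if (is.null(b)) b <- rep(0, length(a))
    if (length(a) != length(b)) stop("paired samples must have equal length")
    d <- a - b
    d <- d[is.finite(d)]
    d <- d[d != 0]  # signed-rank convention: drop zero differences
    n <- length(d)
    if (n == 0) {
      return(list(p = NA_real_, z = NA_real_, statistic = NA_real_, n = 0,
                  degenerate = TRUE, method = "signed-rank"))
    }
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- if (V == mu) 0 else 0.5 * sign(V - mu)
    z <- if (sig2 > 0) (V - mu - cc) / sqrt(sig2) else 0
    if (n <= 12) {
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      Vnull <- as.vector(signs %*% r)
      p <- mean(abs(Vnull - mu) >= abs(V - mu) - 1e-12)
      method <- "signed-rank-exact"
    } else {
      p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
      method <- "signed-rank-normal"
    }
    list(p = min(p, 1), z = z, statistic = V, n = n, degenerate = FALSE,
         method = method)
  } else {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
    r <- rank(c(a, b))
    W <- sum(r[seq_len(n1)])
    mu <- n1 * (n1 + n2 + 1) / 2
    ties <- table(r)
    N <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
    z <- if (sig2 > 0) (W - mu - cc) / sqrt(sig2) else 0
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    list(p = min(p, 1), z = z, statistic = W, n = c(n1, n2),
         degenerate = sig2 == 0, method = "rank-sum-normal")
  }
}

#' Cohen's d effect size
#'
#' Paired version: mean of differences over the standard deviation of the
#' differences. Unpaired: difference of means over the pooled standard
#' deviation.
#'
#' @param a,b numeric samples.
#' @param paired logical.
#' @return scalar d (`NA` when the relevant standard deviation is zero).
#' @export
cohens_d <- function(a, b, paired = TRUE) {
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    d <- a - b
    s <- stats::sd(d)
    if (!is.finite(s) || s == 0) return(NA_real_)
    mean(d) / s
  } else {
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
    if (!is.finite(sp2) || sp2 == 0) return(NA_real_)
    (mean(a) - mean(b)) / sqrt(sp2)
  }
}

#' Percentile bootstrap interval
#'
#' Quantile interval by linear interpolation of order statistics (type-7
#' quantiles).
#'
#' @param samples numeric vector of bootstrap replicates (>= 100 advised for
#'   95 percent intervals).
#' @param level coverage level in (0, 1].
#' @return numeric length-2 vector, lower then upper.
#' @export
bootstrap_ci <- function(samples, level = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0) stop("empty sample")
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  a <- (1 - level) / 2
  unname(stats::quantile(samples, c(a, 1 - a), type = 7))
}

#' Hartigan's dip statistic
#'
#' Maximum-difference distance between the empirical distribution function and
#' the closest unimodal distribution function. Computed exactly by scanning
#' candidate modes: for a mode between consecutive order statistics the left
#' part of the fit must be convex and the right part concave, and the minimal
#' uniform band that admits such a fit is read off the greatest convex
#' minorant (left) and least concave majorant (right) of the empirical cdf's
#' step corners; a point mass at the mode itself is also allowed, which is the
#' configuration that matters for heavily tied samples.
#'
#' @param x numeric sample, `n >= 4` finite values.
#' @return the dip statistic, in `[0, 0.25]`; at least `1/(2n)` for samples of
#'   distinct values.
#' @export
dip_statistic <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4) stop("dip requires at least 4 finite values")
  ux <- unique(x)
  K <- length(ux)
  if (K == 1) return(0)
  cnt <- tabulate(match(x, ux), nbins = K)
  l <- cumsum(cnt) / n        # ecdf value at each unique point
  u <- c(0, l[-K])            # ecdf left limit at each unique point

  # Forward pass: incremental greatest convex minorant of (ux, u).
  # devL[k] = l[k] - gcm(ux[k]); L[m] = max(devL[1:m]), Lp[m] = max(devL[1:(m-1)]).
  devL <- numeric(K)
  L <- numeric(K); Lp <- numeric(K)
  hull <- integer(K); hl <- 0L
  for (m in seq_len(K)) {
    while (hl >= 2L) {
      i <- hull[hl - 1L]; j <- hull[hl]
      # pop j if it lies above the chord i -> m
      if ((u[j] - u[i]) * (ux[m] - ux[i]) >= (u[m] - u[i]) * (ux[j] - ux[i])) {
        hl <- hl - 1L
      } else break
    }
    if (hl >= 1L) {
      i <- hull[hl]
      idx <- i:m
      g <- u[i] + (u[m] - u[i]) * (ux[idx] - ux[i]) / (ux[m] - ux[i])
      devL[idx] <- pmax(devL[idx], l[idx] - g)
    }
    devL[m] <- max(devL[m], l[m] - u[m])
    hl <- hl + 1L; hull[hl] <- m
    Lp[m] <- if (m > 1) max(devL[seq_len(m - 1L)]) else 0
    L[m] <- max(Lp[m], devL[m])
  }

  # Backward pass: least concave majorant of (ux, l) from the right.
  devR <- numeric(K)
  R <- numeric(K); Rp <- numeric(K)
  hull <- integer(K); hl <- 0L
  for (m in rev(seq_len(K))) {
    while (hl >= 2L) {
      i <- hull[hl - 1L]; j <- hull[hl]
      if ((l[j] - l[i]) * (ux[m] - ux[i]) >= (l[m] - l[i]) * (ux[j] - ux[i])) {
        hl <- hl - 1L
      } else break
    }
    if (hl >= 1L) {
      i <- hull[hl]
      idx <- m:i
      g <- l[i] + (l[m] - l[i]) * (ux[idx] - ux[i]) / (ux[m] - ux[i])
      devR[idx] <- pmax(devR[idx], g - u[idx])
    }
    devR[m] <- max(devR[m], l[m] - u[m])
    hl <- hl + 1L; hull[hl] <- m
    Rp[m] <- if (m < K) max(devR[(m + 1L):K]) else 0
    R[m] <- max(Rp[m], devR[m])
  }

  # Mode in a gap (x_j, x_{j+1}): band must cover L(j) on the left and R(j+1)
  # on the right. Mode at a point (atom allowed there): the point's own jump
  # escapes the band, leaving Lp and Rp.
  gap <- pmax(c(0, L), c(R, 0))
  point <- pmax(Lp, Rp)
  min(c(gap, point)) / 2
}

#' Hartigan's dip test with Monte-Carlo uniform null
#'
#' The dip statistic is invariant to monotone transforms of the sample, so the
#' null distribution under any unimodal hypothesis is bounded by the uniform
#' null; the p-value is the fraction of `n_null` uniform samples of the same
#' size whose dip is at least the observed one.
#'
#' @param x numeric sample (`n >= 4`).
#' @param n_null number of uniform null simulations.
#' @param seed integer seed for the null simulation.
#' @param null_dips optional precomputed vector of null dip statistics for
#'   samples of `length(x)`; when supplied, `n_null` and `seed` are ignored.
#' @return object of class `dip_result`: list with `dip`, `p`, `n`, `n_null`,
#'   `seed`.
#' @export
hartigan_dip <- function(x, n_null = 1000, seed = 1, null_dips = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("dip test requires at least 4 finite values")
  d <- dip_statistic(x)
  if (is.null(null_dips)) {
    null_dips <- dip_null_distribution(n, n_null, seed)
  }
  # add-one Monte-Carlo convention so the resolution is 1/(n_null + 1)
  p <- (1 + sum(null_dips >= d - 1e-15)) / (length(null_dips) + 1)
  structure(list(dip = d, p = p, n = n, n_null = length(null_dips),
                 seed = seed),
            class = "dip_result")
}

#' Null distribution of the dip statistic for uniform samples
#'
#' @param n sample size.
#' @param n_null number of simulations.
#' @param seed integer seed.
#' @return vector of `n_null` dip statistics.
#' @export
dip_null_distribution <- function(n, n_null = 1000, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vapply(seq_len(n_null), function(i) dip_statistic(stats::runif(n)),
         numeric(1))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigan dip test: dip = %.4f, p = %.4g (n = %d, %d null sims)\n",
              x$dip, x$p, x$n, x$n_null))
  invisible(x)
}
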