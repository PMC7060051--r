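# Independent brute-force oracle for the dip statistic on small samples of
# distinct values: for every candidate mode placement (between consecutive
# order statistics, or an atom at an order statistic) the smallest uniform
# band admitting a nondecreasing convex-then-concave fit to the empirical
# cdf is found as a linear program (boot::simplex); the dip is the minimum
# over placements.
dip_lp_oracle_permode <- function(x) {
  x <- sort(x); n <- length(x)
  l <- (1:n) / n
  u <- (0:(n - 1)) / n
  solve_mode <- function(left_idx, right_idx, left_end_band, right_start_band) {
    nl <- length(left_idx); nr <- length(right_idx)
    nv <- nl + nr + 1
    eps_col <- nv
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    row <- function(cols, vals) { r <- numeric(nv); r[cols] <- vals; r }
    for (a in seq_len(nl)) {
      k <- left_idx[a]
      ub <- if (a == nl && !is.null(left_end_band)) left_end_band else u[k]
      lb <- if (a == nl && !is.null(left_end_band)) left_end_band else l[k]
      A1 <- rbind(A1, row(c(a, eps_col), c(1, -1))); b1 <- c(b1, ub)
      A2 <- rbind(A2, row(c(a, eps_col), c(1, 1)));  b2 <- c(b2, lb)
    }
    for (a in seq_len(nr)) {
      k <- right_idx[a]
      ub <- if (a == 1 && !is.null(right_start_band)) right_start_band else u[k]
      lb <- if (a == 1 && !is.null(right_start_band)) right_start_band else l[k]
      A1 <- rbind(A1, row(c(nl + a, eps_col), c(1, -1))); b1 <- c(b1, ub)
      A2 <- rbind(A2, row(c(nl + a, eps_col), c(1, 1)));  b2 <- c(b2, lb)
    }
    if (nl >= 3) for (a in 1:(nl - 2)) {
      xa <- x[left_idx[a]]; xb <- x[left_idx[a + 1]]; xc <- x[left_idx[a + 2]]
      A2 <- rbind(A2, row(c(a, a + 1, a + 2),
                          c(xc - xb, -(xc - xa), xb - xa))); b2 <- c(b2, 0)
    }
    if (nr >= 3) for (a in 1:(nr - 2)) {
      xa <- x[right_idx[a]]; xb <- x[right_idx[a + 1]]; xc <- x[right_idx[a + 2]]
      A1 <- rbind(A1, row(nl + c(a, a + 1, a + 2),
                          c(xc - xb, -(xc - xa), xb - xa))); b1 <- c(b1, 0)
    }
    if (nl >= 2) for (a in 1:(nl - 1)) {
      A2 <- rbind(A2, row(c(a, a + 1), c(-1, 1))); b2 <- c(b2, 0)
    }
    if (nr >= 2) for (a in 1:(nr - 1)) {
      A2 <- rbind(A2, row(nl + c(a, a + 1), c(-1, 1))); b2 <- c(b2, 0)
    }
    if (nl >= 1 && nr >= 1) {
      A1 <- rbind(A1, row(c(nl, nl + 1), c(1, -1))); b1 <- c(b1, 0)
    }
    obj <- numeric(nv); obj[eps_col] <- 1
    res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         maxi = FALSE)
    if (res$solved != 1) return(Inf)
    res$value
  }
  gap <- sapply(0:n, function(j) {
    li <- if (j >= 1) 1:j else integer(0)
    ri <- if (j < n) (j + 1):n else integer(0)
    solve_mode(li, ri, NULL, NULL)
  })
  point <- sapply(1:n, function(m) solve_mode(1:m, m:n, u[m], l[m]))
  list(gap = gap, point = point)
}


dip_lp_oracle <- function(x) {
  o <- dip_lp_oracle_permode(x)
  min(c(o$gap, o$point))
}
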