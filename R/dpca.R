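# Demixed principal component analysis with a single categorical factor
# (impending target direction: toward vs away from preferred). The
# mean-centered population matrix is decomposed into a condition-independent
# (time) marginalization and a condition-dependent (direction x time)
# marginalization, and a low-rank encoder/decoder pair is fit per
# marginalization by reduced-rank regression via the singular value
# decomposition.

#' Marginalize a population matrix over its condition factor
#'
#' Decomposes the row-centered input into `X_time` (condition average,
#' repeated across conditions), `X_direction` (per-condition mean minus the
#' condition average), and `X_noise` (residual; identically zero for
#' trial-averaged input). The three parts sum to the centered input exactly.
#'
#' @param X units x (conditions x time) matrix, columns ordered
#'   time-within-condition.
#' @param condition_labels vector of length `ncol(X)` giving each column's
#'   condition; every condition must have the same number of columns, in the
#'   same time order.
#' @return list with `X_time`, `X_direction`, `X_noise`, `X_centered`,
#'   `condition_labels`.
#' @export
dpca_marginalize <- function(X, condition_labels) {
  if (length(condition_labels) != ncol(X)) {
    stop("condition_labels must have one entry per column of X")
  }
  f <- factor(condition_labels, levels = unique(condition_labels))
  counts <- table(f)
  if (length(unique(counts)) != 1) {
    stop("unbalanced condition lengths: all conditions need equal columns")
  }
  Xc <- X - rowMeans(X)
  nc <- nlevels(f)
  nt <- counts[[1]]
  idx <- split(seq_len(ncol(X)), f)
  avg <- matrix(0, nrow(X), nt)
  for (ii in idx) avg <- avg + Xc[, ii, drop = FALSE]
  avg <- avg / nc
  Xt <- Xc; Xd <- Xc
  for (ii in idx) {
    Xt[, ii] <- avg
    Xd[, ii] <- Xc[, ii, drop = FALSE] - avg
  }
  list(X_time = Xt, X_direction = Xd, X_noise = Xc - Xt - Xd,
       X_centered = Xc, condition_labels = f)
}

#' Fit demixed PCA by reduced-rank regression
#'
#' For each marginalization `X_phi`, finds encoder `F` and decoder `D`
#' minimizing `||X_phi - F D X||^2` (plus an optional ridge term on the
#' regression): the least-squares map is projected onto its leading singular
#' subspace. Components from both marginalizations are pooled and ordered by
#' explained variance; each component's variance splits exactly into
#' direction-independent and direction-dependent shares because the
#' marginalizations are orthogonal.
#'
#' With `regularization = 0` the regression uses the minimum-norm
#' least-squares solution (pseudoinverse), which is well defined for the
#' rank-deficient trial-averaged matrices this analysis runs on.
#'
#' @param X units x (conditions x time) matrix.
#' @param condition_labels as in [dpca_marginalize()].
#' @param n_components total number of components to keep (default 10).
#' @param regularization ridge weight (default 0).
#' @return object of class `dpca_model`: per-component `encoder` (units x k),
#'   `decoder` (k x units), `marginalization` ("time" or "direction"),
#'   `variance` (per component), `variance_shares` (k x 2), `total_variance`,
#'   plus the marginalization matrices.
#' @export
fit_dpca <- function(X, condition_labels, n_components = 10,
                     regularization = 0) {
  if (n_components < 1) stop("n_components must be >= 1")
  mg <- dpca_marginalize(X, condition_labels)
  Xc <- mg$X_centered
  if (all(Xc == 0)) stop("input has no variance")
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * sv$d[1] * .Machine$double.eps
  r <- sum(sv$d > tol)
  Ur <- sv$u[, seq_len(r), drop = FALSE]
  dr <- sv$d[seq_len(r)]
  # A_phi = X_phi %*% pinv-ridge(X); in the SVD basis:
  # X_phi V = (A_phi U) diag(d), so A_phi = X_phi V diag(d/(d^2+lambda)) U'
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  comps <- list()
  for (phi in c("time", "direction")) {
    Xp <- if (phi == "time") mg$X_time else mg$X_direction
    if (all(Xp == 0)) next
    A <- Xp %*% Vr %*% (dr / (dr^2 + regularization) * t(Ur))
    M <- A %*% Xc
    sm <- svd(M)
    kp <- min(n_components, sum(sm$d > max(sm$d[1], tol) * 1e-12))
    for (c in seq_len(kp)) {
      f <- sm$u[, c]
      d <- as.vector(t(f) %*% A)
      z <- as.vector(t(d) %*% Xc)  # component time course over all columns
      vt <- sum((d %*% mg$X_time)^2)
      vd <- sum((d %*% mg$X_direction)^2)
      comps[[length(comps) + 1L]] <- list(
        f = f, d = d, marginalization = phi,
        variance = sum(z^2), shares = c(time = vt, direction = vd))
    }
  }
  ord <- order(vapply(comps, function(cc) cc$variance, numeric(1)),
               decreasing = TRUE)
  comps <- comps[ord][seq_len(min(n_components, length(comps)))]
  structure(list(
    encoder = vapply(comps, function(cc) cc$f, numeric(nrow(X))),
    decoder = t(vapply(comps, function(cc) cc$d, numeric(nrow(X)))),
    marginalization = vapply(comps, function(cc) cc$marginalization,
                             character(1)),
    variance = vapply(comps, function(cc) cc$variance, numeric(1)),
    variance_shares = t(vapply(comps, function(cc) cc$shares, numeric(2))),
    total_variance = sum(Xc^2),
    marginalizations = mg,
    regularization = regularization),
    class = "dpca_model")
}

#' Project a population matrix onto a demixed component
#'
#' Applies the component's decoder row and returns the time course per
#' condition.
#'
#' @param model a `dpca_model`.
#' @param X matrix with the same unit rows and column layout used in the fit
#'   (defaults to the fitted centered matrix).
#' @param component_index which component.
#' @return conditions x time matrix of projections.
#' @export
dpca_project <- function(model, X = NULL, component_index = 1) {
  k <- length(model$variance)
  if (component_index < 1 || component_index > k) {
    stop(sprintf("component_index must be in 1..%d", k))
  }
  mg <- model$marginalizations
  if (is.null(X)) X <- mg$X_centered
  z <- as.vector(model$decoder[component_index, ] %*% X)
  f <- mg$condition_labels
  do.call(rbind, lapply(split(z, f), function(v) v))
}

#' @export
print.dpca_model <- function(x, ...) {
  vf <- 100 * x$variance / x$total_variance
  cat(sprintf("dpca_model: %d components (%s); top variance %%: %s\n",
              length(x$variance),
              paste(x$marginalization[seq_len(min(3, length(vf)))],
                    collapse = ", "),
              paste(sprintf("%.1f", vf[seq_len(min(3, length(vf)))]),
                    collapse = ", ")))
  invisible(x)
}
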