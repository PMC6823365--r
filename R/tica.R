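#' Fit a tICA model
#'
#' Time-lagged independent component analysis: builds the instantaneous
#' covariance C and the symmetrized time-lagged covariance C_TL(tau) from
#' mean-free features, and solves the generalized eigenproblem
#' C_TL V = C V Lambda by whitening with small-eigenvalue truncation.
#' Multiple trajectories are pooled by summing (t, t + tau) pairs per
#' trajectory, never across trajectory boundaries. Eigenpairs are sorted by
#' descending eigenvalue with a deterministic sign convention (the
#' largest-magnitude loading of each eigenvector is positive).
#'
#' @param series T x d numeric matrix, or a list of such matrices (one per
#'   trajectory / protomer).
#' @param tau lag time in frames.
#' @param truncation relative C-eigenvalue cutoff for whitening (drop
#'   directions with eigenvalue < `truncation` times the largest).
#' @return object of class `tica_model`: `mean`, `C`, `C_TL`, `tau`,
#'   `eigenvalues`, `eigenvectors` (columns, C-orthonormal), `n_samples`,
#'   `n_pairs`.
#' @export
fit_tica <- function(series, tau, truncation = 1e-8) {
  if (is.matrix(series) || is.data.frame(series)) series <- list(as.matrix(series))
  series <- lapply(series, as.matrix)
  d <- ncol(series[[1]])
  stopifnot(d >= 1, tau >= 1)
  for (s in series) {
    if (nrow(s) <= tau) stop("each trajectory must have T > tau frames")
    if (ncol(s) != d) stop("trajectories differ in dimension")
  }
  n_tot <- sum(vapply(series, nrow, 1L))
  mu <- colSums(do.call(rbind, lapply(series, colSums)) ) / n_tot
  C <- matrix(0, d, d); Ctl <- matrix(0, d, d); n_pairs <- 0L
  for (s in series) {
    X <- sweep(s, 2, mu)
    C <- C + crossprod(X)
    T_i <- nrow(X)
    A <- X[1:(T_i - tau), , drop = FALSE]
    B <- X[(1 + tau):T_i, , drop = FALSE]
    Ctl <- Ctl + crossprod(A, B)
    n_pairs <- n_pairs + (T_i - tau)
  }
  C <- C / n_tot
  Ctl <- Ctl / n_pairs
  Ctl <- (Ctl + t(Ctl)) / 2
  ec <- eigen(C, symmetric = TRUE)
  keep <- ec$values >= truncation * ec$values[1]
  if (!any(keep)) stop("covariance rank-deficient: no directions survive truncation")
  W <- ec$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ec$values[keep]), sum(keep))
  M <- crossprod(W, Ctl %*% W)
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  V <- W %*% em$vectors
  # deterministic sign: largest-|loading| positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(mean = mu, C = C, C_TL = Ctl, tau = tau,
                 eigenvalues = em$values, eigenvectors = V,
                 n_samples = n_tot, n_pairs = n_pairs,
                 feature_names = colnames(series[[1]])),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> d=%d tau=%d n=%d\n eigenvalues: %s\n",
              length(x$mean), x$tau, x$n_samples,
              paste(sprintf("%.4f", x$eigenvalues), collapse = " ")))
  invisible(x)
}

#' Project features onto tICA coordinates
#'
#' @param model a fitted `tica_model`.
#' @param series T x d matrix (or list; concatenated in order).
#' @param m number of leading independent components (default 2).
#' @return T x m matrix of tIC coordinates.
#' @export
project_tica <- function(model, series, m = 2) {
  if (is.list(series) && !is.data.frame(series)) {
    series <- do.call(rbind, lapply(series, as.matrix))
  }
  series <- as.matrix(series)
  if (ncol(series) != length(model$mean)) {
    stop(sprintf("series has %d features; model expects %d",
                 ncol(series), length(model$mean)))
  }
  m <- min(m, ncol(model$eigenvectors))
  X <- sweep(series, 2, model$mean)
  Y <- X %*% model$eigenvectors[, seq_len(m), drop = FALSE]
  colnames(Y) <- paste0("tIC", seq_len(m))
  Y
}

#' Implied timescale of a tICA eigenvalue
#'
#' `tau / (-ln lambda)` in frame units; the relaxation time of the slow mode
#' associated with the component.
#'
#' @param model a `tica_model`.
#' @param i component index.
#' @export
implied_timescale <- function(model, i = 1) {
  lam <- model$eigenvalues[i]
  if (lam <= 0 || lam >= 1) return(NA_real_)
  model$tau / (-log(lam))
}

#' Cluster tICA coordinates into microstates
#'
#' k-means with k-means++ initialization under a fixed seed; assignments are
#' deterministic given the seed. Populations are per-cluster frame
#' fractions; clusters are relabelled by descending population.
#'
#' @param coords T x m tIC coordinate matrix.
#' @param k number of microstates (>= 2).
#' @param seed RNG seed for the initialization.
#' @param iter_max Lloyd iteration cap.
#' @return object of class `microstate_model`: `centers`, `assignments`,
#'   `populations`, `withinss`, `seed`.
#' @export
cluster_microstates <- function(coords, k = 8, seed = 1, iter_max = 100) {
  coords <- as.matrix(coords)
  if (k < 2) stop("k must be >= 2")
  if (nrow(coords) < k) stop("need at least k frames")
  init <- with_private_seed(seed, .kmeanspp_init(coords, k))
  km <- suppressWarnings(
    stats::kmeans(coords, centers = init, iter.max = iter_max,
                  algorithm = "Lloyd"))
  ord <- order(tabulate(km$cluster, k), decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignments <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- NULL
  pops <- tabulate(assignments, k) / nrow(coords)
  structure(list(centers = centers, assignments = assignments,
                 populations = pops, withinss = sum(km$withinss),
                 seed = seed, k = k),
            class = "microstate_model")
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' 2D density landscape of tICA coordinates
#'
#' Histogram on a regular grid, normalized to probabilities, with the
#' negative-log density (a free-energy-like surface in kT units) masked at
#' empty bins.
#'
#' @param coords T x 2 coordinate matrix.
#' @param bins number of bins per axis (length 1 or 2).
#' @param limits optional list of x and y ranges.
#' @return list with `x`, `y` (bin centres), `p` (probability matrix,
#'   sums to 1) and `neglogp` (NA where p = 0).
#' @export
density_landscape <- function(coords, bins = 80, limits = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, all(is.finite(coords)))
  bins <- rep_len(bins, 2)
  rx <- if (is.null(limits)) range(coords[, 1]) else limits[[1]]
  ry <- if (is.null(limits)) range(coords[, 2]) else limits[[2]]
  bx <- seq(rx[1], rx[2], length.out = bins[1] + 1)
  by <- seq(ry[1], ry[2], length.out = bins[2] + 1)
  ix <- pmin(pmax(findInterval(coords[, 1], bx, all.inside = TRUE), 1), bins[1])
  iy <- pmin(pmax(findInterval(coords[, 2], by, all.inside = TRUE), 1), bins[2])
  cnt <- matrix(tabulate(ix + (iy - 1L) * bins[1], bins[1] * bins[2]),
                bins[1], bins[2])
  p <- cnt / sum(cnt)
  nlp <- -log(p)
  nlp[!is.finite(nlp)] <- NA_real_
  list(x = (bx[-1] + bx[-length(bx)]) / 2,
       y = (by[-1] + by[-length(by)]) / 2,
       p = p, neglogp = nlp)
}
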