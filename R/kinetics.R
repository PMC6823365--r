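#' Scrambling-assay kinetic parameters
#'
#' Parameters of the dithionite scrambling assay model: `f0` the fraction of
#' protein-free liposomes, `alpha`/`beta` the forward and backward
#' scrambling rate constants (1/s), `gamma` the effective dithionite
#' reduction rate (`gamma = gamma_prime * dithionite_conc` when given as a
#' second-order constant), and `L_i_PF` the inner-leaflet NBD fraction in
#' protein-free liposomes.
#'
#' @param f0 fraction of protein-free liposomes, in [0, 1].
#' @param alpha,beta scrambling rate constants, 1/s (>= 0).
#' @param gamma effective dithionite rate, 1/s; either given directly or
#'   derived from `gamma_prime * dithionite_conc`.
#' @param gamma_prime second-order dithionite rate constant, 1/(M s).
#' @param dithionite_conc dithionite concentration, M.
#' @param L_i_PF inner-leaflet fraction, in [0, 1].
#' @return list of class `scrambling_params`.
#' @export
scrambling_params <- function(f0, alpha, beta, gamma = NULL,
                              gamma_prime = NULL, dithionite_conc = NULL,
                              L_i_PF = 0.5) {
  if (is.null(gamma)) {
    if (is.null(gamma_prime) || is.null(dithionite_conc)) {
      stop("supply gamma, or gamma_prime and dithionite_conc")
    }
    gamma <- gamma_prime * dithionite_conc
  } else if (!is.null(gamma_prime) && !is.null(dithionite_conc)) {
    if (abs(gamma - gamma_prime * dithionite_conc) > 1e-9 * max(gamma, 1)) {
      stop("gamma inconsistent with gamma_prime * dithionite_conc")
    }
  }
  stopifnot(f0 >= 0, f0 <= 1, alpha >= 0, beta >= 0, gamma > 0,
            L_i_PF >= 0, L_i_PF <= 1)
  structure(list(f0 = f0, alpha = alpha, beta = beta, gamma = gamma,
                 gamma_prime = gamma_prime,
                 dithionite_conc = dithionite_conc, L_i_PF = L_i_PF),
            class = "scrambling_params")
}

#' Eigenstructure of the scrambling kinetics
#'
#' The two (non-positive) relaxation rates of the coupled
#' reduction/flipping system and the composite denominator `D`:
#' `lambda_{1,2} = -((a+b+g) -/+ sqrt((a+b+g)^2 - 4 a g)) / 2`,
#' `D = (lambda1 + a)(lambda2 + b + g) - a b`. Identities
#' `lambda1 lambda2 = a g` and `lambda1 + lambda2 = -(a+b+g)` hold exactly.
#'
#' @param alpha,beta,gamma rate constants, 1/s.
#' @return list with `lambda1`, `lambda2`, `D`, `disc` (the discriminant).
#' @export
scrambling_eigen <- function(alpha, beta, gamma) {
  s <- alpha + beta + gamma
  disc2 <- s^2 - 4 * alpha * gamma
  disc <- sqrt(max(disc2, 0))
  lambda2 <- -(s + disc) / 2
  # lambda1 via the product identity: numerically stable for small alpha
  lambda1 <- if (lambda2 != 0) -(alpha * gamma) / (-lambda2) else 0
  D <- (lambda1 + alpha) * (lambda2 + beta + gamma) - alpha * beta
  list(lambda1 = lambda1, lambda2 = lambda2, D = D, disc = disc)
}

#' Scrambling-assay forward model
#'
#' Total normalized fluorescence after dithionite addition: the protein-free
#' pool decays as `L + (1 - L) exp(-gamma t)`; the proteoliposome pool
#' follows the biexponential solution of the coupled outer-leaflet
#' reduction / transbilayer flipping system, with rates and denominator
#' from [scrambling_eigen()]. Equivalent to the two-leaflet ODE
#' `dF_out/dt = -(gamma + beta) F_out + alpha F_in`,
#' `dF_in/dt = beta F_out - alpha F_in` started from the scrambling steady
#' state `(alpha, beta)/(alpha + beta)` and mixed with the protein-free pool
#' by `f0`. `F(0) = 1` for every valid parameter set.
#'
#' Degenerate branches: for `alpha < eps_deg` the analytic limit
#' `f0 (L + (1 - L) e^{-gamma t}) + (1 - f0)` is used (as alpha -> 0 the
#' proteoliposome pool starts all-inner and is never reduced; the printed
#' closed form divides by `D (alpha + beta) -> 0` there). For
#' `beta < eps_deg` the pool starts all-outer and D again vanishes
#' (`lambda1 = -min(alpha, gamma)` exactly); the limit is a single
#' `e^{-gamma t}` decay. A repeated eigenvalue (discriminant ~ 0) is
#' handled by the defective-matrix solution `e^{lambda t}(1 + ...t)`.
#'
#' @param t time(s) since dithionite addition, s (vectorized).
#' @param params a [scrambling_params()] object.
#' @param eps_deg alpha threshold for the degenerate branch, 1/s.
#' @return normalized fluorescence at `t`.
#' @export
ftot <- function(t, params, eps_deg = 1e-8) {
  if (any(t < 0)) stop("negative time")
  f0 <- params$f0; a <- params$alpha; b <- params$beta
  g <- params$gamma; L <- params$L_i_PF
  pf <- f0 * (L + (1 - L) * exp(-g * t))
  if (a < eps_deg) {
    return(pf + (1 - f0))
  }
  if (b < eps_deg) {
    # beta -> 0: lambda1 = -min(a, g) exactly and D = 0; the pool starts
    # all-outer (steady state (1, 0)) and is quenched as a single exponential
    return(pf + (1 - f0) * exp(-g * t))
  }
  eg <- scrambling_eigen(a, b, g)
  s <- a + b + g
  if (eg$disc < 1e-7 * s) {
    # repeated root: x(t) = e^{lam t} (I + (A - lam I) t) x0, summed
    lam <- -s / 2
    x0 <- c(a, b) / (a + b)
    A <- matrix(c(-(g + b), b, a, -a), 2, 2)
    xt <- vapply(t, function(tt) {
      v <- (diag(2) + (A - diag(lam, 2)) * tt) %*% x0
      sum(v)
    }, numeric(1))
    return(pf + (1 - f0) * exp(lam * t) * xt)
  }
  if (abs(eg$D) < .Machine$double.eps * s^2) {
    stop("degenerate denominator D = 0 with alpha above the epsilon switch")
  }
  l1 <- eg$lambda1; l2 <- eg$lambda2; D <- eg$D
  pro <- (a * (l2 + g) * (l1 + a + b) * exp(l1 * t) +
            l1 * b * (l2 + a + b + g) * exp(l2 * t)) / (D * (a + b))
  pf + (1 - f0) * pro
}

#' Simulate a fluorescence trace
#'
#' [ftot()] evaluated at `times` plus i.i.d. Gaussian noise, packaged with
#' metadata as a `gf_trace`.
#'
#' @param params a [scrambling_params()].
#' @param times sampling times, s, strictly increasing.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return object of class `gf_trace`: `times`, `values`, `metadata`.
#' @export
simulate_trace <- function(params, times, noise_sd = 0, seed = NULL) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  f <- ftot(times, params)
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) with_private_seed(seed, rnorm(length(times), sd = noise_sd))
    else rnorm(length(times), sd = noise_sd)
  } else 0
  structure(list(times = times, values = f + noise,
                 metadata = list(params = params, noise_sd = noise_sd,
                                 seed = seed, sampling_rate_hz =
                                   if (length(times) > 1) 1 / stats::median(diff(times)) else NA,
                                 dithionite_time = 0)),
            class = "gf_trace")
}

#' Read / write traces as CSV
#'
#' Two-column CSV `time_s, fluorescence`, comment lines prefixed `#`.
#' @param path file path.
#' @rdname trace_io
#' @export
read_trace <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "fluorescence") %in% names(tab))) {
    stop("trace CSV must have columns time_s, fluorescence")
  }
  structure(list(times = tab$time_s, values = tab$fluorescence,
                 metadata = list(file = path, dithionite_time = 0)),
            class = "gf_trace")
}

#' @param trace a `gf_trace`.
#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times,
                              fluorescence = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Fit the scrambling model to a trace
#'
#' Bounded nonlinear least squares over (f0, alpha, beta) with `L_i_PF` and
#' `gamma` fixed (experimentally determined), multi-start (best SSE kept).
#' Rates are optimized on a log scale. An identifiability note is attached
#' when the fitted alpha saturates the regime the quenching rate can
#' resolve (alpha >= 5 gamma): in that limit scrambling is faster than
#' reduction and only a lower bound on the rate constants is meaningful.
#'
#' @param trace a `gf_trace` (normalized fluorescence; if the metadata
#'   carries a pre-dithionite segment the trace is normalized to its mean).
#' @param L_i_PF fixed inner-leaflet fraction.
#' @param gamma fixed dithionite rate, 1/s.
#' @param bounds list with elements `f0`, `alpha`, `beta` (length-2 ranges).
#' @param n_starts number of optimizer starts.
#' @param seed RNG seed for the starts.
#' @param leak_rate optional protein-free leak rate L (1/s) folded into the
#'   effective quench rate as `gamma + leak_rate` (off by default: the leak
#'   is normally orders of magnitude below protein-mediated scrambling and
#'   is reported, not modelled).
#' @return object of class `fit_result`: `estimates` (f0, alpha, beta),
#'   `fixed`, `sse`, `converged`, `identifiability_warning`, `n_starts`.
#' @export
fit_scrambling <- function(trace, L_i_PF, gamma,
                           bounds = list(f0 = c(0, 1),
                                         alpha = c(1e-6, 10),
                                         beta = c(1e-6, 10)),
                           n_starts = 8, seed = 1, leak_rate = 0) {
  tt <- trace$times; yy <- trace$values
  dt0 <- trace$metadata$dithionite_time
  if (!is.null(dt0) && dt0 > 0) {
    pre <- yy[tt < dt0]
    if (length(pre)) yy <- yy / mean(pre)
    keep <- tt >= dt0
    tt <- tt[keep] - dt0; yy <- yy[keep]
    .gf_log("trace normalized to the pre-dithionite mean")
  } else {
    .gf_log("trace assumed pre-normalized (no dithionite_time metadata)")
  }
  gamma <- gamma + leak_rate
  if (max(tt) < 5 / gamma) {
    warning("trace covers < 5/gamma after dithionite addition: slow-fit risk")
  }
  # smooth bounded parameterization: f0 and the log-rates each mapped to
  # their box through a scaled logistic, so no optimizer step can stall on
  # a hard bound (L-BFGS-B gets trapped in a spurious f0 = 1 corner there)
  lo <- c(bounds$f0[1], log(bounds$alpha[1]), log(bounds$beta[1]))
  hi <- c(bounds$f0[2], log(bounds$alpha[2]), log(bounds$beta[2]))
  to_box <- function(q) lo + (hi - lo) * stats::plogis(q)
  from_box <- function(p) stats::qlogis(pmin(pmax((p - lo) / (hi - lo),
                                                  1e-9), 1 - 1e-9))
  sse_fun <- function(q) {
    p <- to_box(q)
    pars <- scrambling_params(f0 = p[1], alpha = exp(p[2]), beta = exp(p[3]),
                              gamma = gamma, L_i_PF = L_i_PF)
    sum((ftot(tt, pars) - yy)^2)
  }
  starts <- with_private_seed(seed, {
    s <- matrix(stats::rnorm(3 * n_starts, sd = 1.5), ncol = 3)
    s[1, ] <- from_box(c(0.3, log(0.01), log(0.01)))  # canonical start
    s
  })
  best <- NULL; diags <- character(0)
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch({
      o1 <- stats::optim(starts[i, ], sse_fun, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
      stats::optim(o1$par, sse_fun, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14))
    }, error = function(e) NULL)
    if (is.null(o)) { diags <- c(diags, sprintf("start %d: error", i)); next }
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) {
    stop("all optimizer starts failed: ", paste(diags, collapse = "; "))
  }
  par <- to_box(best$par)
  est <- c(f0 = par[1], alpha = exp(par[2]), beta = exp(par[3]))
  ident <- est[["alpha"]] >= 5 * gamma
  if (ident) {
    .gf_log("alpha >= 5*gamma: rate constants at/beyond the resolvable regime")
  }
  structure(list(estimates = est,
                 fixed = c(L_i_PF = L_i_PF, gamma = gamma),
                 sse = best$value, converged = best$convergence == 0,
                 identifiability_warning = ident,
                 n_starts = n_starts, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> f0=%.3f alpha=%.4g beta=%.4g (SSE %.3g)%s\n",
              x$estimates["f0"], x$estimates["alpha"], x$estimates["beta"],
              x$sse,
              if (x$identifiability_warning) " [alpha unresolved: >= 5*gamma]"
              else ""))
  invisible(x)
}

#' Leak rate from a protein-free trace
#'
#' Least-squares slope of the slow post-dithionite tail of a protein-free
#' trace, reported as a positive decay rate (1/s). The leak reflects slow
#' dithionite permeation or spontaneous flipping and is typically orders of
#' magnitude below protein-mediated scrambling.
#'
#' @param trace a `gf_trace`.
#' @param tail_start time (s) where the tail begins; default: after 10
#'   1/gamma-equivalents estimated from the fast phase, or half the trace.
#' @param min_samples minimum tail length.
#' @return list with `L` (1/s), `intercept`, `n`.
#' @export
fit_leak <- function(trace, tail_start = NULL, min_samples = 100) {
  tt <- trace$times; yy <- trace$values
  if (is.null(tail_start)) tail_start <- tt[1] + (max(tt) - tt[1]) / 2
  keep <- tt >= tail_start
  if (sum(keep) < min_samples) {
    stop(sprintf("tail too short: %d samples (< %d)", sum(keep), min_samples))
  }
  fit <- stats::lm(yy[keep] ~ tt[keep])
  list(L = -unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = sum(keep))
}

#' Active-channel fraction from the chloride-flux assay
#'
#' `A = 100 (1 - delta_cl / delta_cl_pf)`: the percentage of liposomes
#' containing at least one active channel, from the chloride released by
#' detergent relative to protein-free liposomes.
#'
#' @param delta_cl chloride change of the protein sample, mM (>= 0).
#' @param delta_cl_pf chloride content of protein-free liposomes, mM (> 0).
#' @return list with `A` (percent, clipped to [0, 100] with a warning when
#'   out of range), `delta_cl`, `delta_cl_pf`.
#' @export
flux_active_fraction <- function(delta_cl, delta_cl_pf) {
  if (delta_cl_pf <= 0) stop("delta_cl_pf must be > 0")
  if (delta_cl < 0) stop("delta_cl must be >= 0")
  A <- 100 * (1 - delta_cl / delta_cl_pf)
  if (A < 0 || A > 100) {
    warning(sprintf("A = %.1f%% outside [0, 100]: clipped", A))
    A <- min(max(A, 0), 100)
  }
  list(A = A, delta_cl = delta_cl, delta_cl_pf = delta_cl_pf)
}

#' Fold change of scrambling rates with qualitative band
#'
#' Ratio of a reference (wild-type) rate to a mutant rate, with the
#' categorical bands used to describe scrambling phenotypes. Values exactly
#' on a band edge are labelled with ">=".
#'
#' @param rate_mut,rate_wt rate constants, 1/s (> 0).
#' @return list with `fold` and `band` (one of `none`, `>10-fold`,
#'   `>100-fold`, `>1000-fold` or their `>=` edge forms).
#' @export
fold_change <- function(rate_mut, rate_wt) {
  if (rate_mut <= 0 || rate_wt <= 0) stop("rates must be > 0")
  fold <- rate_wt / rate_mut
  edges <- c(10, 100, 1000)
  band <- "none"
  for (e in edges) {
    if (fold > e) band <- sprintf(">%d-fold", e)
    else if (fold == e) band <- sprintf(">=%d-fold", e)
  }
  list(fold = fold, band = band)
}
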