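#' Condition for the BPP rate maximum
#'
#' For a single thermally activated motion the relaxation rate over the
#' correlation time is maximal where \eqn{\omega_0\tau \approx 0.6158}. The
#' critical product is located numerically to high precision (it is the root
#' of a quartic in \eqn{u^2} with no neat closed form).
#'
#' @param omega0 Larmor angular frequency in rad/s.
#' @return `bpp_critical_product()`: the dimensionless product
#'   \eqn{\omega_0\tau} at the maximum. `bpp_tau_max()`: the maximizing
#'   correlation time \eqn{\tau} in seconds for the given `omega0`.
#' @export
bpp_critical_product <- function() {
  g <- function(u) u / (1 + u^2) + 4 * u / (1 + 4 * u^2)
  stats::optimize(g, c(0.1, 2), maximum = TRUE, tol = 1e-12)$maximum
}

#' @rdname bpp_critical_product
#' @export
bpp_tau_max <- function(omega0) {
  stopifnot(omega0 > 0)
  bpp_critical_product() / omega0
}

#' Fit a saturation-recovery curve
#'
#' Least-squares fit of the single-exponential recovery
#' \eqn{M(t) = M_0(1 - e^{-t/T_1})} by Levenberg-Marquardt, seeded from the
#' delay at which the observed magnetization crosses \eqn{(1 - 1/e) M_0}.
#'
#' @param curve A [recovery_curve()].
#' @return A list with elements `t1`, `m0`, their standard errors `t1_se` and
#'   `m0_se`, the residual sum of squares `rss`, and a logical `converged`.
#'   A non-monotone mean trend or a failed optimizer sets `converged = FALSE`
#'   (no error is thrown); a delay design that never approaches equilibrium
#'   (max delay well below the fitted T1) triggers an ill-conditioning
#'   warning.
#' @export
fit_recovery <- function(curve) {
  stopifnot(inherits(curve, "recovery_curve"))
  t <- curve$delays
  m <- curve$magnetization
  m0_init <- if (!is.null(curve$m0_hint)) curve$m0_hint else max(m)
  if (m0_init <= 0) m0_init <- max(abs(m), 1)
  # initial T1: delay at which M first exceeds (1 - 1/e) M0, else span/3
  thr <- (1 - exp(-1)) * m0_init
  idx <- which(m >= thr)
  t1_init <- if (length(idx)) max(t[idx[1]], diff(range(t)) / 20) else max(t) / 3
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(log_t1 = log(t1_init), m0 = m0_init),
      fn = function(p) m - p[2] * (1 - exp(-t / exp(p[1]))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(t1 = NA_real_, m0 = NA_real_, t1_se = NA_real_, m0_se = NA_real_,
                rss = NA_real_, converged = FALSE))
  }
  t1 <- exp(fit$par[[1]]); m0 <- fit$par[[2]]
  rss <- sum(fit$fvec^2)
  df <- length(t) - 2L
  s2 <- if (df > 0) rss / df else 0
  vc <- tryCatch(s2 * solve(fit$hessian / 2), error = function(e) matrix(NA, 2, 2))
  se <- suppressWarnings(sqrt(diag(vc)))
  # check the mean trend: binned means should not decrease systematically
  trend_ok <- TRUE
  if (length(t) >= 6) {
    bins <- cut(seq_along(t), 3, labels = FALSE)
    mu <- tapply(m, bins, mean)
    span <- max(m) - min(m)
    trend_ok <- all(diff(mu) > -0.02 * span)
  }
  converged <- isTRUE(fit$info %in% 1:4) && trend_ok
  if (is.finite(t1) && max(t) < 0.1 * t1)
    warning("ill-conditioned recovery design: maximum delay is far below the fitted T1")
  list(t1 = t1, m0 = m0,
       t1_se = se[1] * t1,   # delta method: se(log t1) * t1
       m0_se = se[2],
       rss = rss, converged = converged)
}

# pack/unpack fit parameters; tau0 and amplitude move in log10 space
.rx_pack <- function(motions, fit_amp) {
  p <- c()
  for (m in motions) {
    p <- c(p, log10(m$tau0), m$ea)
    if (fit_amp) p <- c(p, log10(max(m$amplitude, 1e-300)))
  }
  p
}

.rx_unpack <- function(par, n_motions, fit_amp, amplitudes, labels) {
  k <- if (fit_amp) 3L else 2L
  lapply(seq_len(n_motions), function(i) {
    b <- (i - 1L) * k
    amp <- if (fit_amp) 10^par[b + 3L] else amplitudes[i]
    motion_model(10^par[b + 1L], par[b + 2L], amp, labels[i])
  })
}

#' Fit the multi-motion relaxation model to a T1 temperature series
#'
#' Minimizes the weighted rate residuals
#' \eqn{\sum_j [(1/T_{1,\mathrm{model}} - 1/T_{1,\mathrm{obs}})/\sigma_r]^2}
#' with \eqn{\sigma_r = \sigma_{T_1}/T_1^2} propagated from the T1
#' uncertainties (relative weighting is used when no uncertainties are
#' given). The objective is additive in rates, which keeps the minimum region
#' and the wings on an equal footing. tau0 and the amplitudes are fitted in
#' log10 space (they span decades); Ea is fitted linearly in kJ/mol.
#' Levenberg-Marquardt is restarted from `n_starts` initializations
#' (log-uniform tau0 in \[1e-13, 1e-6\] s, Ea uniform in \[0.1, 30\] kJ/mol,
#' amplitudes log-uniform around the scale implied by the observed maximum
#' rate) plus one data-driven start; the best weighted residual wins, ties
#' broken by fewer iterations.
#'
#' @param dataset A [relaxation_dataset()].
#' @param n_motions Number of motions, 1 to 3.
#' @param n_starts Number of random multi-start initializations (default 32).
#' @param seed Integer seed for the start draws (local to this call).
#' @param amplitudes Optional numeric vector of length `n_motions`: hold the
#'   amplitudes fixed at these values (s^-2) and fit only tau0 and Ea per
#'   motion. Use this when amplitudes are known from second-moment analysis
#'   or have been calibrated against an observed minimum; with all three BPP
#'   parameters free, motions that stay on the slow-motion side of the T1
#'   minimum leave the amplitude--tau0 product as the only identifiable
#'   combination.
#' @param init Optional numeric parameter vector or list of [motion_model()]
#'   used as an additional start.
#' @param labels Labels for the fitted motions.
#'
#' @return An object of class `relaxation_fit`: list with `motions` (fitted
#'   [motion_model()] list), `rel_uncertainty` (relative 1-sigma fractions per
#'   free parameter, from the local curvature), `goodness` (weighted residual
#'   sum of squares), `converged`, `n_starts_used`, and `omega0`.
#' @export
fit_relaxation_model <- function(dataset, n_motions, n_starts = 32L, seed = NULL,
                                 amplitudes = NULL, init = NULL,
                                 labels = paste0("motion", seq_len(n_motions))) {
  stopifnot(inherits(dataset, "relaxation_dataset"))
  if (!n_motions %in% 1:3) stop("`n_motions` must be 1, 2 or 3")
  fit_amp <- is.null(amplitudes)
  if (!fit_amp && length(amplitudes) != n_motions)
    stop("`amplitudes` must have length `n_motions`")
  k <- if (fit_amp) 3L else 2L
  npar <- k * n_motions
  n <- length(dataset$t1)
  if (n < ceiling(3 * npar / 2))
    stop(sprintf("dataset too small: %d points for %d free parameters (need >= %d)",
                 n, npar, ceiling(3 * npar / 2)))
  r_obs <- 1 / dataset$t1
  sigma_r <- dataset$sigma / dataset$t1^2
  if (all(sigma_r == 0)) sigma_r <- r_obs  # relative weighting fallback
  if (any(sigma_r == 0)) sigma_r[sigma_r == 0] <- min(sigma_r[sigma_r > 0])
  temps <- dataset$temperatures
  omega0 <- dataset$omega0

  model_rate <- function(par) {
    r <- 0
    for (i in seq_len(n_motions)) {
      b <- (i - 1L) * k
      tau <- 10^par[b + 1L] * exp(par[b + 2L] * 1000 / (R_GAS * temps))
      amp <- if (fit_amp) 10^par[b + 3L] else amplitudes[i]
      r <- r + amp * (tau / (1 + (omega0 * tau)^2) + 4 * tau / (1 + (2 * omega0 * tau)^2))
    }
    r
  }
  resid_fn <- function(par) (model_rate(par) - r_obs) / sigma_r

  # bounds per parameter block
  lo1 <- c(-14, 0); up1 <- c(-5, 40)
  amp_scale <- log10(max(r_obs) * omega0 / 1.4252)  # amplitude giving observed peak rate at the BPP maximum
  if (fit_amp) { lo1 <- c(lo1, amp_scale - 6); up1 <- c(up1, amp_scale + 4) }
  lower <- rep(lo1, n_motions); upper <- rep(up1, n_motions)

  tau_star <- bpp_critical_product() / omega0
  draw_start <- function() {
    p <- c()
    for (i in seq_len(n_motions)) {
      if (stats::runif(1) < 0.5) {
        # log-uniform tau0, uniform Ea
        p <- c(p, stats::runif(1, -13, -6), stats::runif(1, 0.1, 30))
      } else {
        # anchor the motion's BPP crossing at a temperature in (or above) the
        # sweep so starts concentrate on models with structure in range
        ea <- stats::runif(1, 0.1, 20)
        t_cross <- stats::runif(1, min(temps), 2 * max(temps))
        lt0 <- log10(tau_star) - ea * 1000 / (R_GAS * t_cross) / log(10)
        p <- c(p, max(-14, min(-5, lt0)), ea)
      }
      if (fit_amp) p <- c(p, stats::runif(1, amp_scale - 3, amp_scale + 2))
    }
    p
  }
  # data-driven start: place one motion at the observed rate maximum
  heuristic_start <- function() {
    t_star <- temps[which.max(r_obs)]
    ea0 <- 8
    tau_star <- bpp_critical_product() / omega0
    tau00 <- tau_star / exp(ea0 * 1000 / (R_GAS * t_star))
    p <- c()
    for (i in seq_len(n_motions)) {
      p <- c(p, log10(tau00) + (i - 1) * 2, ea0 + (i - 1) * 2)
      if (fit_amp) p <- c(p, amp_scale - (i - 1))
    }
    pmin(pmax(p, lower), upper)
  }

  starts <- list(heuristic_start())
  if (!is.null(init)) {
    if (is.list(init) && all(vapply(init, inherits, logical(1), "motion_model")))
      init <- .rx_pack(init, fit_amp)
    starts <- c(starts, list(pmin(pmax(init, lower), upper)))
  }
  runner <- function(s0) {
    extra <- lapply(seq_len(max(0L, n_starts - length(s0))), function(i) draw_start())
    c(s0, extra)
  }
  starts <- if (!is.null(seed)) local_seed(seed, runner(starts)) else runner(starts)

  if (!fit_amp) {
    # With fixed amplitudes the slot assignment makes the landscape highly
    # multimodal. A free-amplitude pre-fit finds the rate decomposition
    # easily; its motions are mapped onto the amplitude slots (every
    # permutation) with tau0 rescaled along the slow-side ridge
    # C * tau0^-1 = const, giving informed extra starts.
    pre_ss <- Inf
    pre_seeds <- if (is.null(seed)) list(NULL) else list(seed, seed + 7919L)
    for (ps in pre_seeds) {
    pre <- fit_relaxation_model(dataset, n_motions, n_starts = n_starts,
                                seed = ps, labels = labels)
    pre_ss <- min(pre_ss, pre$goodness)
    if (!is.null(pre$motions)) {
      perms <- if (n_motions == 1L) list(1L)
               else if (n_motions == 2L) list(1:2, 2:1)
               else list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      for (pm in perms) {
        p0 <- numeric(2L * n_motions)
        for (i in seq_len(n_motions)) {
          src <- pre$motions[[pm[i]]]
          t0m <- src$tau0 * amplitudes[i] / src$amplitude
          p0[2L * i - 1L] <- max(-14, min(-5, log10(t0m)))
          p0[2L * i] <- max(0, min(40, src$ea))
        }
        starts[[length(starts) + 1L]] <- p0
      }
    }
    }
  }

  run_lm <- function(p0, maxiter = 500) tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                                            ptol = 1e-12, ftol = 1e-12)),
    error = function(e) NULL)
  fits <- Filter(Negate(is.null), lapply(starts, run_lm))
  if (length(fits)) {
    # polish the leading candidates with a fresh restart from their optimum
    sss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
    for (i in utils::head(order(sss), 5L)) {
      f2 <- run_lm(fits[[i]]$par, maxiter = 1000)
      if (!is.null(f2)) fits[[length(fits) + 1L]] <- f2
    }
  }
  best <- NULL
  for (fit in fits) {
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss - 1e-12 ||
        (abs(ss - best$ss) <= 1e-12 && fit$niter < best$fit$niter))
      best <- list(ss = ss, fit = fit)
  }
  if (!is.null(best)) {
    # basin-hopping polish: jittered restarts around the incumbent; when a
    # fixed-amplitude fit lags well behind its free-amplitude pre-fit (the
    # fixed optimum is nested and should come close), hop harder
    hop <- function(n_hops, scale) {
      for (h in seq_len(n_hops)) {
        p0 <- best$fit$par
        for (i in seq_len(n_motions)) {
          b <- (i - 1L) * k
          p0[b + 1L] <- p0[b + 1L] + stats::rnorm(1, 0, scale)
          p0[b + 2L] <- p0[b + 2L] * stats::runif(1, 1 - scale, 1 + scale)
          if (fit_amp) p0[b + 3L] <- p0[b + 3L] + stats::rnorm(1, 0, scale)
        }
        f2 <- run_lm(pmin(pmax(p0, lower), upper))
        if (!is.null(f2)) {
          ss2 <- sum(f2$fvec^2)
          if (ss2 < best$ss - 1e-12) best <<- list(ss = ss2, fit = f2)
        }
      }
    }
    polish <- function() {
      hop(8L, 0.4)
      if (!fit_amp && is.finite(pre_ss) && best$ss > 1.5 * pre_ss + 1) {
        hop(16L, 0.8)
        hop(8L, 0.3)
      }
      best
    }
    best <- if (!is.null(seed)) local_seed(seed + 104729L, polish()) else polish()
  }
  if (is.null(best)) {
    return(structure(list(motions = NULL, rel_uncertainty = NULL,
                          goodness = Inf, converged = FALSE,
                          n_starts_used = length(starts), omega0 = omega0),
                     class = "relaxation_fit"))
  }
  par <- best$fit$par
  motions <- .rx_unpack(par, n_motions, fit_amp, amplitudes, labels)

  # relative uncertainties from the local curvature (numeric Jacobian)
  J <- matrix(0, n, npar)
  f0 <- resid_fn(par)
  for (j in seq_len(npar)) {
    h <- max(1e-6, abs(par[j]) * 1e-6)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (resid_fn(pj) - f0) / h
  }
  df <- n - npar
  s2 <- if (df > 0) best$ss / df else 1
  # pseudo-inverse keeps the uncertainties finite when a parameter sits on a
  # flat direction or a bound (its own uncertainty is then a lower bound)
  vc <- tryCatch(s2 * solve(crossprod(J)), error = function(e) {
    s2 * pracma::pinv(crossprod(J))
  })
  se <- suppressWarnings(sqrt(pmax(diag(vc), 0)))
  rel <- numeric(npar)
  nm <- character(npar)
  for (i in seq_len(n_motions)) {
    b <- (i - 1L) * k
    rel[b + 1L] <- se[b + 1L] * log(10)                      # log10 tau0 -> relative
    rel[b + 2L] <- se[b + 2L] / max(abs(par[b + 2L]), 1e-12) # Ea relative
    nm[b + 1L] <- paste0(labels[i], ".tau0"); nm[b + 2L] <- paste0(labels[i], ".ea")
    if (fit_amp) { rel[b + 3L] <- se[b + 3L] * log(10); nm[b + 3L] <- paste0(labels[i], ".amplitude") }
  }
  names(rel) <- nm
  structure(list(motions = motions, rel_uncertainty = rel, goodness = best$ss,
                 converged = isTRUE(best$fit$info %in% 1:4),
                 n_starts_used = length(starts), omega0 = omega0),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("<relaxation_fit> %s, weighted RSS = %.4g, %d starts\n",
              if (x$converged) "converged" else "NOT converged",
              x$goodness, x$n_starts_used))
  for (m in x$motions) print(m)
  invisible(x)
}

#' Locate the T1 minimum of a relaxation model
#'
#' Global grid scan followed by local refinement of \eqn{T_1(T)} on
#' `t_range`. A minimum on the boundary of the range (monotone model) is
#' reported with `interior = FALSE`.
#'
#' @param motions A [motion_model()] or list thereof.
#' @param omega0 Larmor angular frequency in rad/s.
#' @param t_range Temperature interval in kelvin, default `c(80, 345)`.
#' @param n_grid Scan resolution.
#' @return List with `t_min` (K), `t1_min` (s) and logical `interior`.
#' @export
find_t1_minimum <- function(motions, omega0, t_range = c(80, 345), n_grid = 2000L) {
  stopifnot(length(t_range) == 2L, t_range[1] > 0, t_range[2] > t_range[1])
  grid <- seq(t_range[1], t_range[2], length.out = n_grid)
  vals <- t1_curve(motions, grid, omega0)
  i <- which.min(vals)
  if (i == 1L || i == n_grid) {
    return(list(t_min = grid[i], t1_min = vals[i], interior = FALSE))
  }
  opt <- stats::optimize(function(T) t1_curve(motions, T, omega0),
                         c(grid[i - 1L], grid[i + 1L]), tol = 1e-10)
  list(t_min = opt$minimum, t1_min = opt$objective, interior = TRUE)
}

#' Calibrate a motion amplitude to a target minimum depth
#'
#' Rescales the amplitude of the dominant motion (the one contributing the
#' largest rate at the current T1 minimum, unless `motion_index` is given) so
#' that the model's minimum T1 over `t_range` equals `target_t1_min`. For a
#' single-motion model this changes only the depth of the minimum, not its
#' position.
#'
#' @inheritParams find_t1_minimum
#' @param target_t1_min Desired minimum T1 in seconds.
#' @param motion_index Index of the motion to rescale; default the dominant
#'   one at the minimum.
#' @return The motion list with the rescaled amplitude.
#' @export
calibrate_amplitude <- function(motions, target_t1_min, omega0,
                                t_range = c(80, 345), motion_index = NULL) {
  motions <- as_motion_list(motions)
  stopifnot(target_t1_min > 0)
  cur <- find_t1_minimum(motions, omega0, t_range)
  if (is.null(motion_index)) {
    contrib <- vapply(motions, function(m)
      bpp_rate(m$amplitude, arrhenius_tau(m, cur$t_min), omega0), numeric(1))
    motion_index <- which.max(contrib)
  }
  t1min_scaled <- function(log_s) {
    mm <- motions
    mm[[motion_index]]$amplitude <- motions[[motion_index]]$amplitude * exp(log_s)
    find_t1_minimum(mm, omega0, t_range)$t1_min
  }
  f <- function(log_s) t1min_scaled(log_s) / target_t1_min - 1
  # t1_min is decreasing in the scale factor; bracket the root
  lo <- -1; hi <- 1
  while (f(lo) < 0 && lo > -40) lo <- lo - 2
  while (f(hi) > 0 && hi < 40) hi <- hi + 2
  if (f(lo) < 0 || f(hi) > 0)
    stop("cannot reach `target_t1_min` by rescaling motion ", motion_index)
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  motions[[motion_index]]$amplitude <- motions[[motion_index]]$amplitude * exp(root)
  motions
}
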