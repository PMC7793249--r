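#' ECAP refractory recovery function
#'
#' Amplitude of the electrically evoked compound action potential as a
#' function of the masker-probe interval (MPI):
#' `A * (1 - exp((t0 - mpi) / tau))`, clamped at 0 for `mpi < t0`.
#' `A` is the saturation amplitude (uV), `t0` the absolute refractory
#' period (ms) and `tau` the relative-refractory time constant (ms); at
#' `mpi = t0 + tau` the response reaches `(1 - 1/e) = 63.2%` of A.
#'
#' @param mpi_ms masker-probe interval(s), ms.
#' @param A saturation amplitude, uV (> 0).
#' @param t0 absolute refractory period, ms (>= 0).
#' @param tau relative-refractory time constant, ms (> 0).
#' @return predicted amplitude(s), uV, in \[0, A\].
#' @export
ecap_model <- function(mpi_ms, A, t0, tau) {
  if (tau <= 0) stop("tau must be positive")
  pmax(0, A * (1 - exp((t0 - mpi_ms) / tau)))
}

#' ECAP recovery-curve container
#'
#' @param mpi_ms strictly increasing masker-probe intervals (ms); the
#'   telemetry protocol modeled spans 0.3 to 10 ms.
#' @param amplitude_uv measured ECAP amplitudes (uV).
#' @param electrode electrode label (e.g. 5 apical / 12 medial / 20 basal).
#' @return object of class `recovery_curve` (a data.frame).
#' @export
recovery_curve <- function(mpi_ms, amplitude_uv, electrode = NA) {
  if (length(mpi_ms) != length(amplitude_uv))
    stop("mpi_ms and amplitude_uv lengths differ")
  if (is.unsorted(mpi_ms, strictly = TRUE))
    stop("mpi_ms must be strictly increasing")
  structure(data.frame(mpi_ms = as.numeric(mpi_ms),
                       amplitude_uv = as.numeric(amplitude_uv)),
            electrode = electrode,
            class = c("recovery_curve", "data.frame"))
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve: %d points, MPI %.3g-%.3g ms, electrode %s>\n",
              nrow(x), min(x$mpi_ms), max(x$mpi_ms),
              as.character(attr(x, "electrode"))))
  invisible(x)
}

#' Default measurement grid: 15 log-spaced MPIs over 0.3-10 ms
#' @export
default_mpi_grid <- function(n = 15L, from_ms = 0.3, to_ms = 10)
  exp(seq(log(from_ms), log(to_ms), length.out = n))

#' Simulate an ECAP recovery measurement
#'
#' Evaluates [ecap_model()] on an MPI grid and adds independent Gaussian
#' measurement noise; a synthetic stand-in for telemetry recordings.
#'
#' @param A,t0,tau true model parameters (defaults are a representative
#'   measurement: A = 104 uV, t0 = 0.52 ms, tau = 1.0 ms).
#' @param mpi_ms measurement grid, ms.
#' @param noise_sd Gaussian noise standard deviation, uV.
#' @param seed RNG seed; the same seed reproduces the same curve.
#' @param electrode electrode label.
#' @return a [recovery_curve()].
#' @export
simulate_recovery_curve <- function(A = 104, t0 = 0.52, tau = 1.0,
                                    mpi_ms = default_mpi_grid(),
                                    noise_sd = 0, seed = NULL,
                                    electrode = NA) {
  if (length(mpi_ms) == 0L) stop("empty MPI grid")
  mu <- ecap_model(mpi_ms, A, t0, tau)
  eps <- if (noise_sd > 0) {
    if (!is.null(seed)) {
      with_preserved_rng(seed, stats::rnorm(length(mpi_ms), 0, noise_sd))
    } else stats::rnorm(length(mpi_ms), 0, noise_sd)
  } else numeric(length(mpi_ms))
  recovery_curve(mpi_ms, mu + eps, electrode = electrode)
}

# run expr under a seeded, restored RNG state
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  expr
}

#' Fit the ECAP recovery function
#'
#' Nonlinear least squares of the clamped recovery model on a measured
#' curve.  Starting values follow the usual heuristic: A from the maximum
#' amplitude, t0 from the earliest MPI whose amplitude exceeds 10% of the
#' maximum, tau = 1 ms.  A derivative-free minimization of the clamped
#' residual sum of squares is polished by a Gauss-Newton pass on the
#' points above the estimated absolute refractory period, where the model
#' is smooth.  Standard errors come from the local linearization at the
#' optimum.
#'
#' @param curve a [recovery_curve()] with at least 4 points.
#' @return object of class `recovery_fit` with components `coefficients`
#'   (A, t0, tau), `se`, `sigma`, `fitted`, `residuals`, `curve`,
#'   `t_recovery` (t0 + tau) and `convergence` info.  Supports `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `fitted`, `simulate` and
#'   `plot`.
#' @export
fit_recovery <- function(curve) {
  stopifnot(inherits(curve, "recovery_curve"))
  mpi <- curve$mpi_ms
  amp <- curve$amplitude_uv
  if (length(mpi) < 4L) stop("need at least 4 measurement points")
  amax <- max(amp)
  if (amax <= 0) stop("non-identifiable fit: curve has no positive amplitudes")

  above <- which(amp > 0.1 * amax)
  start <- c(A = amax, t0 = max(0, min(mpi[above])), tau = 1)

  sse <- function(p) {
    if (p[1] <= 0 || p[3] <= 1e-6 || p[2] < 0) return(1e300)
    sum((amp - ecap_model(mpi, p[1], p[2], p[3]))^2)
  }
  opt <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  par <- opt$par

  # Gauss-Newton polish on the smooth branch (mpi > t0_hat)
  sm <- mpi > par[2] + 1e-9
  if (sum(sm) >= 4L) {
    dat <- data.frame(mpi = mpi[sm], amp = amp[sm])
    nf <- try(stats::nls(amp ~ A * (1 - exp((t0 - mpi) / tau)), data = dat,
                         start = as.list(par), algorithm = "port",
                         lower = c(A = 1e-9, t0 = 0, tau = 1e-6),
                         control = stats::nls.control(maxiter = 200,
                                                      warnOnly = TRUE)),
              silent = TRUE)
    if (!inherits(nf, "try-error")) {
      cand <- stats::coef(nf)
      if (sse(cand) <= sse(par) + 1e-12) par <- cand
    }
  }
  names(par) <- c("A", "t0", "tau")

  fitted <- ecap_model(mpi, par[1], par[2], par[3])
  res <- amp - fitted
  dof <- length(mpi) - 3L
  sigma <- sqrt(sum(res^2) / max(1L, dof))

  # SEs from the numerical Jacobian of the clamped model at the optimum
  J <- numeric_jacobian(function(p) ecap_model(mpi, p[1], p[2], p[3]), par)
  covm <- try(sigma^2 * solve(crossprod(J)), silent = TRUE)
  se <- if (inherits(covm, "try-error")) rep(NA_real_, 3)
        else sqrt(pmax(0, diag(covm)))
  names(se) <- names(par)

  structure(list(coefficients = par, se = se, sigma = sigma,
                 fitted.values = fitted, residuals = res, curve = curve,
                 t_recovery = unname(par[2] + par[3]),
                 convergence = opt$convergence, rss = sum(res^2)),
            class = "recovery_fit")
}

numeric_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(1, abs(p[j]))
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

#' @export
print.recovery_fit <- function(x, digits = 4, ...) {
  cat("ECAP recovery-function fit\n")
  co <- x$coefficients
  cat(sprintf("  A   = %s +/- %s uV (saturation amplitude)\n",
              format(co[1], digits = digits), format(x$se[1], digits = 2)))
  cat(sprintf("  t0  = %s +/- %s ms (absolute refractory period)\n",
              format(co[2], digits = digits), format(x$se[2], digits = 2)))
  cat(sprintf("  tau = %s +/- %s ms (relative-refractory time constant)\n",
              format(co[3], digits = digits), format(x$se[3], digits = 2)))
  cat(sprintf("  t0 + tau = %s ms; residual sd %s uV on %d points\n",
              format(x$t_recovery, digits = digits),
              format(x$sigma, digits = 2), nrow(x$curve)))
  invisible(x)
}

#' @export
summary.recovery_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = tab, sigma = object$sigma,
                 rss = object$rss, n = nrow(object$curve),
                 t_recovery = object$t_recovery),
            class = "summary.recovery_fit")
}

#' @export
print.summary.recovery_fit <- function(x, ...) {
  cat("ECAP recovery-function fit\n\nParameters:\n")
  print(x$coefficients)
  cat(sprintf("\nResidual sd: %.4g uV on %d points (RSS %.4g)\n",
              x$sigma, x$n, x$rss))
  cat(sprintf("Combined recovery time t0 + tau: %.4g ms\n", x$t_recovery))
  invisible(x)
}

#' @export
coef.recovery_fit <- function(object, ...) object$coefficients

#' @export
residuals.recovery_fit <- function(object, ...) object$residuals

#' @export
fitted.recovery_fit <- function(object, ...) object$fitted.values

#' Predict ECAP amplitudes from a fitted recovery function
#' @param object a `recovery_fit`.
#' @param newdata optional data.frame with column `mpi_ms` (or a numeric
#'   vector of MPIs); defaults to the fitted curve's grid.
#' @param ... unused.
#' @export
predict.recovery_fit <- function(object, newdata = NULL, ...) {
  mpi <- if (is.null(newdata)) object$curve$mpi_ms
         else if (is.numeric(newdata)) newdata
         else newdata$mpi_ms
  co <- object$coefficients
  ecap_model(mpi, co[1], co[2], co[3])
}

#' @export
simulate.recovery_fit <- function(object, nsim = 1, seed = NULL, ...) {
  co <- object$coefficients
  gen <- function() simulate_recovery_curve(co[1], co[2], co[3],
                                            mpi_ms = object$curve$mpi_ms,
                                            noise_sd = object$sigma)
  if (!is.null(seed)) with_preserved_rng(seed, replicate(nsim, gen(),
                                                         simplify = FALSE))
  else replicate(nsim, gen(), simplify = FALSE)
}

#' @export
plot.recovery_fit <- function(x, ...) {
  graphics::plot(x$curve$mpi_ms, x$curve$amplitude_uv, log = "x",
                 xlab = "masker-probe interval (ms)",
                 ylab = "ECAP amplitude (uV)", ...)
  grid_mpi <- exp(seq(log(min(x$curve$mpi_ms)), log(max(x$curve$mpi_ms)),
                      length.out = 200))
  graphics::lines(grid_mpi, predict(x, grid_mpi), lty = 2)
  invisible(x)
}

#' Recovery-curve text I/O
#'
#' Two tab-separated columns (`mpi_ms`, `amplitude_uv`) with an
#' `# electrode=` header line.
#'
#' @param curve a [recovery_curve()].
#' @param path file path.
#' @export
write_recovery_curve <- function(curve, path) {
  writeLines(c(sprintf("# electrode=%s", as.character(attr(curve, "electrode"))),
               sprintf("%.6g\t%.6g", curve$mpi_ms, curve$amplitude_uv)), path)
  invisible(path)
}

#' @rdname write_recovery_curve
#' @export
read_recovery_curve <- function(path) {
  lines <- readLines(path)
  el <- NA
  m <- grep("^#\\s*electrode=", lines, value = TRUE)
  if (length(m)) el <- sub("^#\\s*electrode=", "", m[1])
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  v <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  recovery_curve(as.numeric(v[, 1]), as.numeric(v[, 2]), electrode = el)
}

# ---- study statistics -------------------------------------------------------

#' Quade randomized-complete-block test
#'
#' Nonparametric test for condition effects in a complete block design
#' (subjects as blocks, strategy variants as conditions), as used to
#' compare per-subject speech scores across coding-strategy conditions.
#' Wraps the standard implementation; the degenerate all-tied design (no
#' within-block variation anywhere) is defined as "no effect"
#' (statistic 0, p = 1).
#'
#' @param scores numeric matrix, blocks (subjects) x conditions; no
#'   missing cells.
#' @return list with `statistic` (Quade F), `p_value`, `df` (numerator,
#'   denominator degrees of freedom).
#' @export
quade_test <- function(scores) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("score matrix must be complete (no missing cells)")
  b <- nrow(scores); k <- ncol(scores)
  if (b < 2L || k < 2L) stop("need at least 2 blocks and 2 conditions")
  if (all(apply(scores, 1L, function(r) diff(range(r)) == 0)))
    return(list(statistic = 0, p_value = 1,
                df = c(df1 = k - 1, df2 = (b - 1) * (k - 1))))
  ht <- stats::quade.test(scores)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = c(df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2])))
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with the t-approximation p-value, as
#' used to relate refractory-period measures (t0, tau) to the best-
#' performing masking half-life per subject.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n` and `degenerate` (TRUE when a
#'   vector is constant, in which case `rho` is NA).
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    warning("constant vector: Spearman rho is undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x),
       degenerate = FALSE)
}

#' Best half-life per subject
#'
#' Given a subjects-by-conditions score matrix and the half-life value of
#' each condition, returns each subject's best-performing half-life; ties
#' are broken toward the smaller half-life and flagged.
#'
#' @param scores numeric matrix, subjects x conditions.
#' @param t_half_values numeric vector of the conditions' half-lives (ms).
#' @return data.frame with `best_t_half_ms` and `tied` per subject.
#' @export
best_t_half <- function(scores, t_half_values) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(t_half_values))
    stop("one t_half value per condition required")
  ord <- order(t_half_values)
  s <- scores[, ord, drop = FALSE]
  th <- t_half_values[ord]
  best <- apply(s, 1L, function(r) th[which.max(r)])   # first max = smaller T1/2
  tied <- apply(s, 1L, function(r) sum(r == max(r)) > 1L)
  data.frame(best_t_half_ms = best, tied = tied)
}
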