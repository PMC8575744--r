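#' @include event-matrix.R
NULL

#' Returns-allowed interaction decay curve
#'
#' `C(tau)` is the average, over evenly spaced time origins, of the number
#' of pairs bonded both at the origin and at lag `tau`.  Breaks followed by
#' re-formation are counted again (returns allowed), so the curve reflects
#' the persistence-with-returns of the longest-lasting bonding between
#' specific partners rather than a first-passage survival.
#'
#' @slot lags lag grid, ps.
#' @slot counts mean count `C(tau)` at each lag.
#' @slot nOrigins number of origins averaged.
#' @slot type interaction type tag.
#' @slot spacing sample spacing, ps.
#' @export
setClass("DecayCurve",
  representation(lags = "numeric", counts = "numeric", nOrigins = "numeric",
                 type = "character", spacing = "numeric"))

setValidity("DecayCurve", function(object) {
  if (length(object@lags) != length(object@counts))
    "lags and counts differ in length" else TRUE
})

setMethod("show", "DecayCurve", function(object) {
  cat("DecayCurve (", object@type, "): ", length(object@lags),
      " lags over ", max(object@lags), " ps, ", object@nOrigins,
      " origins; C(0) = ", sprintf("%.4g", object@counts[1]), "\n", sep = "")
})

#' Compute the returns-allowed decay curve from a bond-event matrix
#'
#' @param bem a [BondEventMatrix], or a logical pairs x frames matrix (then
#'   supply `times`).
#' @param lag lag window, ps (default 5000 = 5 ns).
#' @param originStride spacing between origins, ps (default 1000).
#' @param firstOrigin earliest origin time, ps (default 0; set to an
#'   equilibration offset for real data).
#' @param times frame times when `bem` is a plain matrix.
#' @return a [DecayCurve].
#' @export
decayCurve <- function(bem, lag = 5000, originStride = 1000,
                       firstOrigin = 0, times = NULL) {
  if (methods::is(bem, "BondEventMatrix")) {
    M <- eventMatrix(bem)
    times <- frameTimes(bem)
    type <- bem@type
  } else {
    M <- bem
    if (is.null(times)) times <- seq_len(ncol(M)) - 1
    type <- "matrix"
  }
  storage.mode(M) <- "double"
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  lagFrames <- round(lag / dt)
  originStep <- max(1L, round(originStride / dt))
  first <- which(times >= firstOrigin - 1e-9)[1]
  if (is.na(first)) stop("firstOrigin is beyond the trajectory span")
  if (lagFrames < 1 || ncol(M) - lagFrames < first)
    stop("insufficient trajectory span for the requested lag window")
  origins <- seq(first, ncol(M) - lagFrames, by = originStep)
  C <- numeric(lagFrames + 1L)
  M0 <- M[, origins, drop = FALSE]
  for (k in 0:lagFrames)
    C[k + 1L] <- sum(M0 * M[, origins + k, drop = FALSE]) / length(origins)
  new("DecayCurve", lags = (0:lagFrames) * dt, counts = C,
      nOrigins = length(origins), type = type, spacing = dt)
}

#' Constrained sum-of-exponentials fit of a decay curve
#'
#' Fits `C(tau) ~ C0 * sum_i (A_i/100) * exp(-tau/T_i)` by unweighted
#' least squares with `A_i >= 0`, `T_i > 0` (enforced by a log
#' parameterisation), Levenberg-Marquardt optimisation and multi-start over
#' log-spaced initial time constants.  Components are reported sorted by
#' ascending `T`; amplitudes are percentages of the fitted total (summing
#' to 100 by construction).  Standard errors come from the local quadratic
#' approximation (Gauss-Newton covariance) at the optimum.  Two time
#' constants within 5 percent of each other flag the fit as degenerate.
#'
#' @param curve a [DecayCurve] (or a [generateDecayCurve()] result).
#' @param n number of components (default 4).
#' @param restarts number of multi-start attempts (default 16).
#' @param seed integer seed for the start jitter (default 1; the fit is
#'   deterministic given the seed).
#' @return a [MultiExpFit].
#' @export
fitMultiExp <- function(curve, n = 4, restarts = 16, seed = 1) {
  tau <- curve@lags
  y <- curve@counts
  if (length(tau) < 4 * n) stop("too few points for ", n, " components")
  if (y[1] <= 0) stop("C(0) must be positive")
  model <- function(p) {
    a <- exp(p[1:n]); Tc <- exp(p[n + 1:n])
    drop(exp(-outer(tau, 1 / Tc)) %*% a)
  }
  resid <- function(p) y - model(p)
  spacing <- max(curve@spacing, 1e-3)
  lagMax <- max(tau)
  baseLogT <- seq(log(spacing), log(lagMax), length.out = n + 2)[2:(n + 1)]
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  diag <- character()
  for (r in seq_len(restarts)) {
    jit <- if (r == 1) rep(0, n) else stats::runif(n, -0.8, 0.8)
    p0 <- c(rep(log(y[1] / n), n), baseLogT + jit)
    ft <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e)
    if (inherits(ft, "error")) { diag <- c(diag, conditionMessage(ft)); next }
    if (is.null(best) || ft$deviance < best$deviance) best <- ft
  }
  if (is.null(best))
    stop("multi-exponential fit failed on all restarts: ",
         paste(unique(diag), collapse = "; "))
  p <- best$par
  a <- exp(p[1:n]); Tc <- exp(p[n + 1:n])
  ord <- order(Tc)
  a <- a[ord]; Tc <- Tc[ord]
  C0 <- sum(a)
  A <- 100 * a / C0
  # analytic Jacobian of the model wrt (log a, log T), sorted order
  E <- exp(-outer(tau, 1 / Tc))
  J <- cbind(sweep(E, 2, a, "*"),
             sweep(E * outer(tau, 1 / Tc), 2, a, "*"))
  sse <- sum((y - drop(E %*% a))^2)
  dof <- max(1, length(tau) - 2 * n)
  covm <- tryCatch(chol2inv(chol(crossprod(J))) * sse / dof,
                   error = function(e) NULL)
  if (!is.null(covm)) {
    seLog <- sqrt(pmax(0, diag(covm)))
    seT <- Tc * seLog[n + 1:n]
    # delta method for A_i = 100 a_i / sum(a): dA_i/dlog a_j = A_i (d_ij - a_j/C0)
    G <- diag(A, n) - outer(A, a / C0)
    seA <- sqrt(pmax(0, diag(G %*% covm[1:n, 1:n] %*% t(G))))
  } else {
    seT <- rep(NA_real_, n); seA <- rep(NA_real_, n)
  }
  degenerate <- n > 1 && any(Tc[-1] / Tc[-n] < 1.05)
  new("MultiExpFit", A = A, T = Tc, C0 = C0, seA = seA, seT = seT,
      sse = sse, lags = tau, fitted = drop(E %*% a),
      residuals = y - drop(E %*% a), converged = best$info %in% 1:4,
      degenerate = degenerate)
}

#' Multi-exponential decomposition of a decay curve
#'
#' @slot A percentage contributions (sum to 100), sorted by ascending `T`.
#' @slot T time constants, ps, strictly increasing.
#' @slot C0 fitted amplitude at lag 0.
#' @slot seA,seT standard errors of `A` and `T`.
#' @slot sse sum of squared residuals.
#' @slot lags,fitted,residuals the fit grid, model values and residuals.
#' @slot converged optimiser termination was regular.
#' @slot degenerate two time constants within 5 percent (identifiability
#'   warning, reported rather than silently returned).
#' @export
setClass("MultiExpFit",
  representation(A = "numeric", T = "numeric", C0 = "numeric",
                 seA = "numeric", seT = "numeric", sse = "numeric",
                 lags = "numeric", fitted = "numeric",
                 residuals = "numeric", converged = "logical",
                 degenerate = "logical"))

setValidity("MultiExpFit", function(object) {
  msgs <- character()
  if (any(object@A < 0)) msgs <- c(msgs, "amplitudes must be non-negative")
  if (abs(sum(object@A) - 100) > 1e-6)
    msgs <- c(msgs, "amplitudes must sum to 100")
  if (length(object@T) > 1 && any(diff(object@T) <= 0))
    msgs <- c(msgs, "time constants must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MultiExpFit", function(object) {
  n <- length(object@A)
  cat("MultiExpFit:", n, "components, C0 =", sprintf("%.4g", object@C0),
      if (object@degenerate) "(degenerate)" else "", "\n")
  print(fitParameters(object), digits = 5)
})

#' @rdname fitParameters
#' @export
setMethod("fitParameters", "MultiExpFit", function(x)
  data.frame(component = seq_along(x@A), A = x@A, seA = x@seA,
             T = x@T, seT = x@seT))

#' Residual diagnostics for a multi-exponential fit
#'
#' The graphical-check companion of the fit: the residual series, the
#' maximum absolute residual relative to `C(0)`, and a Wald-Wolfowitz runs
#' test on residual signs (structured residuals indicate a misfit).
#'
#' @param fit a [MultiExpFit].
#' @param curve the fitted [DecayCurve] (optional; residuals are stored in
#'   the fit).
#' @return list with `series` (data.frame `lag`, `residual`),
#'   `maxAbsRelative`, `residualSd`, and `runs` (list `z`, `p`, `nRuns`).
#' @export
fitResiduals <- function(fit, curve = NULL) {
  r <- fit@residuals
  C0 <- fit@C0
  s <- sign(r[r != 0])
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  nR <- if (length(s)) 1L + sum(diff(s) != 0) else 0L
  if (n1 > 0 && n2 > 0) {
    mu <- 2 * n1 * n2 / (n1 + n2) + 1
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
      ((n1 + n2)^2 * (n1 + n2 - 1))
    z <- (nR - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  } else { z <- NA_real_; p <- NA_real_ }
  list(series = data.frame(lag = fit@lags, residual = r),
       maxAbsRelative = max(abs(r)) / C0,
       residualSd = stats::sd(r),
       runs = list(z = z, p = p, nRuns = nR))
}

#' Analytic multi-exponential decay curve
#'
#' Generates `C(tau) = C0 * sum_i (A_i/100) * exp(-tau/T_i)` on a uniform
#' lag grid, optionally with additive Gaussian noise -- the ground-truth
#' counterpart for round-trip testing of [fitMultiExp()].
#'
#' @param A percentage contributions (must sum to 100 within 0.5, the
#'   rounding slack of published tables).
#' @param T time constants, ps (positive).
#' @param C0 amplitude at lag 0 (default 100).
#' @param lag lag window, ps (default 5000).
#' @param spacing grid spacing, ps (default 1).
#' @param noiseSd Gaussian noise sd (default 0).
#' @param seed RNG seed used when `noiseSd > 0`.
#' @return a [DecayCurve].
#' @export
generateDecayCurve <- function(A, T, C0 = 100, lag = 5000, spacing = 1,
                               noiseSd = 0, seed = NULL) {
  stopifnot(length(A) == length(T))
  if (any(T <= 0) || any(A < 0)) stop("invalid decay parameters")
  if (abs(sum(A) - 100) > 0.5)
    stop("amplitude percentages must sum to 100 (got ", sum(A), ")")
  tau <- seq(0, lag, by = spacing)
  y <- drop(exp(-outer(tau, 1 / T)) %*% (C0 * A / 100))
  if (noiseSd > 0) {
    if (!is.null(seed)) {
      oldseed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(oldseed))
        assign(".Random.seed", oldseed, envir = globalenv()))
      set.seed(seed)
    }
    y <- y + stats::rnorm(length(y), 0, noiseSd)
  }
  new("DecayCurve", lags = tau, counts = y, nOrigins = 0,
      type = "analytic", spacing = spacing)
}

#' Published reference decomposition of the XAN-OH...water H-bond decay
#'
#' The four-exponential components (contribution `A`, percent; time
#' constant `T`, ps) reported for the hydroxyl-water H-bond decay curves of
#' zeaxanthin and of horizontal/vertical lutein in POPC bilayers.  Used as
#' ground-truth generator input for round-trip validation of the fitting
#' stage.
#'
#' @return data.frame with `system`, `A1`..`A4`, `T1`..`T4`.
#' @export
referenceDecayParameters <- function() {
  data.frame(
    system = c("ZEA", "LUT_H_eps", "LUT_H_beta", "LUT_V_eps", "LUT_V_beta"),
    A1 = c(22.46, 23.07, 20.06, 23.18, 23.98),
    T1 = c(2.17, 1.35, 1.69, 1.42, 1.84),
    A2 = c(30.52, 27.11, 29.86, 29.96, 31.25),
    T2 = c(72.1, 64.2, 68.0, 50.0, 58.2),
    A3 = c(31.51, 34.41, 35.42, 31.81, 34.44),
    T3 = c(488.7, 396.7, 476.1, 332.5, 380.9),
    A4 = c(15.51, 15.41, 14.65, 15.05, 10.33),
    T4 = c(2981.3, 2692.7, 9481.5, 1808.7, 3170.3),
    stringsAsFactors = FALSE)
}
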