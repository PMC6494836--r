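#' Initial-rate estimate from a progress curve
#'
#' Least-squares slope of product amount versus time over an early-time
#' window, the standard initial-velocity estimate for enzymatic assays
#' (e.g. the dopamine amount at the first in vitro time point of a
#' decarboxylase reaction).
#'
#' @param time Time points (strictly increasing within the window).
#' @param product Matched product amounts.
#' @param window Length-2 numeric `c(from, to)`; defaults to the full
#'   series.
#' @return The slope, in product units per time unit.
#' @examples
#' initial_rate(c(0, 9), c(0, 45))  # 5 per min
#' @export
initial_rate <- function(time, product, window = range(time)) {
  stopifnot(is.numeric(time), is.numeric(product),
            length(time) == length(product))
  keep <- time >= window[1L] & time <= window[2L]
  t <- time[keep]; p <- product[keep]
  if (length(t) < 2L) stop("window must contain at least 2 points")
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  sum((t - mean(t)) * (p - mean(p))) / sum((t - mean(t))^2)
}

#' Fit the Michaelis-Menten rate law
#'
#' Nonlinear least-squares fit of \eqn{v = V_{max} S / (K_m + S)} to
#' substrate/velocity data, with iterative outlier elimination: after
#' each fit, the point with the largest absolute studentized residual
#' exceeding `outlier_threshold` is removed (one per iteration, up to
#' `max_outlier_frac` of the data) and the model is refit. When
#' `enzyme_conc` is supplied, the turnover number is reported as
#' \eqn{k_{cat} = V_{max} / E_0}.
#'
#' Starting values come from a Hanes-Woolf linearisation; the fit is done
#' with [stats::nls()] (port algorithm, positivity bounds) and falls back
#' to the Levenberg-Marquardt implementation in [minpack.lm::nlsLM()]
#' when that fails to converge.
#'
#' @param substrate Substrate concentrations (e.g. µM L-DOPA); at least
#'   4 distinct levels.
#' @param rate Matched velocities (e.g. nmol H2O2 min^-1 mg^-1).
#' @param enzyme_conc Optional enzyme concentration in units such that
#'   `vmax / enzyme_conc` is a per-minute turnover number.
#' @param outlier_threshold Absolute studentized-residual cutoff
#'   (default 3).
#' @param max_outlier_frac Maximum fraction of points that may be removed
#'   (default 0.2).
#' @return An object of class `mm_fit` with components `km`, `vmax`,
#'   `kcat` (or `NA`), `outliers` (logical flags per input point),
#'   `fit` (the underlying `nls` object on the kept points), `rss`,
#'   `iterations` (outlier-elimination rounds), `converged`, and the
#'   input data. Methods: `print`, `summary`, `coef`, `confint`
#'   (profile-likelihood), `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' d <- gen_mm_dataset(km = 41.7, kcat = 6.51, enzyme_conc = 1,
#'                     noise_cv = 0.05, seed = 1)
#' fit <- mm_fit(d$substrate, d$rate, enzyme_conc = 1)
#' coef(fit)
#' @export
mm_fit <- function(substrate, rate, enzyme_conc = NULL,
                   outlier_threshold = 3, max_outlier_frac = 0.2) {
  stopifnot(is.numeric(substrate), is.numeric(rate),
            length(substrate) == length(rate))
  if (any(substrate < 0)) stop("substrate concentrations must be >= 0")
  if (length(unique(substrate)) < 4L)
    stop("need at least 4 distinct substrate levels")
  n <- length(substrate)
  keep <- rep(TRUE, n)
  max_out <- floor(max_outlier_frac * n)
  iterations <- 0L
  fit <- NULL
  repeat {
    fit <- fit_mm_once(substrate[keep], rate[keep])
    if (iterations >= max_out) break
    r <- studentized_resid(fit)
    worst <- which.max(abs(r))
    if (abs(r[worst]) <= outlier_threshold) break
    keep[which(keep)[worst]] <- FALSE
    iterations <- iterations + 1L
    if (sum(keep) < 4L) stop("outlier elimination removed too many points")
  }
  cf <- stats::coef(fit)
  out <- list(km = unname(cf["Km"]), vmax = unname(cf["Vmax"]),
              kcat = if (is.null(enzyme_conc)) NA_real_
                     else unname(cf["Vmax"]) / enzyme_conc,
              enzyme_conc = enzyme_conc,
              outliers = !keep,
              fit = fit,
              rss = sum(stats::resid(fit)^2),
              iterations = iterations,
              converged = fit$convInfo$isConv %||% TRUE,
              substrate = substrate, rate = rate)
  class(out) <- "mm_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_mm_once <- function(s, v) {
  # Hanes-Woolf start: s/v = Km/Vmax + s/Vmax
  ok <- s > 0 & v > 0
  if (sum(ok) >= 2L) {
    hw <- stats::lm.fit(cbind(1, s[ok]), s[ok] / v[ok])$coefficients
    vmax0 <- 1 / hw[2L]; km0 <- hw[1L] * vmax0
  } else vmax0 <- km0 <- NA_real_
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v) * 1.2
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(s[s > 0])
  dat <- data.frame(s = s, v = v)
  start <- list(Vmax = unname(vmax0), Km = unname(km0))
  attempts <- list(
    function() minpack.lm::nlsLM(
      v ~ Vmax * s / (Km + s), data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    function() stats::nls(
      v ~ Vmax * s / (Km + s), data = dat, start = start,
      algorithm = "port", lower = c(Vmax = 0, Km = 1e-12),
      control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    function() minpack.lm::nlsLM(
      v ~ Vmax * s / (Km + s), data = dat,
      start = list(Vmax = max(v) * 1.5, Km = max(s) / 2),
      control = minpack.lm::nls.lm.control(maxiter = 200)))
  for (try_fit in attempts) {
    fit <- tryCatch(try_fit(), error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (all(is.finite(cf)) && cf[["Km"]] > 0 && cf[["Vmax"]] > 0)
        return(fit)
    }
  }
  stop("Michaelis-Menten fit failed to converge after bounded restarts")
}

# studentized residuals of an nls fit via the gradient-matrix leverage
studentized_resid <- function(fit) {
  e <- stats::resid(fit)
  n <- length(e); p <- length(stats::coef(fit))
  if (n <= p) return(rep(0, n))
  J <- fit$m$gradient()
  h <- diag(J %*% solve(crossprod(J), t(J)))
  h <- pmin(h, 1 - 1e-8)
  sigma <- sqrt(sum(e^2) / (n - p))
  if (sigma == 0) return(rep(0, n))
  e / (sigma * sqrt(1 - h))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  Km   = %.4g\n  Vmax = %.4g\n", x$km, x$vmax))
  if (!is.na(x$kcat)) cat(sprintf("  kcat = %.4g\n", x$kcat))
  if (any(x$outliers))
    cat(sprintf("  outliers removed: %d of %d points\n",
                sum(x$outliers), length(x$outliers)))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(Km = object$km, Vmax = object$vmax, kcat = object$kcat)
}

#' @export
fitted.mm_fit <- function(object, ...) {
  object$vmax * object$substrate / (object$km + object$substrate)
}

#' @export
residuals.mm_fit <- function(object, ...) {
  object$rate - fitted(object)
}

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$substrate
       else if (is.list(newdata)) newdata$s %||% newdata$substrate
       else newdata
  object$vmax * s / (object$km + s)
}

#' Profile-likelihood confidence intervals for a Michaelis-Menten fit
#'
#' Intervals are computed by likelihood profiling of the underlying
#' nonlinear fit ([stats::confint()] on the `nls` object), which yields
#' the asymmetric intervals appropriate for kinetic parameters. When a
#' profile is flat (unidentifiable parameter) or profiling fails, the
#' affected bounds are reported from the asymptotic (curvature-based)
#' approximation and flagged in the `"method"` attribute — never
#' silently.
#'
#' @param object An `mm_fit`.
#' @param parm Ignored; all parameters are reported.
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A matrix with rows `Km`, `Vmax` (and `kcat` when an enzyme
#'   concentration was supplied) and columns `low`, `high`; attribute
#'   `"method"` is `"profile"` or `"asymptotic"` per row.
#' @export
confint.mm_fit <- function(object, parm, level = 0.95, ...) {
  fit <- object$fit
  prof <- tryCatch(
    suppressWarnings(suppressMessages(stats::confint(fit, level = level))),
    error = function(e) NULL)
  method <- c(Km = "profile", Vmax = "profile")
  if (is.null(prof) || any(!is.finite(prof))) {
    # asymptotic fallback: estimate +/- t * se
    se <- summary_se(fit)
    est <- stats::coef(fit)
    df <- length(stats::resid(fit)) - length(est)
    tq <- stats::qt(1 - (1 - level) / 2, df)
    asym <- cbind(est - tq * se, est + tq * se)
    if (is.null(prof)) {
      prof <- asym
      method[] <- "asymptotic"
    } else {
      bad <- !is.finite(prof[, 1L]) | !is.finite(prof[, 2L])
      prof[bad, ] <- asym[rownames(prof)[bad], ]
      method[rownames(prof)[bad]] <- "asymptotic"
    }
  }
  ci <- prof[c("Km", "Vmax"), , drop = FALSE]
  colnames(ci) <- c("low", "high")
  if (!is.null(object$enzyme_conc)) {
    ci <- rbind(ci, kcat = ci["Vmax", ] / object$enzyme_conc)
    method <- c(method, kcat = unname(method["Vmax"]))
  }
  attr(ci, "method") <- method
  attr(ci, "level") <- level
  ci
}

summary_se <- function(fit) {
  J <- fit$m$gradient()
  e <- stats::resid(fit)
  p <- length(stats::coef(fit))
  s2 <- sum(e^2) / (length(e) - p)
  se <- sqrt(diag(solve(crossprod(J))) * s2)
  names(se) <- names(stats::coef(fit))
  se
}

#' @export
summary.mm_fit <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  structure(list(fit = object, ci = ci, level = level),
            class = "summary.mm_fit")
}

#' @export
print.summary.mm_fit <- function(x, ...) {
  f <- x$fit
  cat("Michaelis-Menten fit with profile-likelihood intervals\n")
  show <- function(nm, est) {
    if (nm %in% rownames(x$ci))
      cat(sprintf("  %-5s= %.4g (%.4g-%.4g)\n", nm, est,
                  x$ci[nm, "low"], x$ci[nm, "high"]))
  }
  show("Km", f$km); show("Vmax", f$vmax)
  if (!is.na(f$kcat)) show("kcat", f$kcat)
  cat(sprintf("  residual SS %.4g on %d kept points (%d outliers, %d rounds)\n",
              f$rss, sum(!f$outliers), sum(f$outliers), f$iterations))
  invisible(x)
}

#' @export
plot.mm_fit <- function(x, ...) {
  graphics::plot(x$substrate, x$rate,
                 col = ifelse(x$outliers, "red", "black"),
                 pch = ifelse(x$outliers, 4, 19),
                 xlab = "substrate", ylab = "velocity", ...)
  s <- seq(0, max(x$substrate), length.out = 200)
  graphics::lines(s, x$vmax * s / (x$km + s), col = "forestgreen", lwd = 2)
  invisible(x)
}

#' Bifunctional aldehyde-synthase activity partition
#'
#' Percentage of total flux through the aldehyde-synthase branch of a
#' bifunctional DHPAAS/DDC enzyme, computed from the two measured maximal
#' velocities: `100 * v_aas / (v_aas + v_ddc)`.
#'
#' @param v_aas Aldehyde-synthase Vmax (e.g. nmol H2O2 min^-1 mg^-1).
#' @param v_ddc Decarboxylase Vmax (e.g. nmol dopamine min^-1 mg^-1).
#' @param digits Significant figures for the reported percentage
#'   (default 2, the conventional reporting precision); `NULL` returns
#'   full precision.
#' @return Percentage in \[0, 100\].
#' @examples
#' percent_aas(115, 5.59)   # 95
#' percent_aas(15.4, 247)   # 5.9
#' @export
percent_aas <- function(v_aas, v_ddc, digits = 2) {
  stopifnot(is.numeric(v_aas), is.numeric(v_ddc))
  if (any(v_aas < 0) || any(v_ddc < 0))
    stop("velocities must be >= 0")
  if (any(v_aas + v_ddc == 0))
    stop("partition undefined when both velocities are zero")
  pct <- 100 * v_aas / (v_aas + v_ddc)
  if (is.null(digits)) pct else signif(pct, digits)
}
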