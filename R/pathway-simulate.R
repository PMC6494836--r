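#' Simulate a THP pathway model
#'
#' Integrates the pathway ODE system over `[0, t_end]` with a
#' stiff-capable solver ([deSolve::lsoda]). The state carries the four
#' species (L-DOPA, dopamine, DHPAA, THP) plus two bookkeeping
#' integrals: cumulative substrate fed and cumulative DHPAA drained, so
#' that the DOPA-equivalent balance
#' \deqn{S + DA + AL + 2T + drained - fed}
#' is conserved exactly up to solver tolerance.
#'
#' The feed switch-off at `feed_cap` is handled by splitting the
#' integration at the exact cap-crossing time (the feed integral is
#' linear in time, so the crossing is analytic); the cumulative fed
#' amount therefore never overshoots the cap.
#'
#' @param spec A [pathway_spec()].
#' @param initial A [pathway_state()]; the initial condition (its `t`
#'   component must be 0).
#' @param t_end Simulation end time (h); default 50.
#' @param n_grid Number of uniform output points over `[0, t_end]`;
#'   default 501.
#' @param times Optional explicit output times (must start at 0 and be
#'   strictly increasing); overrides `n_grid`/`t_end`.
#' @param rtol,atol Relative and absolute solver tolerances.
#'
#' @return A data frame of class `thp_trajectory` with columns
#'   `t, S, DA, AL, THP, fed, drained` and attributes `spec` (the model),
#'   `initial`, and `diagnostics` (tolerances and solver status).
#' @examples
#' spec <- pathway_spec("SINGLE_DHPAAS_PATH",
#'                      dhpaas = enzyme_params(5, 0.05),
#'                      phi_aldehyde = 0.5, k_cond = 10, feed_rate = 2)
#' traj <- simulate_pathway(spec, t_end = 50)
#' thp_yield_pct(traj)
#' @export
simulate_pathway <- function(spec, initial = pathway_state(), t_end = 50,
                             n_grid = 501, rtol = 1e-8, atol = 1e-10,
                             times = NULL) {
  stopifnot(inherits(spec, "pathway_spec"))
  if (!inherits(initial, "pathway_state")) initial <- do.call(pathway_state, as.list(initial))
  if (unclass(initial)[["t"]] != 0)
    stop("initial state must be at t = 0")
  y0 <- unclass(initial)[c("S", "DA", "AL", "THP", "fed", "drained")]
  if (y0[["fed"]] > spec$feed_cap)
    stop("initial 'fed' exceeds 'feed_cap'")
  if (is.null(times)) {
    if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
      stop("'t_end' must be > 0")
    times <- seq(0, t_end, length.out = n_grid)
  } else {
    if (times[1L] != 0 || any(diff(times) <= 0))
      stop("'times' must start at 0 and be strictly increasing")
    t_end <- times[length(times)]
  }

  # exact cap-crossing time (fed grows linearly while feeding is on)
  t_cap <- if (spec$feed_rate > 0 && y0[["fed"]] < spec$feed_cap)
    (spec$feed_cap - y0[["fed"]]) / spec$feed_rate else 0

  run <- function(y, tt, feed_on) {
    if (length(tt) < 2L) {
      out <- matrix(c(tt, y), nrow = 1,
                    dimnames = list(NULL, c("time", names(y))))
      return(list(out = out, istate = 2L))
    }
    sol <- deSolve::lsoda(y = y, times = tt, func = pathway_rhs,
                          parms = list(spec = spec, feed_on = feed_on),
                          rtol = rtol, atol = atol)
    istate <- attr(sol, "istate")[1L]
    if (is.null(istate)) istate <- 2L
    if (istate < 0L)
      stop(sprintf(paste0("ODE integration failed (lsoda istate = %d) at ",
                          "rtol = %g, atol = %g"), istate, rtol, atol))
    list(out = sol, istate = istate)
  }

  if (t_cap > 0 && t_cap < t_end) {
    tt1 <- unique(c(times[times < t_cap], t_cap))
    r1 <- run(y0, tt1, feed_on = TRUE)
    y_mid <- r1$out[nrow(r1$out), -1L]
    y_mid[["fed"]] <- spec$feed_cap   # pin the integral at the switch
    tt2 <- unique(c(t_cap, times[times > t_cap]))
    r2 <- run(y_mid, tt2, feed_on = FALSE)
    keep2 <- r2$out[, "time"] %in% times & r2$out[, "time"] > t_cap
    out <- rbind(r1$out[r1$out[, "time"] %in% times, , drop = FALSE],
                 r2$out[keep2, , drop = FALSE])
    istate <- max(r1$istate, r2$istate)
  } else {
    feed_on <- t_cap > 0   # t_cap == 0 means no feeding at all
    r <- run(y0, times, feed_on = feed_on)
    out <- r$out
    istate <- r$istate
  }

  df <- as.data.frame(out)
  names(df)[1L] <- "t"
  # tiny solver-tolerance negatives are clamped; anything larger is an error
  neg_tol <- 100 * atol + rtol * max(abs(df$fed), abs(df$S), 1)
  for (col in c("S", "DA", "AL", "THP", "fed", "drained")) {
    bad <- df[[col]] < -neg_tol
    if (any(bad))
      stop(sprintf("solver produced a substantially negative %s (min %g)",
                   col, min(df[[col]])))
    df[[col]][df[[col]] < 0] <- 0
  }
  structure(df, class = c("thp_trajectory", "data.frame"),
            spec = spec, initial = initial,
            diagnostics = list(rtol = rtol, atol = atol, istate = istate,
                               t_cap = if (t_cap > 0 && t_cap < t_end) t_cap
                                       else NA_real_))
}

# ODE right-hand side; concentrations are clamped at zero inside the rate
# laws so that solver-tolerance undershoot cannot reverse a flux.
pathway_rhs <- function(t, y, parms) {
  spec <- parms$spec
  s  <- max(y[["S"]], 0)
  da <- max(y[["DA"]], 0)
  al <- max(y[["AL"]], 0)

  v_ddc <- if (!is.null(spec$ddc)) {
    inh <- if (spec$feedback) list(dopamine = da) else list()
    mm_velocity(spec$ddc, s, inh)
  } else 0
  v_mao <- if (spec$topology == "MAO_PATH") {
    inh <- list(amine = spec$amine_pool)
    if (spec$feedback) inh$DHPAA <- al
    mm_velocity(spec$mao, da, inh)
  } else 0
  if (!is.null(spec$dhpaas)) {
    inh <- if (spec$feedback) list(dopamine = da, DHPAA = al) else list()
    v_dhp <- mm_velocity(spec$dhpaas, s, inh)
    phi <- spec$phi_aldehyde
    v_ald <- phi * v_dhp
    v_dec <- (1 - phi) * v_dhp
  } else {
    v_dhp <- v_ald <- v_dec <- 0
  }
  v_cond <- spec$k_cond * da * al
  v_drain <- spec$k_drain * al
  feed <- if (parms$feed_on) spec$feed_rate else 0

  list(c(S = feed - v_ddc - v_dhp,
         DA = v_ddc + v_dec - v_mao - v_cond,
         AL = v_ald + v_mao - v_cond - v_drain,
         THP = v_cond,
         fed = feed,
         drained = v_drain))
}

#' @export
print.thp_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  fin <- x[nrow(x), ]
  cat(sprintf("THP pathway trajectory (%s), %d points over [0, %g] h\n",
              spec$topology, nrow(x), max(x$t)))
  cat(sprintf("  final: S = %.4g, DA = %.4g, AL = %.4g, THP = %.4g mM\n",
              fin$S, fin$DA, fin$AL, fin$THP))
  cat(sprintf("  fed = %.4g mM, drained = %.4g mM, yield = %.3g%%\n",
              fin$fed, fin$drained, thp_yield_pct(x)))
  invisible(x)
}

#' @export
plot.thp_trajectory <- function(x, ...) {
  cols <- c(S = "black", DA = "dodgerblue3", AL = "darkorange2",
            THP = "forestgreen")
  ylim <- c(0, max(x$S, x$DA, x$AL, x$THP))
  graphics::plot(x$t, x$S, type = "l", col = cols["S"], ylim = ylim,
                 xlab = "time (h)", ylab = "concentration (mM)", ...)
  graphics::lines(x$t, x$DA, col = cols["DA"])
  graphics::lines(x$t, x$AL, col = cols["AL"])
  graphics::lines(x$t, x$THP, col = cols["THP"], lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = c(1, 1, 1, 2), col = cols,
                   legend = c("L-DOPA", "dopamine", "DHPAA", "THP"))
  invisible(x)
}

#' Molar THP yield of a trajectory
#'
#' Yield on the DOPA-equivalent basis: two molecules of L-DOPA are
#' consumed per THP (one via the amine, one via the aldehyde), so
#' \deqn{yield = 100 \cdot 2 T(t_{end}) / (S_0 + DA_0 + AL_0 + 2 T_0 + fed_{total}).}
#'
#' @param traj A `thp_trajectory` from [simulate_pathway()].
#' @return Yield in percent, in \[0, 100\].
#' @export
thp_yield_pct <- function(traj) {
  stopifnot(inherits(traj, "thp_trajectory"), nrow(traj) >= 1L)
  y0 <- unclass(attr(traj, "initial"))
  fin <- traj[nrow(traj), ]
  denom <- y0[["S"]] + y0[["DA"]] + y0[["AL"]] + 2 * y0[["THP"]] + fin$fed
  if (denom <= 0)
    stop("yield undefined: total DOPA input is zero")
  100 * 2 * fin$THP / denom
}

#' DOPA-equivalent conservation residual
#'
#' Maximum over the trajectory of the relative imbalance of the conserved
#' quantity `S + DA + AL + 2*THP + drained - fed`, normalised by the total
#' DOPA-equivalent input. Values close to solver tolerance indicate a
#' well-integrated trajectory.
#'
#' @param traj A `thp_trajectory`.
#' @return Maximum relative residual (dimensionless).
#' @export
conservation_residual <- function(traj) {
  stopifnot(inherits(traj, "thp_trajectory"))
  y0 <- unclass(attr(traj, "initial"))
  c0 <- y0[["S"]] + y0[["DA"]] + y0[["AL"]] + 2 * y0[["THP"]]
  bal <- traj$S + traj$DA + traj$AL + 2 * traj$THP + traj$drained -
    traj$fed - c0
  total <- c0 + max(traj$fed)
  if (total <= 0) return(0)
  max(abs(bal)) / total
}
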