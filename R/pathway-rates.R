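## Rate laws. All enzymatic velocities are irreversible Michaelis-Menten
## with competitive inhibition entering through an effective Km,
##   Km_eff = Km * (1 + sum_i I_i / Ki_i),
## and the condensation is elementary second-order mass action.

# Effective Km given inhibitor concentrations; inhibitors with no Ki entry
# are inactive.
km_effective <- function(enz, inhibitors) {
  fac <- 1
  for (nm in names(inhibitors)) {
    ki <- unname(enz$ki[nm])
    if (!is.na(ki)) fac <- fac + inhibitors[[nm]] / ki
  }
  unname(enz$km * fac)
}

state_conc <- function(state) {
  x <- unclass(state)
  if (any(x[c("S", "DA", "AL", "THP")] < 0))
    stop("negative concentration in state")
  x
}

#' DDC reaction velocity
#'
#' Michaelis-Menten velocity of the L-DOPA decarboxylase step. With
#' feedback enabled, dopamine inhibits competitively through the DDC
#' `ki["dopamine"]` entry.
#'
#' @param state A [pathway_state()].
#' @param spec A [pathway_spec()] containing a `ddc` block.
#' @return Velocity in mM h^-1.
#' @export
ddc_rate <- function(state, spec) {
  if (is.null(spec$ddc))
    stop("pathway_spec has no 'ddc' block")
  x <- state_conc(state)
  inh <- if (spec$feedback) list(dopamine = x[["DA"]]) else list()
  mm_velocity(spec$ddc, x[["S"]], inh)
}

#' MAO reaction velocity
#'
#' Michaelis-Menten velocity of the dopamine-to-DHPAA oxidation. The
#' fixed competing-amine pool always inhibits competitively (through
#' `ki["amine"]`); with feedback enabled, DHPAA also inhibits (through
#' `ki["DHPAA"]`).
#'
#' @inheritParams ddc_rate
#' @return Velocity in mM h^-1.
#' @export
mao_rate <- function(state, spec) {
  if (spec$topology != "MAO_PATH")
    stop("mao_rate is only defined for topology MAO_PATH")
  x <- state_conc(state)
  inh <- list(amine = spec$amine_pool)
  if (spec$feedback) inh$DHPAA <- x[["AL"]]
  mm_velocity(spec$mao, x[["DA"]], inh)
}

#' Bifunctional DHPAAS branch velocities
#'
#' One Michaelis-Menten velocity on L-DOPA, partitioned into the aldehyde
#' (DHPAA-producing) branch and the decarboxylation (dopamine-producing)
#' branch by the constant fraction `phi_aldehyde`. With feedback enabled,
#' dopamine and DHPAA inhibit competitively through the matching `ki`
#' entries.
#'
#' @inheritParams ddc_rate
#' @return Named numeric vector `c(aldehyde = ..., decarboxylation = ...)`
#'   in mM h^-1; the two components sum to the total velocity.
#' @export
dhpaas_rates <- function(state, spec) {
  if (is.null(spec$dhpaas))
    stop("pathway_spec has no 'dhpaas' block")
  x <- state_conc(state)
  inh <- if (spec$feedback)
    list(dopamine = x[["DA"]], DHPAA = x[["AL"]]) else list()
  v <- mm_velocity(spec$dhpaas, x[["S"]], inh)
  phi <- spec$phi_aldehyde
  c(aldehyde = phi * v, decarboxylation = (1 - phi) * v)
}

mm_velocity <- function(enz, s, inhibitors) {
  if (s <= 0) return(0)
  enz$vmax * s / (km_effective(enz, inhibitors) + s)
}

#' Pictet-Spengler condensation rate
#'
#' Spontaneous second-order condensation of dopamine with DHPAA to form
#' THP: rate = k_cond * \[dopamine\] * \[DHPAA\]. Each THP consumes one
#' molecule of each partner.
#'
#' @inheritParams ddc_rate
#' @return Rate in mM h^-1.
#' @export
condensation_rate <- function(state, spec) {
  x <- state_conc(state)
  spec$k_cond * x[["DA"]] * x[["AL"]]
}

#' Substrate feed term
#'
#' Constant L-DOPA feed that switches off once the cumulative fed amount
#' reaches `feed_cap`.
#'
#' @inheritParams ddc_rate
#' @return Feed rate in mM h^-1.
#' @export
feed_term <- function(state, spec) {
  x <- unclass(state)
  if (x[["fed"]] < spec$feed_cap) spec$feed_rate else 0
}
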