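#' Enzyme kinetic parameter block
#'
#' Bundles the Michaelis-Menten parameters of one enzymatic step, together
#' with optional competitive-inhibition constants.
#'
#' @param vmax Maximal velocity (mM h^-1). Must be >= 0.
#' @param km Michaelis constant (mM). Must be > 0.
#' @param ki Optional named numeric vector of competitive inhibition
#'   constants (mM), all > 0. Recognised names are `"dopamine"`, `"DHPAA"`
#'   and `"amine"` (the generic competing-amine pool seen by MAO).
#'   An inhibitor with no entry here exerts no inhibition.
#'
#' @return An object of class `enzyme_params`.
#' @examples
#' enzyme_params(vmax = 10, km = 0.05, ki = c(dopamine = 1))
#' @export
enzyme_params <- function(vmax, km, ki = NULL) {
  stopifnot(is.numeric(vmax), length(vmax) == 1L, is.finite(vmax),
            is.numeric(km), length(km) == 1L, is.finite(km))
  if (vmax < 0) stop("'vmax' must be >= 0")
  if (km <= 0) stop("'km' must be > 0")
  if (!is.null(ki)) {
    if (!is.numeric(ki) || is.null(names(ki)) || any(!nzchar(names(ki))))
      stop("'ki' must be a named numeric vector")
    if (any(!is.finite(ki)) || any(ki <= 0))
      stop("all inhibition constants must be finite and > 0")
    unknown <- setdiff(names(ki), c("dopamine", "DHPAA", "amine"))
    if (length(unknown))
      stop("unknown inhibitor name(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(vmax = as.numeric(vmax), km = as.numeric(km),
                 ki = if (is.null(ki)) numeric(0) else ki),
            class = "enzyme_params")
}

#' @export
print.enzyme_params <- function(x, ...) {
  cat(sprintf("Enzyme: Vmax = %g mM/h, Km = %g mM", x$vmax, x$km))
  if (length(x$ki))
    cat(sprintf("; Ki: %s",
                paste(sprintf("%s = %g", names(x$ki), x$ki), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Pathway model specification
#'
#' Defines one instance of a THP-production kinetic model: the topology,
#' the enzymes present, the spontaneous Pictet-Spengler condensation, the
#' optional first-order drain of the reactive aldehyde DHPAA, and the
#' L-DOPA feeding regime.
#'
#' Three topologies are supported:
#' \describe{
#'   \item{`MAO_PATH`}{the nonsymmetrical route: DDC converts L-DOPA to
#'     dopamine, and MAO oxidises dopamine to DHPAA. MAO is always subject
#'     to competitive inhibition by the fixed competing-amine pool.}
#'   \item{`DDC_DHPAAS_PATH`}{the symmetrical route: DDC makes dopamine and
#'     DHPAAS makes DHPAA, both directly from L-DOPA in parallel.}
#'   \item{`SINGLE_DHPAAS_PATH`}{one bifunctional DHPAAS produces both
#'     dopamine and DHPAA from L-DOPA; `phi_aldehyde` sets the flux
#'     fraction routed to the aldehyde branch.}
#' }
#'
#' @param topology One of `"MAO_PATH"`, `"DDC_DHPAAS_PATH"`,
#'   `"SINGLE_DHPAAS_PATH"`.
#' @param ddc,mao,dhpaas [enzyme_params()] blocks. `ddc` is required for
#'   `MAO_PATH` and `DDC_DHPAAS_PATH`; `mao` only for `MAO_PATH`;
#'   `dhpaas` for the two DHPAAS topologies.
#' @param phi_aldehyde Fraction (in \[0, 1\]) of the bifunctional DHPAAS
#'   flux routed to the aldehyde branch; equals the "% DHPAAS activity"
#'   of an enzyme variant divided by 100.
#' @param k_cond Second-order Pictet-Spengler condensation rate constant
#'   (mM^-1 h^-1).
#' @param k_drain First-order DHPAA drain constant (h^-1); 0 disables the
#'   drain.
#' @param feed_rate Constant L-DOPA feed rate (mM h^-1).
#' @param feed_cap Maximum cumulative fed substrate (mM); feeding stops
#'   once this amount has been delivered. Default 100.
#' @param feedback Logical; enable product feedback inhibition (dopamine
#'   inhibits DDC and the DHPAAS decarboxylation branch, dopamine and
#'   DHPAA inhibit DHPAAS, DHPAA inhibits MAO, each through the matching
#'   `ki` entry of the enzyme block).
#' @param amine_pool Effective concentration (mM) of the competing amines
#'   seen by MAO; acts through the MAO `ki["amine"]` entry.
#'
#' @return An object of class `pathway_spec`.
#' @examples
#' spec <- pathway_spec("SINGLE_DHPAAS_PATH",
#'                      dhpaas = enzyme_params(10, 0.05),
#'                      phi_aldehyde = 0.5, k_cond = 1, feed_rate = 2)
#' @export
pathway_spec <- function(topology = c("MAO_PATH", "DDC_DHPAAS_PATH",
                                      "SINGLE_DHPAAS_PATH"),
                         ddc = NULL, mao = NULL, dhpaas = NULL,
                         phi_aldehyde = 1, k_cond = 0, k_drain = 0,
                         feed_rate = 0, feed_cap = 100,
                         feedback = FALSE, amine_pool = 0) {
  topology <- match.arg(topology)
  chk_block <- function(b, name) {
    if (!is.null(b) && !inherits(b, "enzyme_params"))
      stop(sprintf("'%s' must be an enzyme_params object", name))
  }
  chk_block(ddc, "ddc"); chk_block(mao, "mao"); chk_block(dhpaas, "dhpaas")
  if (topology == "MAO_PATH") {
    if (is.null(ddc)) stop("topology MAO_PATH requires a 'ddc' block")
    if (is.null(mao)) stop("topology MAO_PATH requires a 'mao' block")
  } else if (topology == "DDC_DHPAAS_PATH") {
    if (is.null(ddc)) stop("topology DDC_DHPAAS_PATH requires a 'ddc' block")
    if (is.null(dhpaas))
      stop("topology DDC_DHPAAS_PATH requires a 'dhpaas' block")
  } else {
    if (is.null(dhpaas))
      stop("topology SINGLE_DHPAAS_PATH requires a 'dhpaas' block")
  }
  if (!is.numeric(phi_aldehyde) || length(phi_aldehyde) != 1L ||
      is.na(phi_aldehyde) || phi_aldehyde < 0 || phi_aldehyde > 1)
    stop("'phi_aldehyde' must be a single number in [0, 1]")
  for (nm in c("k_cond", "k_drain", "feed_rate", "amine_pool")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("'%s' must be a single finite number >= 0", nm))
  }
  if (!is.numeric(feed_cap) || length(feed_cap) != 1L || feed_cap <= 0)
    stop("'feed_cap' must be > 0")
  stopifnot(is.logical(feedback), length(feedback) == 1L, !is.na(feedback))
  structure(list(topology = topology, ddc = ddc, mao = mao, dhpaas = dhpaas,
                 phi_aldehyde = as.numeric(phi_aldehyde),
                 k_cond = as.numeric(k_cond), k_drain = as.numeric(k_drain),
                 feed_rate = as.numeric(feed_rate),
                 feed_cap = as.numeric(feed_cap),
                 feedback = feedback, amine_pool = as.numeric(amine_pool)),
            class = "pathway_spec")
}

#' @export
print.pathway_spec <- function(x, ...) {
  cat("THP pathway model (", x$topology, ")\n", sep = "")
  for (nm in c("ddc", "mao", "dhpaas"))
    if (!is.null(x[[nm]])) { cat(" ", toupper(nm), ": "); print(x[[nm]]) }
  if (x$topology == "SINGLE_DHPAAS_PATH")
    cat(sprintf("  aldehyde-branch fraction phi = %g\n", x$phi_aldehyde))
  cat(sprintf("  k_cond = %g /mM/h, k_drain = %g /h\n", x$k_cond, x$k_drain))
  cat(sprintf("  feed %g mM/h up to %g mM; feedback %s; amine pool %g mM\n",
              x$feed_rate, x$feed_cap, if (x$feedback) "on" else "off",
              x$amine_pool))
  invisible(x)
}

#' Pathway state at one time point
#'
#' @param t Time (h).
#' @param S L-DOPA concentration (mM).
#' @param DA Dopamine concentration (mM).
#' @param AL DHPAA (aldehyde) concentration (mM).
#' @param THP THP concentration (mM).
#' @param fed Cumulative L-DOPA fed (mM).
#' @param drained Cumulative DHPAA lost to the drain (mM).
#'
#' @return A named numeric vector of class `pathway_state`.
#' @export
pathway_state <- function(t = 0, S = 0, DA = 0, AL = 0, THP = 0,
                          fed = 0, drained = 0) {
  x <- c(t = t, S = S, DA = DA, AL = AL, THP = THP,
         fed = fed, drained = drained)
  if (any(!is.finite(x))) stop("all state components must be finite")
  if (any(x[-1] < 0)) stop("concentrations and cumulative terms must be >= 0")
  structure(x, class = "pathway_state")
}
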