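## Embedded constant tables: 2021 IUPAC standard atomic weights
## (conventional/abridged values) and principal-isotope monoisotopic
## masses. Kept local so every mass in the package is bit-reproducible
## with no external dependency.

.atomic_weight <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  Na = 22.990, K = 39.098, Cl = 35.45, F = 18.998, Br = 79.904,
  I = 126.904, Fe = 55.845, Mg = 24.305, Ca = 40.078, Se = 78.971,
  B = 10.81, Si = 28.085)

.monoisotopic_mass <- c(
  H = 1.00782503207, C = 12, N = 14.0030740048, O = 15.9949146196,
  S = 31.97207100, P = 30.97376163, Na = 22.9897692809, K = 38.96370668,
  Cl = 34.96885268, F = 18.99840322, Br = 78.9183371, I = 126.904473,
  Fe = 55.9349375, Mg = 23.9850417, Ca = 39.96259098, Se = 79.9165213,
  B = 11.0093054, Si = 27.9769265325)

.electron_mass <- 0.000548579909

#' Parse a molecular formula
#'
#' Parses a Hill-notation formula string (e.g. `"C16H17NO4"` for THP)
#' into element counts. Only elements in the embedded atomic-mass table
#' are accepted and zero counts are rejected.
#'
#' @param text Formula string.
#' @return A named integer vector of class `mol_formula`.
#' @examples
#' parse_formula("C16H17NO4")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(text) || !length(tokens))
    stop(sprintf("malformed formula string: '%s'", text))
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elems, names(.atomic_weight))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 1L))
    stop("element counts must be >= 1")
  f <- tapply(counts, elems, sum)
  out <- as.integer(f)
  names(out) <- names(f)
  structure(out[hill_order(names(out))], class = "mol_formula")
}

hill_order <- function(elems) {
  if ("C" %in% elems)
    c("C", if ("H" %in% elems) "H", sort(setdiff(elems, c("C", "H"))))
  else sort(elems)
}

#' @export
format.mol_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "mol_formula")) f else parse_formula(f)
}

#' Average (standard atomic weight) molecular mass
#'
#' @param f A `mol_formula` or formula string.
#' @return Mass in g mol^-1.
#' @examples
#' average_mass("C16H17NO4")  # 287.31, consistent with 1 mM THP = 287 mg/L
#' @export
average_mass <- function(f) {
  f <- as_formula(f)
  sum(.atomic_weight[names(f)] * unclass(f))
}

#' Monoisotopic mass of a neutral molecule
#'
#' @inheritParams average_mass
#' @return Monoisotopic mass in u.
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(.monoisotopic_mass[names(f)] * unclass(f))
}

#' Monoisotopic ion m/z
#'
#' Computes the m/z of a singly-charged adduct of the molecule:
#' \describe{
#'   \item{`"M"`}{the neutral monoisotopic mass (no electron correction).}
#'   \item{`"M+H"`}{protonated ion, +1.}
#'   \item{`"M-H"`}{deprotonated ion, -1.}
#'   \item{`"M-3H"`}{loss of three hydrogen atoms followed by loss of one
#'     electron, +1 — the quinone-type oxidation ion observed for
#'     catechol-bearing alkaloids such as THP.}
#' }
#' The electron mass is accounted for on every charged species.
#'
#' @inheritParams average_mass
#' @param adduct One of `"M"`, `"M+H"`, `"M-H"`, `"M-3H"`.
#' @return m/z in u (full precision; round to 4 decimals for reporting).
#' @examples
#' monoisotopic_mz("C16H17NO4", "M-3H")  # 284.0917, the THP-quinone ion
#' @export
monoisotopic_mz <- function(f, adduct = c("M", "M+H", "M-H", "M-3H")) {
  f <- as_formula(f)
  adduct <- match.arg(adduct)
  m <- monoisotopic_mass(f)
  h <- .monoisotopic_mass[["H"]]
  n_h_lost <- switch(adduct, "M" = 0L, "M+H" = -1L, "M-H" = 1L, "M-3H" = 3L)
  if (n_h_lost > 0L && (!"H" %in% names(f) || f[["H"]] < n_h_lost))
    stop(sprintf("adduct %s removes more hydrogens than the formula has",
                 adduct))
  switch(adduct,
         "M"    = m,
         "M+H"  = m + h - .electron_mass,
         "M-H"  = m - h + .electron_mass,
         "M-3H" = m - 3 * h - .electron_mass)
}

#' Convert a molar concentration to a mass concentration
#'
#' @param conc Concentration in µM (>= 0).
#' @inheritParams average_mass
#' @return Concentration in mg L^-1 (full precision; presentation
#'   rounding is the caller's choice).
#' @examples
#' umolar_to_mgL(9.45, "C16H17NO4")  # 2.71 mg/L at 3 significant figures
#' @export
umolar_to_mgL <- function(conc, f) {
  stopifnot(is.numeric(conc), all(conc >= 0))
  conc * average_mass(f) / 1000
}

#' @rdname umolar_to_mgL
#' @param mgL Concentration in mg L^-1.
#' @export
mgL_to_umolar <- function(mgL, f) {
  stopifnot(is.numeric(mgL), all(mgL >= 0))
  mgL * 1000 / average_mass(f)
}

#' Stoichiometric molar yield
#'
#' Percent conversion of substrate to product on a molar basis,
#' accounting for the stoichiometry: for THP, two L-DOPA molecules are
#' consumed per product (one via dopamine, one via DHPAA), so the
#' default `stoich = 2`.
#'
#' @param product_uM Product concentration (µM).
#' @param substrate_uM Substrate input (µM), > 0.
#' @param stoich Substrate molecules consumed per product molecule
#'   (>= 1, default 2).
#' @return Yield in percent (full precision).
#' @examples
#' molar_yield_pct(219, 1875)   # 23.36 -> printed as 23%
#' molar_yield_pct(9.45, 1000)  # 1.89%
#' @export
molar_yield_pct <- function(product_uM, substrate_uM, stoich = 2) {
  stopifnot(is.numeric(product_uM), is.numeric(substrate_uM),
            is.numeric(stoich), stoich >= 1)
  if (any(substrate_uM <= 0)) stop("substrate input must be > 0")
  100 * stoich * product_uM / substrate_uM
}

#' Fold change between two titers
#'
#' @param after,before Titers in the same units; `before` must be > 0.
#' @return The ratio `after / before`.
#' @examples
#' fold_change(1.5, 0.2)  # 7.5
#' @export
fold_change <- function(after, before) {
  stopifnot(is.numeric(after), is.numeric(before))
  if (any(before <= 0)) stop("'before' must be > 0")
  after / before
}
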