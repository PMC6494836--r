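## Seeded synthetic-data generators. Every generator is a pure function
## of its arguments including the seed, so fixtures are bit-identical
## across runs and platforms.

#' Generate a synthetic Michaelis-Menten rate dataset
#'
#' Emulates an H2O2-production rate assay: velocities on the MM curve
#' \eqn{v = k_{cat} E_0 S / (K_m + S)} with multiplicative Gaussian noise
#' (assay error in fluorometric rate data scales with signal) and
#' optional injected gross outliers. Defaults reproduce a wild-type
#' DHPAAS-like enzyme (Km 41.7 µM, kcat 6.51 min^-1).
#'
#' @param km Michaelis constant (µM).
#' @param kcat Turnover number (min^-1).
#' @param enzyme_conc Enzyme concentration; `vmax = kcat * enzyme_conc`.
#' @param substrate Substrate grid (µM). The default is 8 levels from
#'   Km/8 to 16 Km, duplicated (n = 16). The grid must span below Km/2
#'   and above 2 Km so both parameters are identifiable.
#' @param noise_cv Relative (CV) Gaussian noise, >= 0.
#' @param outliers Optional data frame with columns `index` and
#'   `multiplier`: rates at those indices are multiplied after noise.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A data frame `substrate, rate, replicate` of class
#'   `rate_dataset`, with the generating truth in attribute `"truth"`.
#' @export
gen_mm_dataset <- function(km = 41.7, kcat = 6.51, enzyme_conc = 1,
                           substrate = NULL, noise_cv = 0,
                           outliers = NULL, seed = NULL) {
  stopifnot(km > 0, kcat >= 0, enzyme_conc > 0, noise_cv >= 0)
  if (is.null(substrate))
    substrate <- rep(km * c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16), each = 2)
  if (!any(substrate < km / 2) || !any(substrate > 2 * km))
    stop("substrate grid must span below Km/2 and above 2*Km")
  if (!is.null(seed)) set.seed(as.integer(seed))
  vmax <- kcat * enzyme_conc
  v <- vmax * substrate / (km + substrate)
  if (noise_cv > 0)
    v <- v * (1 + stats::rnorm(length(v), 0, noise_cv))
  if (!is.null(outliers)) {
    stopifnot(is.data.frame(outliers),
              all(c("index", "multiplier") %in% names(outliers)),
              all(outliers$index >= 1), all(outliers$index <= length(v)))
    v[outliers$index] <- v[outliers$index] * outliers$multiplier
  }
  rep_id <- stats::ave(substrate, substrate, FUN = seq_along)
  structure(data.frame(substrate = substrate, rate = v,
                       replicate = as.integer(rep_id)),
            class = c("rate_dataset", "data.frame"),
            truth = list(km = km, kcat = kcat, enzyme_conc = enzyme_conc,
                         vmax = vmax, noise_cv = noise_cv,
                         outliers = outliers))
}

#' Generate a noisy observed trajectory with its ground truth
#'
#' Runs [simulate_pathway()] and samples the species concentrations at
#' the observation times with multiplicative Gaussian noise; both the
#' noise-free truth and the observations are returned, so recovery tests
#' never re-derive ground truth.
#'
#' @param spec A [pathway_spec()].
#' @param times Observation times (h), within the simulated horizon; the
#'   simulation grid is the union of these with 0.
#' @param noise_cv Relative observation noise, >= 0.
#' @param seed Integer seed.
#' @param initial Initial [pathway_state()].
#' @return A list with `truth` (the full `thp_trajectory`) and `obs`
#'   (data frame `t, S, DA, AL, THP` with noise applied).
#' @export
gen_trajectory_dataset <- function(spec, times, noise_cv = 0, seed = NULL,
                                   initial = pathway_state()) {
  stopifnot(is.numeric(times), all(times >= 0), noise_cv >= 0)
  grid <- sort(unique(c(0, times)))
  truth <- simulate_pathway(spec, initial = initial, times = grid)
  if (!is.null(seed)) set.seed(as.integer(seed))
  obs <- truth[truth$t %in% times, c("t", "S", "DA", "AL", "THP")]
  if (noise_cv > 0) {
    for (col in c("S", "DA", "AL", "THP"))
      obs[[col]] <- pmax(0, obs[[col]] *
                           (1 + stats::rnorm(nrow(obs), 0, noise_cv)))
  }
  rownames(obs) <- NULL
  list(truth = truth, obs = obs)
}

#' Generate a synthetic AAAD sequence family with planted triads
#'
#' Builds a random reference protein (a synthetic stand-in for a real
#' DHPAAS, carrying the F79-Y80-N192 triad) and `n` mutated copies. Each
#' copy gets a planted triad according to its assignment (`"DHPAAS"` =
#' F/Y/N, `"DDC"` = Y/F/H, `"mixed"` = Y/Y/N) and independent
#' substitutions at non-triad positions with the given per-site rate.
#' The expected classification of every copy is emitted alongside as a
#' truth table.
#'
#' @param n Number of family members.
#' @param ref_length Reference length (>= 192).
#' @param mutation_rate Per-site substitution probability in \[0, 1).
#' @param assignments Character vector (recycled to length `n`) over
#'   `"DHPAAS"`, `"DDC"`, `"mixed"`; default cycles through all three.
#' @param seed Integer seed.
#' @return A list with `reference` (string), `sequences` (named
#'   character vector) and `truth` (data frame `id, assignment, label`).
#' @export
gen_motif_family <- function(n = 200, ref_length = 250, mutation_rate = 0,
                             assignments = c("DHPAAS", "DDC", "mixed"),
                             seed = NULL) {
  if (ref_length < 192)
    stop("reference must be at least 192 residues long")
  stopifnot(n >= 1, mutation_rate >= 0, mutation_rate < 1,
            all(assignments %in% c("DHPAAS", "DDC", "mixed")))
  if (!is.null(seed)) set.seed(as.integer(seed))
  aa20 <- setdiff(.aa_alphabet, "X")
  triad_pos <- c(79L, 80L, 192L)
  triads <- list(DHPAAS = c("F", "Y", "N"), DDC = c("Y", "F", "H"),
                 mixed = c("Y", "Y", "N"))
  labels <- c(DHPAAS = "DHPAAS-like", DDC = "DDC-like",
              mixed = "intermediate")
  ref <- sample(aa20, ref_length, replace = TRUE)
  ref[triad_pos] <- triads$DHPAAS
  assignments <- rep_len(assignments, n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- ref
    if (mutation_rate > 0) {
      hit <- stats::runif(ref_length) < mutation_rate
      hit[triad_pos] <- FALSE   # triads are planted, not drifted
      for (j in which(hit)) s[j] <- sample(setdiff(aa20, s[j]), 1L)
    }
    s[triad_pos] <- triads[[assignments[i]]]
    seqs[i] <- paste(s, collapse = "")
  }
  ids <- sprintf("synth_%03d_%s", seq_len(n), assignments)
  names(seqs) <- ids
  list(reference = paste(ref, collapse = ""),
       sequences = seqs,
       truth = data.frame(id = ids, assignment = assignments,
                          label = unname(labels[assignments]),
                          stringsAsFactors = FALSE))
}

#' Default Monte-Carlo parameter ranges
#'
#' Returns the packaged stand-in range table used for the eight-scenario
#' ensemble grid. The ranges are literature-plausible magnitudes for the
#' DDC/MAO/DHPAAS enzymes and the spontaneous condensation and drain
#' constants (units mM, h); they are shipped as an editable CSV under
#' `inst/extdata/` and documented in the methods vignette.
#'
#' @param preset Preset name; currently `"fig2-grid"` (the scenario
#'   grid) and `"adversarial"` (degenerate/extreme ranges exercising
#'   error paths).
#' @param topology Which topology's ranges to return.
#' @param drain Include the DHPAA drain constant range?
#' @return A [param_ranges()] table.
#' @export
gen_default_ranges <- function(preset = "fig2-grid",
                               topology = c("MAO_PATH", "DDC_DHPAAS_PATH"),
                               drain = FALSE) {
  topology <- match.arg(topology)
  if (!preset %in% c("fig2-grid", "adversarial"))
    stop(sprintf("unknown preset '%s'", preset))
  if (preset == "adversarial") {
    return(param_ranges(c("k_cond", "feed_rate", "dhpaas.vmax"),
                        low = c(0, 0, 1e-6), high = c(0, 0, 1e-6),
                        scale = c("linear", "linear", "log")))
  }
  path <- system.file("extdata", "fig2_grid_ranges_synthetic.csv",
                      package = "thpkin", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- tab[tab$topology == topology, ]
  if (!drain) tab <- tab[tab$name != "k_drain", ]
  param_ranges(tab$name, tab$low, tab$high, tab$scale)
}

#' Build the eight-scenario ensemble grid
#'
#' Constructs the \{MAO, DDC-DHPAAS\} x \{drain on/off\} x
#' \{feedback on/off\} grid of [ensemble_spec()] objects used to compare
#' predicted THP yields across pathway designs, with the packaged
#' default ranges. Feed runs at a sampled constant rate up to the 100 mM
#' cap over a 50 h horizon.
#'
#' @param n_iter Iterations per scenario.
#' @param t_end Horizon (h).
#' @return A named list of 8 `ensemble_spec`s, ready for
#'   [compare_scenarios()].
#' @export
fig2_scenario_grid <- function(n_iter = 200, t_end = 50) {
  base_for <- function(topology, feedback) {
    if (topology == "MAO_PATH")
      pathway_spec("MAO_PATH",
                   ddc = enzyme_params(10, 0.1, ki = c(dopamine = 1)),
                   mao = enzyme_params(10, 0.2,
                                       ki = c(amine = 1, DHPAA = 1)),
                   k_cond = 1, feed_rate = 2, feed_cap = 100,
                   feedback = feedback, amine_pool = 10)
    else
      pathway_spec("DDC_DHPAAS_PATH",
                   ddc = enzyme_params(10, 0.1, ki = c(dopamine = 1)),
                   dhpaas = enzyme_params(10, 0.05,
                                          ki = c(dopamine = 1, DHPAA = 1)),
                   phi_aldehyde = 1, k_cond = 1, feed_rate = 2,
                   feed_cap = 100, feedback = feedback)
  }
  out <- list()
  for (topology in c("MAO_PATH", "DDC_DHPAAS_PATH")) {
    short <- if (topology == "MAO_PATH") "MAO" else "DDC-DHPAAS"
    for (drain in c(FALSE, TRUE)) for (feedback in c(FALSE, TRUE)) {
      label <- paste0(short,
                      if (drain) "+drain" else "",
                      if (feedback) "+feedback" else "")
      out[[label]] <- ensemble_spec(
        base_for(topology, feedback),
        gen_default_ranges("fig2-grid", topology, drain = drain),
        n_iter = n_iter, t_end = t_end)
    }
  }
  out
}
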