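make_single <- function(vmax = 10, km = 0.5, phi = 0.5, k_cond = 1, ...) {
  pathway_spec("SINGLE_DHPAAS_PATH",
               dhpaas = enzyme_params(vmax, km),
               phi_aldehyde = phi, k_cond = k_cond, ...)
}

test_that("DDC velocity follows competitive-inhibition Michaelis-Menten", {
  spec <- pathway_spec("DDC_DHPAAS_PATH",
                       ddc = enzyme_params(8, 2, ki = c(dopamine = 3)),
                       dhpaas = enzyme_params(1, 1))
  expect_equal(ddc_rate(pathway_state(S = 0, DA = 5), spec), 0)
  expect_equal(ddc_rate(pathway_state(S = 2), spec), 4)  # half saturation
  # S = 2*Km, feedback on, DA = Ki: Vmax*2Km/(2Km + 2Km) = Vmax/2
  spec_fb <- pathway_spec("DDC_DHPAAS_PATH",
                          ddc = enzyme_params(8, 2, ki = c(dopamine = 3)),
                          dhpaas = enzyme_params(1, 1), feedback = TRUE)
  expect_equal(ddc_rate(pathway_state(S = 4, DA = 3), spec_fb), 4)
  # feedback off: inhibitor ignored
  expect_equal(ddc_rate(pathway_state(S = 4, DA = 3), spec),
               8 * 4 / (2 + 4))
  expect_error(ddc_rate(pathway_state(S = 1), make_single()), "ddc")
})

test_that("MAO velocity includes the amine pool competitively", {
  mao_spec <- function(amine_pool = 0, feedback = FALSE)
    pathway_spec("MAO_PATH",
                 ddc = enzyme_params(1, 1),
                 mao = enzyme_params(6, 1.5, ki = c(amine = 2, DHPAA = 1)),
                 amine_pool = amine_pool, feedback = feedback)
  expect_equal(mao_rate(pathway_state(DA = 0), mao_spec()), 0)
  expect_equal(mao_rate(pathway_state(DA = 1.5), mao_spec()), 3)
  # DA = Km, amine_pool = Ki: Vmax*Km/(2Km + Km) = Vmax/3
  expect_equal(mao_rate(pathway_state(DA = 1.5), mao_spec(amine_pool = 2)),
               2)
  # feedback adds DHPAA inhibition on top
  r_fb <- mao_rate(pathway_state(DA = 1.5, AL = 1),
                   mao_spec(amine_pool = 2, feedback = TRUE))
  expect_equal(r_fb, 6 * 1.5 / (1.5 * (1 + 1 + 1) + 1.5))
  expect_error(mao_rate(pathway_state(DA = 1), make_single()), "MAO_PATH")
})

test_that("bifunctional DHPAAS splits one MM velocity by phi", {
  st <- pathway_state(S = 0.5)
  expect_equal(dhpaas_rates(st, make_single(phi = 1)),
               c(aldehyde = 5, decarboxylation = 0))
  expect_equal(dhpaas_rates(st, make_single(phi = 0)),
               c(aldehyde = 0, decarboxylation = 5))
  # saturation limit at the wild-type 95% partition
  r <- dhpaas_rates(pathway_state(S = 5000), make_single(phi = 0.95))
  expect_equal(unname(r[1L]), 0.95 * 10, tolerance = 1e-3)
  expect_equal(unname(r[2L]), 0.05 * 10, tolerance = 1e-3)
  expect_equal(sum(r), 10 * 5000 / (0.5 + 5000))
  expect_error(make_single(phi = 1.2), "phi_aldehyde")
  expect_error(make_single(phi = -0.1), "phi_aldehyde")
})

test_that("condensation is second-order mass action", {
  spec <- make_single(k_cond = 1)
  expect_equal(condensation_rate(pathway_state(DA = 0, AL = 3), spec), 0)
  expect_equal(condensation_rate(pathway_state(DA = 2, AL = 0), spec), 0)
  expect_equal(condensation_rate(pathway_state(DA = 2, AL = 3), spec), 6)
  r1 <- condensation_rate(pathway_state(DA = 1, AL = 1.5), spec)
  r2 <- condensation_rate(pathway_state(DA = 2, AL = 3), spec)
  expect_equal(r2, 4 * r1)
  expect_error(pathway_state(DA = -1), ">= 0")
})

test_that("feeding stops exactly at the cap", {
  spec <- make_single(vmax = 0, feed_rate = 4, feed_cap = 100)
  expect_equal(feed_term(pathway_state(fed = 0), spec), 4)
  expect_equal(feed_term(pathway_state(fed = 100), spec), 0)
  # integral over [0, 50] at 4 mM/h caps at exactly 100 mM (t = 25 h)
  spec2 <- pathway_spec("SINGLE_DHPAAS_PATH",
                        dhpaas = enzyme_params(0, 1),
                        feed_rate = 4, feed_cap = 100)
  traj <- simulate_pathway(spec2, t_end = 50)
  expect_equal(max(traj$fed), 100)
  expect_equal(traj$fed[traj$t == 25], 100)
  expect_equal(traj$fed[traj$t == 12.5], 50)
  expect_true(all(diff(traj$fed) >= 0))
})

test_that("null dynamics give a constant state", {
  spec <- pathway_spec("SINGLE_DHPAAS_PATH", dhpaas = enzyme_params(0, 1))
  traj <- simulate_pathway(spec, initial = pathway_state(S = 1, DA = 0.5),
                           t_end = 10, n_grid = 21)
  expect_equal(traj$S, rep(1, 21))
  expect_equal(traj$DA, rep(0.5, 21))
  expect_equal(traj$THP, rep(0, 21))
})

test_that("condensation-only model matches its closed form", {
  # dDA/dt = -k DA^2 when DA = AL: DA(t) = c0 / (1 + k c0 t)
  k <- 0.7; c0 <- 2
  spec <- pathway_spec("SINGLE_DHPAAS_PATH", dhpaas = enzyme_params(0, 1),
                       k_cond = k)
  traj <- simulate_pathway(spec, initial = pathway_state(DA = c0, AL = c0),
                           t_end = 20, n_grid = 11)
  analytic <- c0 / (1 + k * c0 * traj$t)
  expect_lt(max(abs(traj$DA - analytic) / analytic), 1e-5)
  expect_equal(traj$DA, traj$AL, tolerance = 1e-9)
})

random_spec <- function() {
  topology <- sample(c("MAO_PATH", "DDC_DHPAAS_PATH",
                       "SINGLE_DHPAAS_PATH"), 1L)
  ep <- function() enzyme_params(stats::runif(1, 0.5, 30),
                                 stats::runif(1, 0.02, 2),
                                 ki = c(dopamine = stats::runif(1, 0.1, 10),
                                        DHPAA = stats::runif(1, 0.1, 10),
                                        amine = stats::runif(1, 0.1, 10)))
  pathway_spec(topology,
               ddc = if (topology != "SINGLE_DHPAAS_PATH") ep(),
               mao = if (topology == "MAO_PATH") ep(),
               dhpaas = if (topology != "MAO_PATH") ep(),
               phi_aldehyde = stats::runif(1),
               k_cond = stats::runif(1, 0.05, 10),
               k_drain = sample(c(0, stats::runif(1, 0, 1)), 1L),
               feed_rate = stats::runif(1, 0, 4),
               feed_cap = 100,
               feedback = sample(c(TRUE, FALSE), 1L),
               amine_pool = stats::runif(1, 0, 10))
}

test_that("DOPA-equivalent conservation and monotonicity hold on random models", {
  set.seed(20260927)
  for (i in 1:25) {
    init <- pathway_state(S = stats::runif(1, 0, 5),
                          DA = stats::runif(1, 0, 1),
                          AL = stats::runif(1, 0, 1))
    traj <- simulate_pathway(random_spec(), initial = init, t_end = 50,
                             n_grid = 101)
    expect_lt(conservation_residual(traj), 1e-6)
    expect_true(all(diff(traj$THP) >= -1e-9))
    expect_true(all(diff(traj$fed) >= -1e-12))
    expect_true(all(diff(traj$drained) >= -1e-12))
    y <- thp_yield_pct(traj)
    expect_gte(y, 0)
    expect_lte(y, 100)
  }
})

test_that("complete condensation gives a 100% yield", {
  spec <- pathway_spec("SINGLE_DHPAAS_PATH", dhpaas = enzyme_params(0, 1),
                       k_cond = 50)
  traj <- simulate_pathway(spec, initial = pathway_state(DA = 1, AL = 1),
                           t_end = 2000, n_grid = 51)
  expect_equal(thp_yield_pct(traj), 100, tolerance = 0.05)
  # undefined on zero input
  empty <- simulate_pathway(spec, initial = pathway_state(), t_end = 1,
                            n_grid = 5)
  expect_error(thp_yield_pct(empty), "zero")
})

test_that("yield of the bifunctional pathway peaks at a balanced split", {
  phis <- seq(0.05, 0.95, by = 0.05)
  yields <- vapply(phis, function(phi) {
    spec <- pathway_spec("SINGLE_DHPAAS_PATH",
                         dhpaas = enzyme_params(4, 0.1),
                         phi_aldehyde = phi, k_cond = 2, feed_rate = 2)
    thp_yield_pct(simulate_pathway(spec, t_end = 50, n_grid = 51))
  }, numeric(1))
  expect_equal(phis[which.max(yields)], 0.5)
  # symmetric about 0.5 since dopamine and DHPAA enter symmetrically
  expect_equal(yields, rev(yields), tolerance = 1e-6)
})

test_that("topology validation rejects incomplete specs", {
  expect_error(pathway_spec("MAO_PATH", mao = enzyme_params(1, 1)), "ddc")
  expect_error(pathway_spec("MAO_PATH", ddc = enzyme_params(1, 1)), "mao")
  expect_error(pathway_spec("DDC_DHPAAS_PATH", ddc = enzyme_params(1, 1)),
               "dhpaas")
  expect_error(enzyme_params(-1, 1), "vmax")
  expect_error(enzyme_params(1, 0), "km")
  expect_error(enzyme_params(1, 1, ki = c(dopamine = -2)), "> 0")
})
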