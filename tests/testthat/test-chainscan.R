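test_that("radius of gyration matches closed forms and degenerate inputs", {
  b <- 3.8
  straight <- cbind((0:2) * b, 0, 0)
  expect_equal(radius_of_gyration(straight), sqrt(b^2 * (3^2 - 1) / 12))
  expect_equal(round(radius_of_gyration(straight), 4), 3.1027)
  coincident <- matrix(1.5, nrow = 4, ncol = 3)
  expect_equal(radius_of_gyration(coincident), 0)
  expect_error(radius_of_gyration(matrix(0, 1, 3)),
               class = "osmofret_domain_error")
})

test_that("freely jointed ensemble reproduces the ideal-chain Rg^2", {
  n <- 50; b <- 3.8
  rg2 <- vapply(1:3000, function(s) radius_of_gyration(fjc_chain(n, b, seed = s))^2, 0)
  target <- b^2 / 6 * (n^2 - 1) / n
  expect_lt(abs(mean(rg2) - target) / target, 0.05)
})

test_that("pairwise energies match formulas and vanish beyond all cutoffs", {
  m <- chain_model("KAK")
  cond <- solution_condition(0, debye_length = 10)
  far <- rbind(c(0, 0, 0), c(100, 100, 100), c(200, 0, 0))
  e <- chain_energy(far, m, cond)
  expect_equal(e$total, 0)
  expect_equal(e$u_lj, 0)
  expect_equal(e$w_el, 0, tolerance = 1e-9)
  # two +1 charges at r = debye length: w_el = (l_B / kappa_D) e^{-1}
  at_debye <- rbind(c(0, 0, 0), c(100, 100, 100), c(10, 0, 0))
  e2 <- chain_energy(at_debye, m, cond)
  expect_equal(e2$w_el, 7.1 / 10 * exp(-1))
  expect_error(chain_energy(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), m, cond),
               class = "osmofret_geometry_error")
})

test_that("chain energy equals an independent plain-R re-implementation", {
  m <- chain_model("MKEELRRASGDEPLKHSIDA")
  cond <- solution_condition(2, debye_length = 10)
  lambda_eff <- 2 * m$contact_eps
  for (s in 1:5) {
    conf <- fjc_chain(20, 3.8, seed = 200 + s)
    mine <- chain_energy(conf, m, cond)
    ref <- r_chain_energy(conf, m$charges, m$hydropathy, lambda_eff,
                          debye = 10, lB = 7.1, eps0 = m$eps0,
                          sigma = m$bead_diameter)
    expect_equal(mine$total, ref$total, tolerance = 1e-10)
    expect_equal(mine$u_lj, ref$u_lj, tolerance = 1e-10)
    expect_equal(mine$w_el, ref$w_el, tolerance = 1e-10)
    expect_equal(mine$w_solv, ref$w_solv, tolerance = 1e-10)
    expect_equal(mine$total, mine$w_solv + mine$u_lj + mine$w_el)
  }
})

test_that("Monte Carlo sampling is seed-deterministic with honest bookkeeping", {
  m <- chain_model("EKEKEKEKEKEK")
  cond <- solution_condition(1)
  e1 <- mc_sample_ensemble(m, cond, steps = 8000, equil = 2000,
                           snapshot_every = 50, n_repeats = 2, seed = 11)
  e2 <- mc_sample_ensemble(m, cond, steps = 8000, equil = 2000,
                           snapshot_every = 50, n_repeats = 2, seed = 11)
  expect_identical(e1$rg, e2$rg)
  expect_lt(e1$max_energy_drift, 1e-8)
  # distinct repeats explore distinct trajectories
  rg_wide <- tidyr::pivot_wider(e1$rg, names_from = "repeat_id",
                                values_from = "rg")
  expect_false(identical(rg_wide[[2]], rg_wide[[3]]))
})

test_that("a non-interacting chain accepts every proposal", {
  m0 <- chain_model("GGGGGGGG", bead_diameter = 1e-6, eps0 = 0)
  ens <- mc_sample_ensemble(m0, solution_condition(0), steps = 4000,
                            equil = 500, n_repeats = 1, seed = 2)
  expect_equal(ens$acceptance_rates, 1)
})

test_that("excluded volume swells the chain beyond the freely jointed limit", {
  n <- 50; b <- 3.8
  m <- chain_model(strrep("G", n), eps0 = 0)  # repulsive core only
  ens <- mc_sample_ensemble(m, solution_condition(0), steps = 4e4,
                            equil = 1e4, snapshot_every = 100,
                            n_repeats = 3, seed = 7)
  fjc_rg <- sqrt(b^2 / 6 * (n^2 - 1) / n)
  expect_gt(mean(ens$repeat_means), fjc_rg)
})

test_that("sampled ensemble matches a Boltzmann-reweighted direct oracle", {
  # independent route: weight freely jointed conformations by exp(-E) using
  # the plain-R energy, and compare the weighted mean Rg to the MC sampler
  m <- chain_model("EKEKEKEK")
  cond <- solution_condition(1)
  lambda_eff <- 1 * m$contact_eps
  set.seed(31)
  M <- 8000
  rg <- numeric(M); en <- numeric(M)
  for (i in seq_len(M)) {
    conf <- fjc_chain(8, 3.8, seed = 30000 + i)
    rg[i] <- radius_of_gyration(conf)
    en[i] <- r_chain_energy(conf, m$charges, m$hydropathy, lambda_eff,
                            sigma = m$bead_diameter)$total
  }
  w <- exp(-en)
  oracle_mean <- sum(w * rg) / sum(w)
  ens <- mc_sample_ensemble(m, cond, steps = 4e4, equil = 1e4,
                            snapshot_every = 25, n_repeats = 3, seed = 3)
  expect_lt(abs(mean(ens$repeat_means) - oracle_mean), 0.2)
})

test_that("solution scan normalizes to the most expanding condition", {
  m <- chain_model("GSEEKKDGSRAGSEDKKAGSTEGRKDLSGE")
  sc <- solution_scan(m, lambda_grid = c(0, 2, 8), steps = 3e4, equil = 8e3,
                      n_repeats = 3, seed = 5)
  expect_equal(max(sc$normalized_rg), 1)
  expect_equal(sc$normalized_rg, sc$mean_rg / max(sc$mean_rg))
  expect_true(all(diff(sc$mean_rg) < 0))  # compaction grows with lambda
  expect_equal(scan_sensitivity(sc), 1 - min(sc$normalized_rg))
  # determinism of the whole scan
  sc2 <- solution_scan(m, lambda_grid = c(0, 2, 8), steps = 3e4, equil = 8e3,
                       n_repeats = 3, seed = 5)
  expect_identical(as.data.frame(sc), as.data.frame(sc2))
  expect_error(solution_scan(m, lambda_grid = 2),
               class = "osmofret_invalid_parameter")
  expect_error(solution_scan(m, lambda_grid = c(1, 2)),
               class = "osmofret_invalid_parameter")
})
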