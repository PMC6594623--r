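test_that("ensemble bookkeeping: gap starts at the initial D and seeds are reproducible", {
  ens <- run_ensemble(c(0.5, 0.25, 0.25), N = 20, main_rates, n_reps = 30,
                      seed = 3, grid = seq(0, 4, 0.5))
  expect_equal(ens$gap$D_bar[1], 0.25)  # D(0) exact, zero variance
  expect_equal(ens$gap$se[1], 0)
  expect_equal(ens$n_reps, 30)
  ens2 <- run_ensemble(c(0.5, 0.25, 0.25), N = 20, main_rates, n_reps = 30,
                       seed = 3, grid = seq(0, 4, 0.5))
  expect_identical(ens$replicates, ens2$replicates)
  expect_identical(ens$D, ens2$D)

  td <- tidy(ens)
  expect_setequal(td$term, c("F_hat", "Tcons_mean"))
  expect_true(all(td$conf.high >= td$conf.low))
  g <- glance(ens)
  expect_true(g$F_hat >= 0 && g$F_hat <= 1)
})

test_that("an ensemble started at consensus is degenerate", {
  ens <- run_ensemble(c(0, 0, 1), N = 20, main_rates, n_reps = 10, seed = 1)
  expect_equal(ens$F_hat[["estimate"]], 1)
  expect_equal(ens$Tcons[["estimate"]], 0)
})

test_that("equalization fit recovers a noiseless exponential exactly", {
  grid <- seq(0, 10, 0.25)
  series <- tibble::tibble(t = grid, D_bar = -0.75 * exp(-0.3125 * grid))
  fit <- estimate_tequal(series)
  expect_equal(fit$T_equal[["estimate"]], 3.2, tolerance = 1e-10)
  expect_equal(fit$rate[["estimate"]], 0.3125, tolerance = 1e-10)
  expect_error(estimate_tequal(tibble::tibble(t = grid, D_bar = 0 * grid)),
               "nonzero")
})

test_that("equalization fit on simulated ensembles recovers 1 / (e + i) for both presets", {
  for (rates in list(main_rates, s2_rates)) {
    ens <- run_ensemble(c(0, 1, 0), N = 100, rates, n_reps = 400, seed = 29,
                        grid = seq(0, 10, 0.25), t_max = 10)
    fit <- estimate_tequal(ens, n_boot = 400)
    expect_true(ci_covers(fit$T_equal, equalization_time(rates)))
    expect_true(ci_covers(fit$rate, rates$e + rates$i))
  }
})

test_that("red-win fraction estimates the strength m independently of N", {
  ic <- c(0, 1, 0)  # m = 0.8
  for (N in c(25, 50, 100)) {
    ens <- run_ensemble(ic, N = N, main_rates, n_reps = 300, seed = 37 + N)
    expect_true(ci_covers(ens$F_hat, 0.8))
  }
})

test_that("red/blue symmetry: F(ic) + F(swapped ic) = 1 within CI", {
  ic <- c(0.25, 0.75, 0)
  e1 <- run_ensemble(ic, N = 50, main_rates, n_reps = 400, seed = 41)
  e2 <- run_ensemble(swap_ic(ic), N = 50, main_rates, n_reps = 400, seed = 43)
  s <- e1$F_hat[["estimate"]] + e2$F_hat[["estimate"]]
  half <- 1.96 * sqrt(0.65 * 0.35 / 400 + 0.35 * 0.65 / 400)
  expect_lt(abs(s - 1), half * 1.5)
})

test_that("mean consensus time scales linearly with N", {
  ic <- c(0.5, 0.5, 0)
  e25 <- run_ensemble(ic, N = 25, main_rates, n_reps = 300, seed = 47)
  e50 <- run_ensemble(ic, N = 50, main_rates, n_reps = 300, seed = 53)
  ratio <- e50$Tcons[["estimate"]] / e25$Tcons[["estimate"]]
  # delta-method SE of the ratio from the two mean SEs
  se_of <- function(ci) (ci[["conf.high"]] - ci[["estimate"]]) / 1.96
  se_ratio <- ratio * sqrt((se_of(e50$Tcons) / e50$Tcons[["estimate"]])^2 +
                           (se_of(e25$Tcons) / e25$Tcons[["estimate"]])^2)
  expect_lt(abs(ratio - 2), 3 * se_ratio)
})

test_that("consensus time depends on the initial state only through m", {
  # all-hypocrite versus all-frank initial conditions sharing m = 0.5
  e_hyp <- run_ensemble(c(0.5, 0.5, 0), N = 50, main_rates, n_reps = 400,
                        seed = 59)
  e_frank <- run_ensemble(c(0, 0, 0.5), N = 50, main_rates, n_reps = 400,
                          seed = 61)
  expect_true(intervals_overlap(
    e_hyp$Tcons[["conf.low"]], e_hyp$Tcons[["conf.high"]],
    e_frank$Tcons[["conf.low"]], e_frank$Tcons[["conf.high"]]))
})

test_that("attractor diagnostics: on-curve points have zero distance, gap equals layer gap", {
  z <- 0.25
  g <- attractor_hypocrite_fraction(z, main_rates)
  comp <- realize_composition(c(g, g, z), 16)  # (3, 3, 4) exactly on curve
  traj <- run_cvm(comp, main_rates, seed = 2)
  diag0 <- attractor_diagnostics(traj, main_rates)
  expect_lt(diag0$dist[diag0$t == 0], 1e-8)
  # the layer gap |rho_R - rho_r| is the hypocrite gap |D| by identity
  fr_gap <- abs((traj$n_Rb - traj$n_Br) / 16)
  rho_gap <- abs(((traj$n_Rb + traj$n_Rr) - (traj$n_Br + traj$n_Rr)) / 16)
  expect_identical(fr_gap, rho_gap)
})

test_that("ensembles collapse onto the attractor during the first stage", {
  seeds <- withr::with_seed(67, sample.int(1e8, 30))
  trajs <- lapply(seeds, function(s)
    run_cvm(realize_composition(c(0, 1, 0), 100), main_rates, seed = s,
            grid = c(0, 10), t_max = Inf, record_events = FALSE))
  d <- attractor_diagnostics(trajs, main_rates)
  expect_lt(d$dist[d$t == 10], 0.5 * d$dist[d$t == 0])
})

test_that("benchmark table assembles observed and predicted columns", {
  tab <- reproduce_table2("main", n_reps = 40, seed = 71, N = 50)
  expect_equal(nrow(tab), 12L)
  pred_F <- tab$predicted[tab$quantity == "F"]
  expect_equal(round(pred_F, 2), unname(table2_m))
  pred_T <- tab$predicted[tab$quantity == "T_cons"]
  # predicted consensus times at the overridden N scale as N / 400
  expect_equal(pred_T, unname(table2_Tcons) * 50 / 400, tolerance = 1e-4)
  expect_equal(unique(tab$predicted[tab$quantity == "T_equal"]), 3.2)
  expect_true(all(tab$observed[tab$quantity == "F"] >= 0 &
                    tab$observed[tab$quantity == "F"] <= 1))
  expect_s3_class(tab, "cvm_table2")
})
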