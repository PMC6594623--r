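test_that("transition channels match the count-based rate table", {
  # absorbing states emit no channels (total outflow 0)
  expect_equal(nrow(transition_rates(composition(0, 0, 10, N = 10), main_rates)), 0L)
  expect_equal(nrow(transition_rates(composition(0, 0, 0, N = 10), main_rates)), 0L)

  # all-Rb group: the public layer is uniformly red, so no copy flux; only
  # externalization (to Bb) and internalization (to Rr) remain
  N <- 8
  ch <- transition_rates(composition(N, 0, 0, N = N), main_rates)
  expect_equal(nrow(ch), 2L)
  ext <- ch[ch$n_Bb == 1L, ]
  int <- ch[ch$n_Rr == 1L, ]
  expect_equal(ext$rate, main_rates$e * N)
  expect_equal(int$rate, main_rates$i * N)

  # single hypocrite: channels {-> Bb at e, -> Rr at i}
  ch1 <- transition_rates(composition(1, 0, 0, N = 1), main_rates)
  expect_equal(sort(ch1$rate), sort(c(main_rates$e, main_rates$i)))

  # generic interior state: total outflow equals the hand-computed sum
  comp <- composition(3, 2, 4, N = 12)
  ch <- transition_rates(comp, main_rates)
  a <- 3; b <- 2; r <- 4; q <- 3; R <- a + r; B <- b + q; N <- 12
  with_rates <- main_rates
  expected_total <- with_rates$c * (a * B + b * R + r * B + q * R) / N +
    with_rates$e * (a + b) + with_rates$i * (a + b)
  expect_equal(sum(ch$rate), expected_total)
})

test_that("trajectories conserve N, start at t = 0, and stop at consensus", {
  traj <- run_cvm(composition(5, 5, 0, N = 10), main_rates, seed = 42)
  expect_equal(traj$t[1], 0)
  expect_true(all(diff(traj$t) > 0))
  expect_true(all(traj$n_Rb + traj$n_Br + traj$n_Rr + traj$n_Bb == 10L))
  expect_true(attr(traj, "terminal_status") %in% c("absorbed_red", "absorbed_blue"))
  final <- traj[nrow(traj), ]
  expect_true(final$n_Rb == 0 && final$n_Br == 0 &&
                final$n_Rr %in% c(0L, 10L))
  expect_equal(attr(traj, "t_end"), max(traj$t))

  # a consensus start absorbs immediately
  traj0 <- run_cvm(composition(0, 0, 10, N = 10), main_rates, seed = 1)
  expect_equal(attr(traj0, "t_end"), 0)
  expect_equal(attr(traj0, "terminal_status"), "absorbed_red")
})

test_that("identical seeds give identical trajectories", {
  a <- run_cvm(composition(4, 3, 2, N = 12), main_rates, seed = 99)
  b <- run_cvm(composition(4, 3, 2, N = 12), main_rates, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("single-agent hypocrite chain matches the two-branch solution", {
  # one Rb agent: first state change is -> Bb w.p. e/(e+i) (blue consensus)
  # or -> Rr w.p. i/(e+i) (red consensus), after Exp(e+i) time
  n <- 2000
  status <- character(n)
  t_end <- numeric(n)
  seeds <- withr::with_seed(7, sample.int(1e8, n))
  for (k in seq_len(n)) {
    tr <- run_cvm(composition(1, 0, 0, N = 1), main_rates, seed = seeds[k])
    status[k] <- attr(tr, "terminal_status")
    t_end[k] <- attr(tr, "t_end")
  }
  p_red <- mean(status == "absorbed_red")
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(p_red - 0.2), 1.96 * se * 1.5)
  expect_lt(abs(mean(t_end) - 3.2), 1.96 * sd(t_end) / sqrt(n) * 1.5)
})

test_that("i = 0 with a mixed private layer is refused without t_max", {
  frozen_rates <- rate_set(1, 1/4, 0)
  comp <- composition(0, 5, 0, N = 10)
  expect_error(run_cvm(comp, frozen_rates, seed = 1), "t_max")
  traj <- run_cvm(comp, frozen_rates, seed = 1, t_max = 5)
  expect_true(attr(traj, "terminal_status") %in% c("truncated", "frozen"))
  # uniform private layer with i = 0 still absorbs (single-layer dynamics)
  traj2 <- run_cvm(composition(3, 0, 0, N = 10), frozen_rates, seed = 2)
  expect_equal(attr(traj2, "terminal_status"), "absorbed_blue")
})

test_that("single-layer model reproduces neutral-drift fixation and Eq-1 times", {
  n <- 400
  seeds <- withr::with_seed(5, sample.int(1e8, n))
  wins <- logical(n); times <- numeric(n)
  for (k in seq_len(n)) {
    tr <- run_bvm(25, N = 50, c = 1, seed = seeds[k], record_events = FALSE)
    wins[k] <- attr(tr, "terminal_status") == "absorbed_red"
    times[k] <- attr(tr, "t_end")
  }
  expect_lt(abs(mean(wins) - 0.5), 1.96 * sqrt(0.25 / n) * 1.5)
  theo <- bvm_consensus_time(0.5, 50, 1)
  expect_lt(abs(mean(times) - theo), 1.96 * sd(times) / sqrt(n) * 1.5)
})

test_that("grid sampling is piecewise constant and persists beyond absorption", {
  traj <- run_cvm(composition(5, 5, 0, N = 10), main_rates, seed = 3)
  expect_error(sample_at(traj, -1), "nonnegative")
  s0 <- sample_at(traj, 0)
  expect_equal(c(s0$n_Rb, s0$n_Br, s0$n_Rr), c(5L, 5L, 0L))
  far <- sample_at(traj, attr(traj, "t_end") + 100)
  final <- traj[nrow(traj), ]
  expect_equal(far$n_Rr, final$n_Rr)
  # straddling the first event
  t1 <- traj$t[2]
  before <- sample_at(traj, t1 * 0.999)
  at <- sample_at(traj, t1)
  expect_equal(c(before$n_Rb, before$n_Br, before$n_Rr), c(5L, 5L, 0L))
  expect_equal(c(at$n_Rb, at$n_Br, at$n_Rr),
               c(traj$n_Rb[2], traj$n_Br[2], traj$n_Rr[2]))
  # grid recording inside the engine agrees with event-log resampling
  grid <- seq(0, attr(traj, "t_end"), length.out = 7)
  traj_g <- run_cvm(composition(5, 5, 0, N = 10), main_rates, seed = 3,
                    grid = grid, record_events = FALSE)
  resampled <- sample_at(traj, grid)
  for (col in c("n_Rb", "n_Br", "n_Rr")) {
    expect_equal(resampled[[col]], traj_g[[col]])
  }
})

test_that("ensemble mean of the strength m is conserved over time", {
  rates <- main_rates
  ic <- c(0.1, 0.6, 0.1)
  m0 <- strength_m(0.1 + 0.1, 0.6 + 0.1, rates)
  ens <- run_ensemble(ic, N = 50, rates, n_reps = 400, seed = 13,
                      grid = c(1, 5, 25), keep_grid_states = TRUE)
  gs <- ens$grid_states
  for (j in seq_along(c(1, 5, 25))) {
    rho_R <- (gs$n_Rb[, j] + gs$n_Rr[, j]) / 50
    rho_r <- (gs$n_Br[, j] + gs$n_Rr[, j]) / 50
    m_t <- strength_m(rho_R, rho_r, rates)
    se <- sd(m_t) / sqrt(length(m_t))
    expect_lt(abs(mean(m_t) - m0), 1.96 * se * 1.5)
  }
})

test_that("agent-based reference agrees with the Gillespie engine in the mean", {
  comp <- composition(5, 5, 0, N = 10)
  n <- 600
  seeds <- withr::with_seed(17, sample.int(1e8, 2 * n))
  t_agent <- vapply(seq_len(n), function(k)
    run_cvm_agent(comp, main_rates, seed = seeds[k])$t_end, numeric(1))
  t_gill <- vapply(seq_len(n), function(k) {
    tr <- run_cvm(comp, main_rates, seed = seeds[n + k], record_events = FALSE)
    attr(tr, "t_end")
  }, numeric(1))
  se <- sqrt(var(t_agent) / n + var(t_gill) / n)
  expect_lt(abs(mean(t_agent) - mean(t_gill)), 3 * se)
})
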