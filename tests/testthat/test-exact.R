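test_that("state enumeration has size choose(N + 3, 3)", {
  expect_equal(nrow(enumerate_states(1)), 4L)
  expect_equal(nrow(enumerate_states(2)), 10L)
  expect_equal(nrow(enumerate_states(20)), 1771L)
  st <- enumerate_states(3)
  expect_true(all(st$n_Rb + st$n_Br + st$n_Rr + st$n_Bb == 3L))
  expect_equal(nrow(dplyr::distinct(st)), nrow(st))
})

test_that("generator rows sum to zero and consensus rows are identically zero", {
  for (rates in list(main_rates, s2_rates)) {
    gen <- build_generator(5, rates)
    expect_lt(max(abs(Matrix::rowSums(gen))), 1e-12)
    st <- attr(gen, "states")
    red <- which(st$n_Rr == 5L)
    blue <- which(st$n_Bb == 5L)
    expect_equal(max(abs(gen[red, ])), 0)
    expect_equal(max(abs(gen[blue, ])), 0)
  }
  # single-agent generator: Rb row has off-diagonals e (to Bb) and i (to Rr)
  gen1 <- build_generator(1, main_rates)
  st1 <- attr(gen1, "states")
  rb <- which(st1$n_Rb == 1L); bb <- which(st1$n_Bb == 1L)
  rr <- which(st1$n_Rr == 1L)
  expect_equal(gen1[rb, bb], main_rates$e)
  expect_equal(gen1[rb, rr], main_rates$i)
  expect_equal(gen1[rb, rb], -(main_rates$e + main_rates$i))
})

test_that("exact absorption matches hand-solved small chains", {
  sol1 <- exact_solution(1, main_rates)
  rb <- which(sol1$n_Rb == 1L)
  expect_equal(sol1$p_red[rb], 0.2)
  expect_equal(sol1$t_mean[rb], 3.2)
  expect_equal(sol1$t_mean[sol1$n_Rr == 1L], 0)
  expect_equal(sol1$t_mean[sol1$n_Bb == 1L], 0)

  sol2 <- exact_solution(2, main_rates)
  sym <- which(sol2$n_Rb == 1L & sol2$n_Br == 1L)
  expect_equal(sol2$p_red[sym], 0.5)
})

test_that("absorption probability equals the martingale strength at every state", {
  rate_grid <- list(main_rates, s2_rates, rate_set(0.5, 1, 0.3),
                    rate_set(2, 0.05, 0.8), rate_set(1, 0, 0.5))
  for (rates in rate_grid) {
    for (N in c(3, 7, 10)) {
      sol <- exact_solution(N, rates)
      expect_lt(max(abs(sol$p_red - sol$m)), 1e-10)
    }
  }
})

test_that("mean absorption times are red/blue symmetric", {
  sol <- exact_solution(6, main_rates)
  key <- function(a, b, r, q) paste(a, b, r, q)
  lut <- setNames(sol$t_mean, key(sol$n_Rb, sol$n_Br, sol$n_Rr, sol$n_Bb))
  swapped <- lut[key(sol$n_Br, sol$n_Rb, sol$n_Bb, sol$n_Rr)]
  expect_equal(unname(swapped), sol$t_mean)
})

test_that("i = 0 is refused by the exact solver", {
  expect_error(exact_solution(4, rate_set(1, 1/4, 0)), "i > 0")
})

test_that("exact mean times approach the large-N closed form", {
  ratios <- vapply(c(10, 20, 30, 40), function(N) {
    sol <- exact_solution(N, main_rates)
    start <- which(sol$n_Br == N)  # all publicly-blue hypocrites
    sol$t_mean[start] / cvm_consensus_time(0.8, N, main_rates)
  }, numeric(1))
  # the closed form is a large-N result: the exact time exceeds it by a
  # finite-size margin (< 10% here) that shrinks monotonically beyond N = 20
  expect_true(all(ratios > 1))
  expect_true(all(ratios < 1.10))
  expect_true(all(diff(ratios[-1]) < 0))
})

test_that("mean-field drift vanishes at consensus and contracts the gap at rate e + i", {
  expect_equal(unname(mean_field_drift(c(0, 0, 1), main_rates)), c(0, 0, 0))
  expect_equal(unname(mean_field_drift(c(0, 0, 0), main_rates)), c(0, 0, 0))
  set.seed(31)
  for (k in 1:100) {
    fr <- runif(3); fr <- fr / sum(fr) * runif(1)  # random valid fractions
    rates <- rate_set(runif(1, 0.1, 3), runif(1, 0, 2), runif(1, 0, 2))
    d <- mean_field_drift(fr, rates)
    D <- fr[1] - fr[2]
    expect_equal(unname(d[1] - d[2]), -(rates$e + rates$i) * D,
                 tolerance = 1e-12)
  }
})

test_that("mean-field drift is tangent to the attractor curve", {
  for (rates in list(main_rates, s2_rates, rate_set(0.7, 0.4, 0.15))) {
    for (z in c(0.05, 0.25, 0.5, 0.9)) {
      g <- attractor_hypocrite_fraction(z, rates)
      v <- mean_field_drift(c(g, g, z), rates)
      # tangent direction of s -> (g(s), g(s), s)
      h <- 1e-6
      gp <- (attractor_hypocrite_fraction(z + h, rates) -
               attractor_hypocrite_fraction(z - h, rates)) / (2 * h)
      tangent <- c(gp, gp, 1); tangent <- tangent / sqrt(sum(tangent^2))
      normal_comp <- v - sum(v * tangent) * tangent
      expect_lt(sqrt(sum(normal_comp^2)), 1e-7)
    }
  }
  # exact interior point: normal component at machine precision
  v <- mean_field_drift(c(0.1875, 0.1875, 0.25), main_rates)
  slope <- cvoter:::attractor_slope(0.25, main_rates)
  tangent <- c(slope, slope, 1); tangent <- tangent / sqrt(sum(tangent^2))
  expect_lt(sqrt(sum((v - sum(v * tangent) * tangent)^2)), 1e-10)
})

test_that("exact mean times match stochastic ensemble means", {
  sol <- exact_solution(10, main_rates)
  comp <- composition(5, 5, 0, N = 10)
  idx <- which(sol$n_Rb == 5L & sol$n_Br == 5L & sol$n_Rr == 0L)
  n <- 1000
  seeds <- withr::with_seed(23, sample.int(1e8, n))
  times <- vapply(seq_len(n), function(k) {
    attr(run_cvm(comp, main_rates, seed = seeds[k], record_events = FALSE),
         "t_end")
  }, numeric(1))
  half <- 1.96 * sd(times) / sqrt(n)
  expect_lt(abs(mean(times) - sol$t_mean[idx]), half * 1.5)
})
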