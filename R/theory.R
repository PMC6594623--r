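#' Strength of the red opinion (martingale consensus probability)
#'
#' The strength `m = (i * rho_R + e * rho_r) / (e + i)` weighs the public and
#' private abundances of red by the rates that carry information between the
#' layers. Because the expected value of `m` is conserved by the dynamics
#' (it is a martingale of the process), `m` evaluated at the initial state
#' equals the probability that the eventual consensus is red. It depends on
#' neither the copy rate `c` nor the group size `N`.
#'
#' `m` remains well defined at `i = 0` (the martingale argument still holds)
#' even though the consensus-time formulas diverge there.
#'
#' @param rho_R fraction of publicly red individuals, in \[0, 1\]; vectorized.
#' @param rho_r fraction of privately red individuals, in \[0, 1\]; vectorized.
#' @param rates a [rate_set()] with `e + i > 0`.
#' @return The red-consensus probability, in \[0, 1\].
#' @examples
#' rates <- rate_set(1, 1/4, 1/16)
#' strength_m(0, 1, rates)       # all privately red: 0.80
#' strength_m(0.75, 0.5, rates)  # 0.55
#' @export
strength_m <- function(rho_R, rho_r, rates) {
  rates <- as_rate_set(rates)
  if (rates$e + rates$i <= 0) {
    stop("strength_m is undefined when e = i = 0 (no coupling between layers)",
         call. = FALSE)
  }
  stopifnot(all(rho_R >= 0 & rho_R <= 1), all(rho_r >= 0 & rho_r <= 1))
  (rates$i * rho_R + rates$e * rho_r) / (rates$e + rates$i)
}

#' Mean consensus time of the basic (single-layer) voter model
#'
#' On the complete graph with self-links, a group of `N` individuals with an
#' initial fraction `rho_R` of reds reaches consensus after a mean time
#' `-(N / c) * (rho * log(rho) + (1 - rho) * log(1 - rho))`, the classic
#' entropy-shaped first-passage time of neutral drift. The removable
#' singularity at the boundaries is handled by the convention
#' `0 * log(0) = 0`, so the time is exactly 0 at `rho_R` 0 or 1. The formula
#' is symmetric under swapping red and blue (`rho_R <-> 1 - rho_R`).
#'
#' @param rho_R initial fraction of reds, in \[0, 1\]; vectorized.
#' @param N group size.
#' @param c copy rate.
#' @return Mean consensus time, in the time units of `1 / c`.
#' @examples
#' bvm_consensus_time(0.5, N = 400, c = 1)  # 400 * log(2)
#' @export
bvm_consensus_time <- function(rho_R, N, c) {
  stopifnot(all(rho_R >= 0 & rho_R <= 1), N >= 1, c > 0)
  -(N / c) * xlogx(rho_R) - (N / c) * xlogx(1 - rho_R)
}

# x*log(x) with the removable singularity at 0 closed by continuity
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

#' Consensus-time slowdown factor of the concealed voter model
#'
#' The ratio of the mean consensus time of the two-layer model to that of
#' the single-layer model with the same `N` and `c`:
#' `tau = (c + e + i) * (e + i)^2 / (i * ((e + i)^2 + c * i))`.
#' `tau > 1` whenever `e > 0`: the possibility of hypocrisy always delays
#' consensus. As `i -> Inf` the private layer tracks the public one
#' instantly and `tau -> 1`; as `i -> 0` the private layer freezes and the
#' consensus time diverges, so `i = 0` is rejected.
#'
#' @param rates a [rate_set()] with `i > 0`.
#' @return Dimensionless slowdown factor, `>= 1`.
#' @examples
#' slowdown_tau(rate_set(1, 1/4, 1/16))  # about 12.8
#' @export
slowdown_tau <- function(rates) {
  rates <- as_rate_set(rates)
  if (rates$i <= 0) {
    stop(paste("slowdown_tau diverges at i = 0: the private layer is frozen",
               "and the mean consensus time is infinite"), call. = FALSE)
  }
  ei <- rates$e + rates$i
  (rates$c + ei) * ei^2 / (rates$i * (ei^2 + rates$c * rates$i))
}

#' Mean consensus time of the concealed voter model
#'
#' For a large group, the mean consensus time depends on the initial state
#' only through the strength `m`:
#' `T = -N * (c + e + i) * (e + i)^2 / (c * i * ((e + i)^2 + c * i)) *
#' (m log m + (1 - m) log(1 - m))`, which is exactly the single-layer
#' consensus time evaluated at `rho_R = m`, multiplied by the slowdown
#' factor [slowdown_tau()].
#'
#' @param m initial strength of red, in \[0, 1\]; vectorized. Usually
#'   computed with [strength_m()].
#' @param N group size.
#' @param rates a [rate_set()] with `i > 0`.
#' @return Mean consensus time.
#' @examples
#' rates <- rate_set(1, 1/4, 1/16)
#' cvm_consensus_time(0.8, N = 400, rates)  # about 2563.0
#' @export
cvm_consensus_time <- function(m, N, rates) {
  rates <- as_rate_set(rates)
  if (rates$i <= 0) {
    stop("cvm_consensus_time is infinite at i = 0 (frozen private layer)",
         call. = FALSE)
  }
  stopifnot(all(m >= 0 & m <= 1))
  slowdown_tau(rates) * bvm_consensus_time(m, N, rates$c)
}

#' Hypocrite abundance on the attractor of the mean-field flow
#'
#' The deterministic (large-N) flow of the fractions collapses trajectories
#' onto an arch-shaped curve along which the two hypocrite types are equally
#' abundant. Parameterized by the frank-red fraction `rho_Rr`, the curve is
#' `rho_Rb = rho_Br = (sqrt((e + i)^2 + 4 c (c + e + i) rho_Rr) - (e + i)) /
#' (2 c) - rho_Rr`. It vanishes at both endpoints (`rho_Rr` 0 and 1, the two
#' consensus states) and is nonnegative in between.
#'
#' @param rho_Rr frank-red fraction, in \[0, 1\]; vectorized.
#' @param rates a [rate_set()].
#' @return The common hypocrite fraction `rho_Rb = rho_Br` on the curve.
#' @examples
#' attractor_hypocrite_fraction(0.25, rate_set(1, 1/4, 1/16))  # 0.1875
#' @export
attractor_hypocrite_fraction <- function(rho_Rr, rates) {
  rates <- as_rate_set(rates)
  stopifnot(all(rho_Rr >= 0 & rho_Rr <= 1))
  ei <- rates$e + rates$i
  (sqrt(ei^2 + 4 * rates$c * (rates$c + ei) * rho_Rr) - ei) /
    (2 * rates$c) - rho_Rr
}

# d(rho_Rb)/d(rho_Rr) along the attractor; used for tangency checks
attractor_slope <- function(rho_Rr, rates) {
  rates <- as_rate_set(rates)
  ei <- rates$e + rates$i
  (rates$c + ei) / sqrt(ei^2 + 4 * rates$c * (rates$c + ei) * rho_Rr) - 1
}

#' Expected hypocrite gap at time t
#'
#' The ensemble mean of the gap `D = rho_Rb - rho_Br` between the two
#' hypocrite types decays exponentially at rate `e + i`, independently of
#' `c` and `N`: `mean D(t) = D0 * exp(-(e + i) * t)`. By the identity
#' `D = rho_R - rho_r` the same law governs the gap between the public and
#' private abundances of red.
#'
#' @param t time, nonnegative; vectorized.
#' @param D0 initial gap `rho_Rb(0) - rho_Br(0)`.
#' @param rates a [rate_set()].
#' @return Expected gap at time `t`.
#' @export
mean_gap <- function(t, D0, rates) {
  rates <- as_rate_set(rates)
  stopifnot(all(t >= 0))
  D0 * exp(-(rates$e + rates$i) * t)
}

#' Equalization time of the two hypocrite types
#'
#' The e-folding time of the expected hypocrite gap, `T_equal = 1 / (e + i)`.
#' It depends on neither `N`, `c`, nor the initial condition, and is
#' typically orders of magnitude shorter than the consensus time: the fast
#' first stage of consensus formation (collapse onto the attractor) versus
#' the slow second stage (random walk along it).
#'
#' @param rates a [rate_set()] with `e + i > 0`.
#' @return Equalization time, in the same time units as the rates.
#' @examples
#' equalization_time(rate_set(1, 1/4, 1/16))  # 3.2
#' @export
equalization_time <- function(rates) {
  rates <- as_rate_set(rates)
  if (rates$e + rates$i <= 0) {
    stop("equalization_time is undefined when e = i = 0", call. = FALSE)
  }
  1 / (rates$e + rates$i)
}

#' Closed-form predictions for a given initial condition
#'
#' Bundles every closed-form quantity for one parameter set and initial
#' condition: the strength `m` (red-consensus probability), the single-layer
#' consensus time evaluated at `m`, the slowdown factor `tau`, the two-layer
#' consensus time `T_cvm = tau * T_bvm(m)`, and the equalization time.
#'
#' @param ic an [initial_condition()] (or numeric triple
#'   `(rho_Rb, rho_Br, rho_Rr)`).
#' @param N group size the time predictions refer to.
#' @param rates a [rate_set()] with `i > 0`.
#' @return A one-row tibble of class `cvm_theory` with columns `N`, `c`,
#'   `e`, `i`, `rho_Rb`, `rho_Br`, `rho_Rr`, `m`, `T_bvm`, `tau`, `T_cvm`,
#'   `T_equal`.
#' @examples
#' theory_prediction(initial_condition(0, 1, 0), N = 400, rate_set(1, 1/4, 1/16))
#' @export
theory_prediction <- function(ic, N, rates) {
  ic <- as_initial_condition(ic)
  rates <- as_rate_set(rates)
  rho_R <- ic$rho_Rb + ic$rho_Rr
  rho_r <- ic$rho_Br + ic$rho_Rr
  m <- strength_m(rho_R, rho_r, rates)
  out <- tibble(
    N = as.integer(N), c = rates$c, e = rates$e, i = rates$i,
    rho_Rb = ic$rho_Rb, rho_Br = ic$rho_Br, rho_Rr = ic$rho_Rr,
    m = m,
    T_bvm = bvm_consensus_time(m, N, rates$c),
    tau = slowdown_tau(rates),
    T_cvm = cvm_consensus_time(m, N, rates),
    T_equal = equalization_time(rates)
  )
  class(out) <- c("cvm_theory", class(out))
  out
}
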