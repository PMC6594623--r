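#' Enumerate all compositions of a group of size N
#'
#' Lexicographic enumeration of the `choose(N + 3, 3)` states
#' `(n_Rb, n_Br, n_Rr)` with nonnegative entries summing to at most `N`
#' (`n_Bb` implied). The row order is the canonical state index used by
#' [build_generator()] and [exact_solution()].
#'
#' @param N group size.
#' @return A tibble with columns `n_Rb`, `n_Br`, `n_Rr`, `n_Bb`.
#' @examples
#' nrow(enumerate_states(2))  # 10
#' @export
enumerate_states <- function(N) {
  stopifnot(N >= 1, N == round(N))
  N <- as.integer(N)
  grid <- expand.grid(n_Rr = 0:N, n_Br = 0:N, n_Rb = 0:N)[, 3:1]
  grid <- grid[rowSums(grid) <= N, , drop = FALSE]
  grid <- grid[order(grid$n_Rb, grid$n_Br, grid$n_Rr), , drop = FALSE]
  out <- as_tibble(grid)
  out$n_Bb <- N - out$n_Rb - out$n_Br - out$n_Rr
  out
}

state_key <- function(a, b, r, N) {
  (a * (N + 1) + b) * (N + 1) + r
}

#' Infinitesimal generator of the count-based chain
#'
#' Builds the sparse transition-rate matrix over all states of
#' [enumerate_states()]: off-diagonal entries are the channel rates of
#' [transition_rates()] applied to every state, the diagonal is minus the
#' row sum, and consensus states have identically zero rows (absorbing).
#'
#' @param N group size.
#' @param rates a [rate_set()].
#' @return A sparse `dgCMatrix` of dimension `choose(N + 3, 3)` squared,
#'   with the state table attached as attribute `states`.
#' @export
build_generator <- function(N, rates) {
  rates <- as_rate_set(rates)
  st <- enumerate_states(N)
  S <- nrow(st)
  keys <- state_key(st$n_Rb, st$n_Br, st$n_Rr, N)
  idx_of <- integer(max(keys) + 1L)
  idx_of[keys + 1L] <- seq_len(S)
  a <- st$n_Rb; b <- st$n_Br; r <- st$n_Rr; q <- st$n_Bb
  R <- a + r; B <- b + q
  # per-channel (target-delta, rate) across all states, matching
  # transition_rates(); channels sharing a target merge via sparseMatrix's
  # summing of duplicate triplets
  chan <- list(
    list(d = c(-1L, 0L, 0L), rate = rates$c * a * B / N + rates$e * a),
    list(d = c(0L, -1L, 1L), rate = rates$c * b * R / N + rates$e * b),
    list(d = c(0L, 1L, -1L), rate = rates$c * r * B / N),
    list(d = c(1L, 0L, 0L),  rate = rates$c * q * R / N),
    list(d = c(-1L, 0L, 1L), rate = rates$i * a),
    list(d = c(0L, -1L, 0L), rate = rates$i * b)
  )
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (ch in chan) {
    keep <- which(ch$rate > 0)
    if (!length(keep)) next
    tk <- state_key(a[keep] + ch$d[1L], b[keep] + ch$d[2L],
                    r[keep] + ch$d[3L], N)
    ii <- c(ii, keep)
    jj <- c(jj, idx_of[tk + 1L])
    xx <- c(xx, ch$rate[keep])
  }
  gen <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(S, S))
  Matrix::diag(gen) <- Matrix::diag(gen) - Matrix::rowSums(gen)
  attr(gen, "states") <- st
  gen
}

consensus_indices <- function(states) {
  red <- which(states$n_Rb == 0 & states$n_Br == 0 & states$n_Bb == 0)
  blue <- which(states$n_Rb == 0 & states$n_Br == 0 & states$n_Rr == 0)
  list(red = red, blue = blue)
}

#' Exact absorption probabilities and mean absorption times
#'
#' Solves the absorbing Markov chain exactly for small groups: for every
#' state, the probability `p_red` that the chain is absorbed in the red
#' consensus (the linear system `Q_t p = -rates into red consensus` on the
#' transient states, with boundary values 1 at red and 0 at blue consensus)
#' and the mean absorption time `t_mean` (`Q_t t = -1`, 0 at both consensus
#' states). These are the independent oracle against which the closed-form
#' strength (martingale) and consensus-time formulas and the stochastic
#' engine are verified.
#'
#' Requires `i > 0`; with a frozen private layer (`i = 0`) absorption from
#' mixed private states is impossible and the transient system is singular.
#'
#' @param N group size (dense solve; intended for `N` up to a few tens).
#' @param rates a [rate_set()] with `i > 0`.
#' @return An object of class `cvm_exact`: a tibble with the state columns,
#'   `rho_R`, `rho_r`, `m` (closed-form strength), `p_red` and `t_mean`,
#'   with `N` and the rates as attributes.
#' @examples
#' sol <- exact_solution(2, rate_set(1, 1/4, 1/16))
#' max(abs(sol$p_red - sol$m))  # martingale: ~1e-16
#' @export
exact_solution <- function(N, rates) {
  rates <- as_rate_set(rates)
  if (!rates$ergodic) {
    stop(paste("exact_solution requires i > 0: with a frozen private layer,",
               "absorption from mixed private states is impossible and the",
               "transient system is singular"), call. = FALSE)
  }
  gen <- build_generator(N, rates)
  st <- attr(gen, "states")
  S <- nrow(st)
  cons <- consensus_indices(st)
  trans <- setdiff(seq_len(S), c(cons$red, cons$blue))
  Qt <- gen[trans, trans, drop = FALSE]
  r_red <- gen[trans, cons$red, drop = FALSE]

  p <- numeric(S)
  p[cons$red] <- 1
  p[trans] <- as.numeric(Matrix::solve(Qt, -r_red))

  t_mean <- numeric(S)
  t_mean[trans] <- as.numeric(Matrix::solve(Qt, rep(-1, length(trans))))

  rho_R <- (st$n_Rb + st$n_Rr) / N
  rho_r <- (st$n_Br + st$n_Rr) / N
  out <- dplyr::bind_cols(st, tibble(
    rho_R = rho_R, rho_r = rho_r,
    m = strength_m(rho_R, rho_r, rates),
    p_red = p, t_mean = t_mean
  ))
  structure(out, class = c("cvm_exact", class(out)),
            N = N, rates = rates)
}

#' Absorption probabilities for every state (exact)
#'
#' @param N group size.
#' @param rates a [rate_set()] with `i > 0`.
#' @return Numeric vector of red-consensus probabilities in state order.
#' @seealso [exact_solution()] for the full table.
#' @export
absorption_probability <- function(N, rates) {
  exact_solution(N, rates)$p_red
}

#' Mean absorption (consensus) times for every state (exact)
#'
#' @inheritParams absorption_probability
#' @return Numeric vector of mean first-passage times to consensus.
#' @export
mean_absorption_time <- function(N, rates) {
  exact_solution(N, rates)$t_mean
}

#' Mean-field drift of the composition fractions
#'
#' The deterministic large-N flow obtained by taking expectations of the
#' per-capita net flux of each channel. With `x = rho_Rb`, `y = rho_Br`,
#' `z = rho_Rr`, `w = rho_Bb`, `rho_R = x + z` and `rho_B = y + w`:
#' `dx/dt = c w rho_R - c x rho_B - (e + i) x`,
#' `dy/dt = c z rho_B - c y rho_R - (e + i) y`,
#' `dz/dt = c y rho_R + e y + i x - c z rho_B`.
#' The hypocrite gap obeys `d(x - y)/dt = -(e + i)(x - y)` identically, and
#' the flow is tangent to the attractor curve of
#' [attractor_hypocrite_fraction()].
#'
#' @param fractions numeric triple `(rho_Rb, rho_Br, rho_Rr)` or an
#'   [initial_condition()].
#' @param rates a [rate_set()].
#' @return Named numeric vector `c(d_rho_Rb, d_rho_Br, d_rho_Rr)`.
#' @examples
#' mean_field_drift(c(0.1875, 0.1875, 0.25), rate_set(1, 1/4, 1/16))
#' @export
mean_field_drift <- function(fractions, rates) {
  ic <- as_initial_condition(fractions)
  rates <- as_rate_set(rates)
  x <- ic$rho_Rb; y <- ic$rho_Br; z <- ic$rho_Rr
  w <- 1 - x - y - z
  rho_R <- x + z; rho_B <- y + w
  ei <- rates$e + rates$i
  c(d_rho_Rb = rates$c * w * rho_R - rates$c * x * rho_B - ei * x,
    d_rho_Br = rates$c * z * rho_B - rates$c * y * rho_R - ei * y,
    d_rho_Rr = rates$c * y * rho_R + rates$e * y + rates$i * x -
      rates$c * z * rho_B)
}

#' @export
#' @method print cvm_exact
print.cvm_exact <- function(x, ...) {
  cat(sprintf("<cvm_exact> N = %d (%d states), c = %g, e = %g, i = %g\n",
              attr(x, "N"), nrow(x), attr(x, "rates")$c,
              attr(x, "rates")$e, attr(x, "rates")$i))
  NextMethod()
}

#' @export
glance.cvm_exact <- function(x, ...) {
  tibble(
    N = attr(x, "N"), n_states = nrow(x),
    max_abs_p_minus_m = max(abs(x$p_red - x$m)),
    max_t_mean = max(x$t_mean)
  )
}
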