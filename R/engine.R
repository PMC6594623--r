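#' State-changing transition channels of a composition
#'
#' Enumerates the channels of the count-based continuous-time chain from a
#' given composition, with copy channels sharing a target merged into one
#' row. With counts `a = n_Rb`, `b = n_Br`, `r = n_Rr`, `q = n_Bb` and layer
#' totals `R = a + r` (publicly red), `B = b + q`, the channels are
#' `Rb -> Bb` at `c a B / N + e a`, `Br -> Rr` at `c b R / N + e b`,
#' `Rr -> Br` at `c r B / N`, `Bb -> Rb` at `c q R / N`, `Rb -> Rr` at
#' `i a`, and `Br -> Bb` at `i b`. Channels with rate 0 are dropped, so a
#' consensus state returns an empty table (it is absorbing).
#'
#' @param comp a [composition()].
#' @param rates a [rate_set()].
#' @return A tibble with columns `channel`, `n_Rb`, `n_Br`, `n_Rr`, `n_Bb`
#'   (the target composition) and `rate`.
#' @examples
#' transition_rates(composition(1, 0, 0, N = 1), rate_set(1, 1/4, 1/16))
#' @export
transition_rates <- function(comp, rates) {
  stopifnot(inherits(comp, "composition"))
  rates <- as_rate_set(rates)
  a <- comp$n_Rb; b <- comp$n_Br; r <- comp$n_Rr; q <- comp$n_Bb
  N <- comp$N
  R <- a + r; B <- b + q
  ch <- tibble(
    channel = c("Rb>Bb", "Br>Rr", "Rr>Br", "Bb>Rb", "Rb>Rr", "Br>Bb"),
    d_Rb = c(-1L, 0L, 0L, 1L, -1L, 0L),
    d_Br = c(0L, -1L, 1L, 0L, 0L, -1L),
    d_Rr = c(0L, 1L, -1L, 0L, 1L, 0L),
    rate = c(rates$c * a * B / N + rates$e * a,
             rates$c * b * R / N + rates$e * b,
             rates$c * r * B / N,
             rates$c * q * R / N,
             rates$i * a,
             rates$i * b)
  )
  ch <- dplyr::filter(ch, .data$rate > 0)
  dplyr::transmute(ch,
    channel = .data$channel,
    n_Rb = a + .data$d_Rb, n_Br = b + .data$d_Br, n_Rr = r + .data$d_Rr,
    n_Bb = N - .data$n_Rb - .data$n_Br - .data$n_Rr,
    rate = .data$rate)
}

new_trajectory <- function(df, model, status, t_end, n_events, seed, params,
                           sampled) {
  structure(df,
            class = c("cvm_trajectory", class(tibble())),
            model = model, terminal_status = status, t_end = t_end,
            n_events = n_events, seed = seed, params = params,
            sampled = sampled)
}

status_label <- function(code) {
  c("truncated", "absorbed_red", "absorbed_blue", "frozen")[code + 1L]
}

#' Simulate one realization of the concealed voter model
#'
#' Runs the count-based Gillespie algorithm from an initial composition to
#' consensus (or to `t_max`). The chain samples the next state-changing
#' channel proportionally to its rate ([transition_rates()]) and waits an
#' exponential time with the total-rate mean; this is distributionally
#' identical to the per-agent algorithm ([run_cvm_agent()]) but takes O(1)
#' work per event regardless of `N`.
#'
#' When `i = 0` and the private layer of `comp0` is mixed, absorption is not
#' guaranteed (the private layer can freeze), so a finite `t_max` is
#' required.
#'
#' @param comp0 initial [composition()], or an [initial_condition()] plus `N`.
#' @param rates a [rate_set()].
#' @param seed integer RNG seed (optional; when `NULL` the current RNG
#'   state is used).
#' @param N group size, needed only when `comp0` is an initial condition.
#' @param t_max optional truncation time; default none (`Inf`).
#' @param grid optional increasing vector of times in `[0, t_max]` at which
#'   to record the state (used instead of the event log for large runs).
#' @param record_events whether to keep the full event log; defaults to
#'   `TRUE` for `N <= 200` with no grid, else `FALSE`. Capped at
#'   `max_events` rows.
#' @param max_events event-log row cap (default `2^21`).
#' @return A `cvm_trajectory`: a tibble with columns `t`, `n_Rb`, `n_Br`,
#'   `n_Rr`, `n_Bb` (one row per event, or per grid point in sampled mode)
#'   with attributes `terminal_status` (`"absorbed_red"`, `"absorbed_blue"`
#'   or `"truncated"`), `t_end` (the consensus time when absorbed),
#'   `n_events`, `seed`, and `params`.
#' @examples
#' traj <- run_cvm(composition(5, 5, 0, N = 10), rate_set(1, 1/4, 1/16), seed = 1)
#' attr(traj, "terminal_status")
#' @export
run_cvm <- function(comp0, rates, seed = NULL, N = NULL, t_max = Inf,
                    grid = NULL, record_events = NULL, max_events = 2^21) {
  if (inherits(comp0, "initial_condition") ||
      (is.numeric(comp0) && length(comp0) == 3L)) {
    if (is.null(N)) stop("N is required when comp0 is an initial condition",
                         call. = FALSE)
    comp0 <- realize_composition(comp0, N)
  }
  stopifnot(inherits(comp0, "composition"))
  rates <- as_rate_set(rates)
  if (rates$i == 0 && !is.finite(t_max)) {
    rho_r_mixed <- (comp0$n_Br + comp0$n_Rr) %in% seq_len(comp0$N - 1L)
    if (rho_r_mixed) {
      stop(paste("i = 0 with a mixed private layer can never reach consensus;",
                 "supply a finite t_max"), call. = FALSE)
    }
  }
  if (!is.null(grid)) {
    stopifnot(is.numeric(grid), !is.unsorted(grid), all(grid >= 0),
              all(grid <= t_max))
  } else {
    grid <- numeric(0)
  }
  if (is.null(record_events)) {
    record_events <- comp0$N <= 200L && length(grid) == 0L
  }
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_cvm_gillespie(comp0$n_Rb, comp0$n_Br, comp0$n_Rr, comp0$N,
                           rates$c, rates$e, rates$i, t_max, as.numeric(grid),
                           if (isTRUE(record_events)) as.integer(max_events) else 0L)
  params <- list(N = comp0$N, rates = rates, comp0 = comp0, t_max = t_max)
  if (isTRUE(record_events)) {
    df <- tibble(t = res$times, n_Rb = res$ev_a, n_Br = res$ev_b,
                 n_Rr = res$ev_r)
    sampled <- FALSE
  } else if (length(grid) > 0L) {
    df <- tibble(t = as.numeric(grid),
                 n_Rb = res$grid_states[, 1L], n_Br = res$grid_states[, 2L],
                 n_Rr = res$grid_states[, 3L])
    sampled <- TRUE
  } else {
    df <- tibble(t = res$t_end, n_Rb = res$a, n_Br = res$b, n_Rr = res$r)
    sampled <- TRUE
  }
  df$n_Bb <- comp0$N - df$n_Rb - df$n_Br - df$n_Rr
  new_trajectory(df, "cvm", status_label(res$status), res$t_end,
                 res$n_events, seed, params, sampled)
}

#' Simulate one realization of the basic (single-layer) voter model
#'
#' Count-based Gillespie simulation of neutral drift on the complete graph:
#' the red count moves up or down by one, each direction at rate
#' `c R (N - R) / N`, until one colour takes over.
#'
#' @param n_R initial number of reds.
#' @param N group size.
#' @param c copy rate.
#' @param seed integer RNG seed (optional).
#' @param t_max optional truncation time.
#' @param record_events keep the full event log (default `TRUE` for
#'   `N <= 200`).
#' @param max_events event-log row cap.
#' @return A `cvm_trajectory` with columns `t`, `n_R` and the same
#'   attributes as [run_cvm()].
#' @examples
#' traj <- run_bvm(25, N = 50, c = 1, seed = 1)
#' attr(traj, "t_end")
#' @export
run_bvm <- function(n_R, N, c, seed = NULL, t_max = Inf,
                    record_events = NULL, max_events = 2^21) {
  stopifnot(n_R >= 0, n_R <= N, N >= 1, c > 0)
  if (is.null(record_events)) record_events <- N <= 200L
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_bvm_gillespie(as.integer(n_R), as.integer(N), c, t_max,
                           if (isTRUE(record_events)) as.integer(max_events) else 0L)
  df <- if (isTRUE(record_events)) {
    tibble(t = res$times, n_R = res$ev_R)
  } else {
    tibble(t = res$t_end, n_R = res$R)
  }
  new_trajectory(df, "bvm", status_label(res$status), res$t_end,
                 res$n_events, seed, list(N = N, c = c, n_R0 = n_R,
                                          t_max = t_max),
                 !isTRUE(record_events))
}

#' Agent-based reference simulations
#'
#' The literal per-agent Monte Carlo algorithms, kept as reference
#' implementations for distributional-equivalence tests against the
#' count-based Gillespie engine. Each step picks a focal individual
#' uniformly at random, draws `u ~ U(0, c + e + i)` to choose between
#' copying a random neighbour's public opinion (self allowed, a null event
#' when colours agree), externalizing, or internalizing, then advances time
#' by an exponential increment with mean `1 / ((c + e + i) N)`. Null events
#' consume time but change nothing; consensus is tested after every step.
#'
#' Only terminal information (status and consensus time) is returned.
#'
#' @param comp0 initial [composition()].
#' @param rates a [rate_set()].
#' @param seed integer RNG seed (optional).
#' @param t_max optional truncation time (required when `i = 0` with a mixed
#'   private layer).
#' @return A list with `terminal_status`, `t_end` and `n_events` (agent
#'   activations, null events included).
#' @examples
#' run_cvm_agent(composition(5, 5, 0, N = 10), rate_set(1, 1/4, 1/16), seed = 1)
#' @export
run_cvm_agent <- function(comp0, rates, seed = NULL, t_max = Inf) {
  stopifnot(inherits(comp0, "composition"))
  rates <- as_rate_set(rates)
  if (rates$i == 0 && !is.finite(t_max) &&
      (comp0$n_Br + comp0$n_Rr) %in% seq_len(comp0$N - 1L)) {
    stop("i = 0 with a mixed private layer requires a finite t_max",
         call. = FALSE)
  }
  # expand counts into per-agent colour vectors (1 = red, 0 = blue)
  ext <- rep(c(1L, 0L, 1L, 0L),
             c(comp0$n_Rb, comp0$n_Br, comp0$n_Rr, comp0$n_Bb))
  itn <- rep(c(0L, 1L, 1L, 0L),
             c(comp0$n_Rb, comp0$n_Br, comp0$n_Rr, comp0$n_Bb))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_cvm_agent(ext, itn, rates$c, rates$e, rates$i, t_max)
  list(terminal_status = status_label(res$status), t_end = res$t_end,
       n_events = res$n_events)
}

#' @rdname run_cvm_agent
#' @param n_R,N,c initial red count, group size and copy rate for the
#'   single-layer reference.
#' @export
run_bvm_agent <- function(n_R, N, c, seed = NULL, t_max = Inf) {
  stopifnot(n_R >= 0, n_R <= N, N >= 1, c > 0)
  col <- rep(c(1L, 0L), c(n_R, N - n_R))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_bvm_agent(col, c, t_max)
  list(terminal_status = status_label(res$status), t_end = res$t_end,
       n_events = res$n_events)
}

#' Sample a trajectory on a time grid
#'
#' Piecewise-constant lookup: the state at time `t` is the state at the last
#' recorded event time `<= t`; beyond absorption or truncation the final
#' state persists. Exact for event-logged trajectories; for grid-sampled
#' trajectories the lookup is exact only at the recorded grid times.
#'
#' @param traj a `cvm_trajectory`.
#' @param t_grid nonnegative, nondecreasing times.
#' @return A tibble with column `t` followed by the state columns of `traj`.
#' @examples
#' traj <- run_cvm(composition(5, 5, 0, N = 10), rate_set(1, 1/4, 1/16), seed = 1)
#' sample_at(traj, c(0, 1, 10, 1e6))
#' @export
sample_at <- function(traj, t_grid) {
  stopifnot(inherits(traj, "cvm_trajectory"), is.numeric(t_grid))
  if (any(t_grid < 0)) stop("sample times must be nonnegative", call. = FALSE)
  idx <- findInterval(t_grid, traj$t)
  idx[idx == 0L] <- 1L  # t before the first record: initial state
  out <- dplyr::select(as_tibble(traj), -"t")[idx, , drop = FALSE]
  dplyr::bind_cols(tibble(t = t_grid), out)
}

#' @export
#' @method print cvm_trajectory
print.cvm_trajectory <- function(x, ...) {
  cat(sprintf("<cvm_trajectory: %s> N = %d, %s, t_end = %g, %d recorded rows (%s)\n",
              attr(x, "model"), attr(x, "params")$N,
              attr(x, "terminal_status"), attr(x, "t_end"), nrow(x),
              if (isTRUE(attr(x, "sampled"))) "sampled" else "event log"))
  NextMethod()
}
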