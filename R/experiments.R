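# normal-approximation binomial CI for a proportion
binom_ci <- function(k, n, level = 0.95) {
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(estimate = p, conf.low = max(0, p - half), conf.high = min(1, p + half))
}

# t-distribution CI for a mean
mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  half <- if (n > 1) qt(1 - (1 - level) / 2, n - 1) * sd(x) / sqrt(n) else NA_real_
  c(estimate = m, conf.low = m - half, conf.high = m + half)
}

# deterministic, order-independent per-replicate seeds from one master seed
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run an ensemble of concealed-voter-model realizations
#'
#' Simulates `n_reps` independent realizations from the same initial
#' condition and summarizes them: the fraction `F` of red-consensus
#' outcomes with a 95% binomial confidence interval (an estimator of the
#' strength `m`), the mean consensus time with a t-interval, and the
#' ensemble-mean hypocrite gap `D(t) = rho_Rb(t) - rho_Br(t)` on a time
#' grid. Each replicate gets a deterministic seed derived from
#' `seed`, so results are reproducible and independent of execution order.
#'
#' @param ic an [initial_condition()] or numeric triple.
#' @param N group size.
#' @param rates a [rate_set()].
#' @param n_reps number of replicates (at least 2).
#' @param seed master seed for the ensemble.
#' @param grid optional time grid on which the gap `D` is recorded per
#'   replicate.
#' @param t_max optional truncation time (e.g. to study only the fast
#'   equalization stage); truncated replicates contribute no consensus
#'   outcome or time.
#' @param keep_grid_states keep the full per-replicate composition at grid
#'   times (arrays `reps x grid`), needed for martingale diagnostics.
#' @param level confidence level for all intervals.
#' @return An object of class `cvm_ensemble`: a list with `replicates`
#'   (tibble: `rep`, `seed`, `terminal_status`, `t_cons`, `n_events`),
#'   `gap` (tibble: `t`, `D_bar`, `se`, `n`), the per-replicate gap matrix
#'   `D`, summary fields `F_hat`, `Tcons`, and the parameter record.
#' @examples
#' ens <- run_ensemble(c(0, 1, 0), N = 25, rate_set(1, 1/4, 1/16),
#'                     n_reps = 50, seed = 1)
#' glance(ens)
#' @export
run_ensemble <- function(ic, N, rates, n_reps, seed, grid = NULL,
                         t_max = Inf, keep_grid_states = FALSE,
                         level = 0.95) {
  ic <- as_initial_condition(ic)
  rates <- as_rate_set(rates)
  stopifnot(n_reps >= 2)
  comp0 <- realize_composition(ic, N)
  seeds <- replicate_seeds(seed, n_reps)
  has_grid <- !is.null(grid) && length(grid) > 0L

  status <- character(n_reps)
  t_cons <- rep(NA_real_, n_reps)
  n_events <- numeric(n_reps)
  D <- if (has_grid) matrix(NA_real_, n_reps, length(grid)) else NULL
  states <- if (has_grid && keep_grid_states) {
    list(n_Rb = matrix(NA_integer_, n_reps, length(grid)),
         n_Br = matrix(NA_integer_, n_reps, length(grid)),
         n_Rr = matrix(NA_integer_, n_reps, length(grid)))
  } else NULL

  for (k in seq_len(n_reps)) {
    traj <- run_cvm(comp0, rates, seed = seeds[k], t_max = t_max,
                    grid = grid, record_events = FALSE)
    status[k] <- attr(traj, "terminal_status")
    if (status[k] %in% c("absorbed_red", "absorbed_blue")) {
      t_cons[k] <- attr(traj, "t_end")
    }
    n_events[k] <- attr(traj, "n_events")
    if (has_grid) {
      D[k, ] <- (traj$n_Rb - traj$n_Br) / N
      if (keep_grid_states) {
        states$n_Rb[k, ] <- traj$n_Rb
        states$n_Br[k, ] <- traj$n_Br
        states$n_Rr[k, ] <- traj$n_Rr
      }
    }
  }

  n_abs <- sum(!is.na(t_cons))
  F_hat <- if (n_abs > 0) {
    binom_ci(sum(status == "absorbed_red"), n_abs, level)
  } else c(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_)
  Tcons <- if (n_abs > 0) mean_ci(t_cons, level) else
    c(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_)

  gap <- if (has_grid) {
    tibble(t = as.numeric(grid),
           D_bar = colMeans(D),
           se = apply(D, 2, sd) / sqrt(n_reps),
           n = n_reps)
  } else NULL

  structure(
    list(
      replicates = tibble(rep = seq_len(n_reps), seed = seeds,
                          terminal_status = status, t_cons = t_cons,
                          n_events = n_events),
      gap = gap, D = D, grid_states = states,
      F_hat = F_hat, Tcons = Tcons,
      n_reps = n_reps, n_absorbed = n_abs, level = level,
      params = list(ic = ic, N = N, rates = rates, seed = seed,
                    t_max = t_max, grid = grid)
    ),
    class = "cvm_ensemble"
  )
}

#' @export
#' @method print cvm_ensemble
print.cvm_ensemble <- function(x, ...) {
  p <- x$params
  cat(sprintf("<cvm_ensemble> %d reps, N = %d, c = %g, e = %g, i = %g, seed = %s\n",
              x$n_reps, p$N, p$rates$c, p$rates$e, p$rates$i,
              format(p$seed)))
  cat(sprintf("  IC (rho_Rb, rho_Br, rho_Rr) = (%g, %g, %g); %d absorbed\n",
              p$ic$rho_Rb, p$ic$rho_Br, p$ic$rho_Rr, x$n_absorbed))
  if (x$n_absorbed > 0) {
    cat(sprintf("  F_hat = %.3f [%.3f, %.3f];  mean T_cons = %.1f [%.1f, %.1f]\n",
                x$F_hat[["estimate"]], x$F_hat[["conf.low"]], x$F_hat[["conf.high"]],
                x$Tcons[["estimate"]], x$Tcons[["conf.low"]], x$Tcons[["conf.high"]]))
  }
  invisible(x)
}

#' @export
tidy.cvm_ensemble <- function(x, ...) {
  rows <- list(
    tibble(term = "F_hat", estimate = x$F_hat[["estimate"]],
           conf.low = x$F_hat[["conf.low"]], conf.high = x$F_hat[["conf.high"]]),
    tibble(term = "Tcons_mean", estimate = x$Tcons[["estimate"]],
           conf.low = x$Tcons[["conf.low"]], conf.high = x$Tcons[["conf.high"]])
  )
  dplyr::bind_rows(rows)
}

#' @export
glance.cvm_ensemble <- function(x, ...) {
  p <- x$params
  tibble(
    n_reps = x$n_reps, n_absorbed = x$n_absorbed,
    N = p$N, c = p$rates$c, e = p$rates$e, i = p$rates$i,
    m_theory = strength_m(p$ic$rho_Rb + p$ic$rho_Rr,
                          p$ic$rho_Br + p$ic$rho_Rr, p$rates),
    F_hat = x$F_hat[["estimate"]],
    F_low = x$F_hat[["conf.low"]], F_high = x$F_hat[["conf.high"]],
    Tcons_mean = x$Tcons[["estimate"]],
    Tcons_low = x$Tcons[["conf.low"]], Tcons_high = x$Tcons[["conf.high"]]
  )
}

#' Estimate the equalization time from ensemble gap decay
#'
#' Fits the exponential-decay law of the ensemble-mean hypocrite gap,
#' `mean D(t) = D0 exp(-(e + i) t)`, by ordinary least squares of
#' `log |D_bar(t)|` on `t`, and reports the e-folding time
#' `T_equal = -1 / slope` together with the fitted decay rate. Grid points
#' dominated by noise are excluded: the fit uses times where
#' `|D_bar(t)| > max(3 se(D_bar(t)), |D0| exp(-3))`. Confidence intervals
#' come from a replicate-level bootstrap (resampling rows of the
#' per-replicate gap matrix and refitting).
#'
#' @param x a `cvm_ensemble` with a recorded gap series, or a tibble with
#'   columns `t` and `D_bar` (then no bootstrap CI is available unless the
#'   matrix `D` is supplied).
#' @param D0 initial gap; defaults to `D_bar(0)`.
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param level confidence level.
#' @return An object of class `cvm_tequal_fit`: a list with `T_equal`,
#'   `rate` (each a named vector estimate/conf.low/conf.high), the fit
#'   window, and the underlying series.
#' @examples
#' grid <- seq(0, 10, 0.5)
#' fit <- estimate_tequal(tibble::tibble(t = grid,
#'                                       D_bar = -exp(-0.3125 * grid)))
#' fit$T_equal[["estimate"]]  # 3.2
#' @export
estimate_tequal <- function(x, D0 = NULL, n_boot = 1000, level = 0.95) {
  if (inherits(x, "cvm_ensemble")) {
    if (is.null(x$gap)) {
      stop("ensemble has no gap series; rerun run_ensemble() with a grid",
           call. = FALSE)
    }
    gap <- x$gap
    D <- x$D
    if (is.null(D0)) D0 <- x$params$ic$rho_Rb - x$params$ic$rho_Br
  } else {
    gap <- as_tibble(x)
    stopifnot(all(c("t", "D_bar") %in% names(gap)))
    D <- NULL
    if (is.null(D0)) D0 <- gap$D_bar[gap$t == min(gap$t)][1L]
  }
  if (is.null(D0) || !is.finite(D0) || D0 == 0) {
    stop("estimate_tequal requires a nonzero initial gap D0", call. = FALSE)
  }
  se <- if ("se" %in% names(gap)) gap$se else rep(0, nrow(gap))
  floor_level <- pmax(3 * se, abs(D0) * exp(-3))
  window <- abs(gap$D_bar) > floor_level & gap$D_bar != 0
  if (sum(window) < 3L) {
    stop("fewer than 3 usable grid points above the noise floor", call. = FALSE)
  }

  fit_slope <- function(t, D_bar, keep) {
    stats::coef(lm(log(abs(D_bar[keep])) ~ t[keep]))[[2L]]
  }
  slope <- fit_slope(gap$t, gap$D_bar, window)
  est_T <- -1 / slope
  est_rate <- -slope

  ci_T <- c(NA_real_, NA_real_); ci_rate <- c(NA_real_, NA_real_)
  if (!is.null(D)) {
    n <- nrow(D)
    boots <- vapply(seq_len(n_boot), function(b) {
      rows <- sample.int(n, n, replace = TRUE)
      db <- colMeans(D[rows, , drop = FALSE])
      keep <- window & db != 0
      if (sum(keep) < 3L) return(NA_real_)
      fit_slope(gap$t, db, keep)
    }, numeric(1L))
    boots <- boots[is.finite(boots)]
    alpha <- (1 - level) / 2
    ci_rate <- quantile(-boots, c(alpha, 1 - alpha), names = FALSE)
    ci_T <- quantile(-1 / boots, c(alpha, 1 - alpha), names = FALSE)
  }

  structure(
    list(
      T_equal = c(estimate = est_T, conf.low = ci_T[1L], conf.high = ci_T[2L]),
      rate = c(estimate = est_rate, conf.low = ci_rate[1L],
               conf.high = ci_rate[2L]),
      D0 = D0, window = gap$t[window], gap = gap, level = level
    ),
    class = "cvm_tequal_fit"
  )
}

#' @export
#' @method print cvm_tequal_fit
print.cvm_tequal_fit <- function(x, ...) {
  cat(sprintf("<cvm_tequal_fit> T_equal = %.3f [%s, %s], decay rate = %.4f\n",
              x$T_equal[["estimate"]],
              format(x$T_equal[["conf.low"]], digits = 4),
              format(x$T_equal[["conf.high"]], digits = 4),
              x$rate[["estimate"]]))
  invisible(x)
}

#' @export
tidy.cvm_tequal_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "T_equal", estimate = x$T_equal[["estimate"]],
           conf.low = x$T_equal[["conf.low"]],
           conf.high = x$T_equal[["conf.high"]]),
    tibble(term = "decay_rate", estimate = x$rate[["estimate"]],
           conf.low = x$rate[["conf.low"]], conf.high = x$rate[["conf.high"]])
  )
}

#' Distance of trajectory snapshots to the mean-field attractor
#'
#' For each snapshot of each trajectory, computes the Euclidean distance in
#' `(rho_Rb, rho_Br, rho_Rr)` space to the nearest point of the attractor
#' curve (numerically minimized over its parameter `rho_Rr`), together with
#' the layer gap `|rho_R - rho_r|` (identical to `|D|` by the gap
#' identity). Averaged over trajectories, the distance shrinks during the
#' fast first stage of consensus formation as the ensemble collapses onto
#' the attractor.
#'
#' @param trajectories a `cvm_trajectory` or list of them, all sharing the
#'   same parameters; grid-sampled trajectories on a common grid are
#'   averaged pointwise.
#' @param rates the [rate_set()] of the trajectories.
#' @return A tibble with columns `t`, `dist` (mean distance to the curve)
#'   and `layer_gap` (mean `|rho_R - rho_r|`).
#' @export
attractor_diagnostics <- function(trajectories, rates) {
  rates <- as_rate_set(rates)
  if (inherits(trajectories, "cvm_trajectory")) {
    trajectories <- list(trajectories)
  }
  dist_to_curve <- function(x, y, z) {
    obj <- function(s) {
      g <- attractor_hypocrite_fraction(s, rates)
      (x - g)^2 + (y - g)^2 + (z - s)^2
    }
    sqrt(optimize(obj, c(0, 1), tol = 1e-10)$objective)
  }
  per_traj <- purrr::map(trajectories, function(traj) {
    N <- attr(traj, "params")$N
    tibble(
      t = traj$t,
      dist = purrr::pmap_dbl(
        list(traj$n_Rb / N, traj$n_Br / N, traj$n_Rr / N), dist_to_curve),
      layer_gap = abs((traj$n_Rb - traj$n_Br) / N)
    )
  })
  dplyr::bind_rows(per_traj) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(dist = mean(.data$dist),
                     layer_gap = mean(.data$layer_gap), .groups = "drop")
}

#' Benchmark initial conditions and rate presets
#'
#' The four reference initial conditions `(rho_Rb, rho_Br, rho_Rr)` —
#' `(0, 1, 0)`, `(0.25, 0.75, 0)`, `(0.5, 0.25, 0.25)`, `(0.75, 0, 0)` —
#' and the two rate presets used throughout: `main` (`c = 1, e = 1/4,
#' i = 1/16`, the default study conditions at `N = 400`) and `s2` (the
#' swapped-rate variant `c = 1, e = 1/16, i = 1/4`).
#'
#' @param preset `"main"` or `"s2"`.
#' @return `cvm_preset()`: a list with `name`, `rates`, `N`, and `ics`
#'   (list of four [initial_condition()]s, named by their figure symbols).
#' @examples
#' cvm_preset("main")$rates
#' @export
cvm_preset <- function(preset = c("main", "s2")) {
  preset <- match.arg(preset)
  rates <- switch(preset,
                  main = rate_set(1, 1/4, 1/16),
                  s2 = rate_set(1, 1/16, 1/4))
  list(
    name = preset,
    rates = rates,
    N = 400L,
    ics = list(
      square   = initial_condition(0.00, 1.00, 0.00),
      triangle = initial_condition(0.25, 0.75, 0.00),
      diamond  = initial_condition(0.50, 0.25, 0.25),
      nabla    = initial_condition(0.75, 0.00, 0.00)
    )
  )
}

#' Reproduce the benchmark table of predicted and observed quantities
#'
#' For each of the four reference initial conditions, runs an ensemble to
#' absorption (recording the hypocrite gap on a grid covering the
#' equalization stage) and tabulates, side by side, the observed and
#' predicted red-consensus fraction `F` (predicted: the strength `m`), the
#' mean consensus time, and the equalization time (predicted:
#' `1 / (e + i)`).
#'
#' With the default `n_reps = 1000` at `N = 400` this reproduces the study
#' conditions; smaller `n_reps` or `N` give a cheaper table with
#' correspondingly wider intervals.
#'
#' @param preset `"main"` or `"s2"` (see [cvm_preset()]).
#' @param n_reps replicates per initial condition.
#' @param seed master seed; each initial condition uses a distinct derived
#'   seed.
#' @param N group size override (default 400).
#' @param grid_dt spacing of the gap grid (default 0.25, covering
#'   `[0, 4 T_equal]`).
#' @return A tibble of class `cvm_table2` with one row per initial
#'   condition and quantity, columns `ic`, `rho_Rb`, `rho_Br`, `rho_Rr`,
#'   `quantity`, `observed`, `conf.low`, `conf.high`, `predicted`,
#'   `n_reps`.
#' @examples
#' \donttest{
#' reproduce_table2("main", n_reps = 100, seed = 1, N = 100)
#' }
#' @export
reproduce_table2 <- function(preset = c("main", "s2"), n_reps = 1000, seed,
                             N = NULL, grid_dt = 0.25) {
  ps <- cvm_preset(match.arg(preset))
  if (!is.null(N)) ps$N <- as.integer(N)
  t_eq <- equalization_time(ps$rates)
  grid <- seq(0, 4 * t_eq, by = grid_dt)
  ic_seeds <- replicate_seeds(seed, length(ps$ics))

  rows <- purrr::imap(ps$ics, function(ic0, nm) {
    k <- match(nm, names(ps$ics))
    ens <- run_ensemble(ic0, ps$N, ps$rates, n_reps = n_reps,
                        seed = ic_seeds[k], grid = grid)
    th <- theory_prediction(ic0, ps$N, ps$rates)
    d0 <- ic0$rho_Rb - ic0$rho_Br
    teq <- if (d0 != 0) estimate_tequal(ens) else NULL
    tibble(
      ic = nm, rho_Rb = ic0$rho_Rb, rho_Br = ic0$rho_Br, rho_Rr = ic0$rho_Rr,
      quantity = c("F", "T_cons", "T_equal"),
      observed = c(ens$F_hat[["estimate"]], ens$Tcons[["estimate"]],
                   if (is.null(teq)) NA_real_ else teq$T_equal[["estimate"]]),
      conf.low = c(ens$F_hat[["conf.low"]], ens$Tcons[["conf.low"]],
                   if (is.null(teq)) NA_real_ else teq$T_equal[["conf.low"]]),
      conf.high = c(ens$F_hat[["conf.high"]], ens$Tcons[["conf.high"]],
                    if (is.null(teq)) NA_real_ else teq$T_equal[["conf.high"]]),
      predicted = c(th$m, th$T_cvm, th$T_equal),
      n_reps = n_reps
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cvm_table2", class(out)),
            preset = ps$name, N = ps$N, seed = seed)
}
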