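#' Group composition of the concealed voter model
#'
#' The full state of a group of `N` individuals on the complete graph is the
#' integer count of each agent type: `n_Rb` (publicly red, privately blue
#' hypocrites), `n_Br` (publicly blue, privately red hypocrites), `n_Rr`
#' (frank reds), and the derived `n_Bb = N - n_Rb - n_Br - n_Rr` (frank
#' blues). Blue quantities are always derived, never stored.
#'
#' @param n_Rb,n_Br,n_Rr nonnegative integer counts; their sum must not
#'   exceed `N`.
#' @param N group size, a positive integer.
#'
#' @return An object of class `composition`: a list with integer fields
#'   `n_Rb`, `n_Br`, `n_Rr`, `n_Bb`, `N`.
#' @examples
#' composition(0, 400, 0, N = 400)   # every individual a publicly blue hypocrite
#' @seealso [comp_fractions()], [classify_composition()], [realize_composition()]
#' @export
composition <- function(n_Rb, n_Br, n_Rr, N) {
  counts <- c(n_Rb, n_Br, n_Rr)
  stopifnot(length(counts) == 3L, is.numeric(counts), is.numeric(N), length(N) == 1L)
  if (any(counts != round(counts)) || N != round(N)) {
    stop("composition counts and N must be integers", call. = FALSE)
  }
  counts <- as.integer(round(counts)); N <- as.integer(round(N))
  if (N < 1L) stop("group size N must be at least 1", call. = FALSE)
  if (any(counts < 0L)) stop("composition counts must be nonnegative", call. = FALSE)
  if (sum(counts) > N) {
    stop("composition counts exceed the group size N", call. = FALSE)
  }
  structure(
    list(n_Rb = counts[[1L]], n_Br = counts[[2L]], n_Rr = counts[[3L]],
         n_Bb = N - sum(counts), N = N),
    class = "composition"
  )
}

#' @export
#' @method print composition
print.composition <- function(x, ...) {
  cat(sprintf("<composition> N = %d: Rb %d | Br %d | Rr %d | Bb %d (%s)\n",
              x$N, x$n_Rb, x$n_Br, x$n_Rr, x$n_Bb,
              classify_composition(x)))
  invisible(x)
}

#' Derived fractions and summary observables of a composition
#'
#' Returns the per-type fractions together with the observables the theory is
#' written in: `rho_R = rho_Rb + rho_Rr` (publicly red), `rho_r = rho_Br +
#' rho_Rr` (privately red), and the hypocrite gap `D = rho_Rb - rho_Br`,
#' which satisfies the exact identity `D = rho_R - rho_r`.
#'
#' @param comp a [composition()].
#' @return A one-row tibble with columns `N`, `rho_Rb`, `rho_Br`, `rho_Rr`,
#'   `rho_Bb`, `rho_R`, `rho_r`, `D`.
#' @examples
#' comp_fractions(composition(200, 100, 100, N = 400))
#' @export
comp_fractions <- function(comp) {
  stopifnot(inherits(comp, "composition"))
  N <- comp$N
  tibble(
    N      = N,
    rho_Rb = comp$n_Rb / N,
    rho_Br = comp$n_Br / N,
    rho_Rr = comp$n_Rr / N,
    rho_Bb = comp$n_Bb / N,
    rho_R  = (comp$n_Rb + comp$n_Rr) / N,
    rho_r  = (comp$n_Br + comp$n_Rr) / N,
    D      = (comp$n_Rb - comp$n_Br) / N
  )
}

#' Classify a composition as interior, consensus, or frozen when i = 0
#'
#' A consensus is a state in which a single opinion occupies both layers of
#' every individual: no hypocrites and either all or none frank red. States
#' with no hypocrites but a mixed private layer (`0 < n_Rr < N`) are
#' classified `frozen_if_i0`: with internalization switched off (`i = 0`)
#' the private layer can never change again, so the external process mixes
#' forever while the group never reaches full consensus. Simulations and the
#' exact solver use this flag to refuse non-absorbing configurations.
#'
#' @param comp a [composition()].
#' @return One of `"interior"`, `"red_consensus"`, `"blue_consensus"`,
#'   `"frozen_if_i0"`.
#' @examples
#' classify_composition(composition(0, 0, 7, N = 7))   # red consensus
#' classify_composition(composition(0, 0, 3, N = 10))  # frozen_if_i0
#' @export
classify_composition <- function(comp) {
  stopifnot(inherits(comp, "composition"))
  if (comp$n_Rb == 0L && comp$n_Br == 0L) {
    if (comp$n_Rr == comp$N) return("red_consensus")
    if (comp$n_Rr == 0L) return("blue_consensus")
    return("frozen_if_i0")
  }
  "interior"
}

#' Is a composition an absorbing consensus state?
#'
#' @param comp a [composition()].
#' @return `TRUE` iff all individuals share one opinion in both layers.
#' @export
is_consensus <- function(comp) {
  classify_composition(comp) %in% c("red_consensus", "blue_consensus")
}

#' Initial condition as fractions of the group
#'
#' Initial states are specified as fractions `(rho_Rb, rho_Br, rho_Rr)` of
#' the group in each non-frank-blue type; the frank-blue fraction is implied.
#' [realize_composition()] converts fractions to integer counts at a given
#' group size.
#'
#' @param rho_Rb,rho_Br,rho_Rr fractions in \[0, 1\] with sum at most 1.
#' @return An object of class `initial_condition`.
#' @examples
#' initial_condition(0, 1, 0)     # everyone a publicly blue hypocrite
#' @export
initial_condition <- function(rho_Rb, rho_Br, rho_Rr) {
  fr <- c(rho_Rb, rho_Br, rho_Rr)
  stopifnot(is.numeric(fr), length(fr) == 3L)
  if (any(!is.finite(fr)) || any(fr < 0)) {
    stop("initial-condition fractions must be nonnegative", call. = FALSE)
  }
  if (sum(fr) > 1 + 1e-12) {
    stop("initial-condition fractions must sum to at most 1", call. = FALSE)
  }
  structure(
    list(rho_Rb = fr[[1L]], rho_Br = fr[[2L]], rho_Rr = fr[[3L]]),
    class = "initial_condition"
  )
}

#' @export
#' @method print initial_condition
print.initial_condition <- function(x, ...) {
  cat(sprintf("<initial_condition> rho_Rb = %g, rho_Br = %g, rho_Rr = %g, rho_Bb = %g\n",
              x$rho_Rb, x$rho_Br, x$rho_Rr,
              1 - x$rho_Rb - x$rho_Br - x$rho_Rr))
  invisible(x)
}

as_initial_condition <- function(x) {
  if (inherits(x, "initial_condition")) return(x)
  if (inherits(x, "composition")) {
    return(initial_condition(x$n_Rb / x$N, x$n_Br / x$N, x$n_Rr / x$N))
  }
  if (is.numeric(x) && length(x) == 3L) {
    return(initial_condition(x[[1L]], x[[2L]], x[[3L]]))
  }
  stop("cannot interpret object as an initial_condition", call. = FALSE)
}

#' Realize an initial condition as integer counts at group size N
#'
#' Fractions are converted to counts by largest-remainder rounding over the
#' four types (quotas `rho * N`, floor, then distribute the remaining seats
#' by descending fractional part with the deterministic tie-break order
#' Rb, Br, Rr, Bb). When every `rho * N` is integral the result is exact.
#'
#' @param ic an [initial_condition()] (or a numeric vector of the three
#'   fractions).
#' @param N group size.
#' @return A [composition()] whose counts sum to `N`.
#' @examples
#' realize_composition(initial_condition(0.5, 0.25, 0.25), N = 400)
#' @export
realize_composition <- function(ic, N) {
  ic <- as_initial_condition(ic)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1, N == round(N))
  N <- as.integer(round(N))
  quota <- c(ic$rho_Rb, ic$rho_Br, ic$rho_Rr,
             1 - ic$rho_Rb - ic$rho_Br - ic$rho_Rr) * N
  # guard against tiny negative frank-blue quota from float round-off
  quota[quota < 0 & quota > -1e-9] <- 0
  base <- floor(quota + 1e-9)  # treat near-integral quotas as exact
  rem <- quota - base
  short <- N - sum(base)
  if (short > 0) {
    # ties broken by position: Rb, Br, Rr, Bb
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    base[take] <- base[take] + 1
  }
  composition(base[[1L]], base[[2L]], base[[3L]], N = N)
}
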