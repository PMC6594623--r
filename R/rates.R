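#' Per-individual transition rates of the concealed voter model
#'
#' Bundles the three Poisson rates that drive the dynamics: `c`, the rate at
#' which an individual copies the public opinion of a uniformly random
#' neighbour (self included); `e`, the externalization rate at which the
#' private opinion overwrites the public one (Rb -> Bb, Br -> Rr); and `i`,
#' the internalization rate at which the public opinion overwrites the
#' private one (Rb -> Rr, Br -> Bb). All three share the same unit,
#' events per individual per unit time.
#'
#' When `i = 0` the private layer never changes, so a group whose private
#' layer is mixed can never reach full consensus; such rate sets are flagged
#' as non-ergodic and the consensus-time formulas and the exact solver refuse
#' them.
#'
#' @param c copy rate; must be positive.
#' @param e externalization rate; must be nonnegative.
#' @param i internalization rate; must be nonnegative.
#'
#' @return An object of class `rate_set`: a list with elements `c`, `e`, `i`
#'   and a logical `ergodic` (`TRUE` iff `i > 0`).
#' @examples
#' rate_set(c = 1, e = 1/4, i = 1/16)
#' @export
rate_set <- function(c, e, i) {
  stopifnot(is.numeric(c), is.numeric(e), is.numeric(i),
            length(c) == 1L, length(e) == 1L, length(i) == 1L)
  if (!is.finite(c) || c <= 0) {
    stop("copy rate `c` must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(e) || e < 0) {
    stop("externalization rate `e` must be a nonnegative finite number", call. = FALSE)
  }
  if (!is.finite(i) || i < 0) {
    stop("internalization rate `i` must be a nonnegative finite number", call. = FALSE)
  }
  structure(
    list(c = as.numeric(c), e = as.numeric(e), i = as.numeric(i),
         ergodic = i > 0),
    class = "rate_set"
  )
}

#' @export
#' @method print rate_set
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> c = %g, e = %g, i = %g (%s)\n",
              x$c, x$e, x$i,
              if (x$ergodic) "ergodic" else "non-ergodic: i = 0"))
  invisible(x)
}

as_rate_set <- function(x) {
  if (inherits(x, "rate_set")) return(x)
  if (is.list(x) && all(c("c", "e", "i") %in% names(x))) {
    return(rate_set(x$c, x$e, x$i))
  }
  stop("cannot interpret object as a rate_set", call. = FALSE)
}
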