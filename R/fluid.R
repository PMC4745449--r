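#' Herschel-Bulkley fluid parameters
#'
#' Constructs the constitutive parameter set of a Herschel-Bulkley fluid,
#' \eqn{|\tau| = \tau_y + k (-\partial w/\partial r)^n}. All three
#' parameters are nondimensional: stresses are scaled by the wall shear of
#' the reference Newtonian flow and lengths by the normal lumen radius.
#'
#' The classical reductions are available as named constructors:
#' \code{newtonian_fluid()} (\eqn{n = 1}, \eqn{\tau_y = 0}),
#' \code{power_law_fluid()} (\eqn{\tau_y = 0}) and
#' \code{bingham_fluid()} (\eqn{n = 1}).
#'
#' @param n Power-law (fluid behaviour) index, \eqn{n > 0}. Blood in small
#'   vessels is shear thinning, typically \eqn{n < 1}.
#' @param k Consistency index, \eqn{k > 0} (nondimensional).
#' @param tau_y Yield stress, \eqn{\tau_y \ge 0} (nondimensional). Below
#'   this stress the material translates as a rigid plug.
#' @return An object of class \code{"hb_fluid"}: a named list with
#'   components \code{n}, \code{k}, \code{tau_y}.
#' @examples
#' hb_fluid(n = 0.8, k = 1.2, tau_y = 0.1)
#' newtonian_fluid(k = 1)
#' @export
hb_fluid <- function(n, k, tau_y = 0) {
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(tau_y), length(tau_y) == 1L, is.finite(tau_y))
  if (n <= 0) stop("'n' must be positive, got ", n)
  if (k <= 0) stop("'k' must be positive, got ", k)
  if (tau_y < 0) stop("'tau_y' must be nonnegative, got ", tau_y)
  structure(list(n = as.numeric(n), k = as.numeric(k),
                 tau_y = as.numeric(tau_y)),
            class = "hb_fluid")
}

#' @rdname hb_fluid
#' @export
newtonian_fluid <- function(k = 1) hb_fluid(n = 1, k = k, tau_y = 0)

#' @rdname hb_fluid
#' @export
power_law_fluid <- function(n, k) hb_fluid(n = n, k = k, tau_y = 0)

#' @rdname hb_fluid
#' @export
bingham_fluid <- function(k, tau_y) hb_fluid(n = 1, k = k, tau_y = tau_y)

#' @export
print.hb_fluid <- function(x, ...) {
  kind <- if (x$tau_y == 0 && x$n == 1) "Newtonian"
  else if (x$tau_y == 0) "power-law"
  else if (x$n == 1) "Bingham-plastic"
  else "Herschel-Bulkley"
  cat(sprintf("%s fluid: n = %g, k = %g, tau_y = %g\n",
              kind, x$n, x$k, x$tau_y))
  invisible(x)
}

as_hb_fluid <- function(x) {
  if (inherits(x, "hb_fluid")) return(x)
  if (is.list(x) && all(c("n", "k") %in% names(x)))
    return(hb_fluid(x$n, x$k, if (is.null(x$tau_y)) 0 else x$tau_y))
  stop("cannot interpret object as an hb_fluid")
}
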