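#' Power-law (zero yield stress) pressure gradient
#'
#' Closed-form pressure gradient driving flow rate \code{Q} through a tube
#' of radius \code{R} when \eqn{\tau_y = 0}:
#' \eqn{q_0 = (2k/R^{3n+1})\,((3n+1)Q/n)^n}. For \eqn{n = 1} this is the
#' Poiseuille value \eqn{8kQ/R^4}.
#'
#' @param R Local tube radius. Vectorised.
#' @param Q Prescribed flow rate (per \eqn{\pi}).
#' @param fluid An \code{\link{hb_fluid}} (its \code{tau_y} is ignored).
#' @return Pressure gradient \eqn{q_0 > 0}.
#' @export
q_powerlaw <- function(R, Q, fluid) {
  fluid <- as_hb_fluid(fluid)
  stopifnot(is.numeric(R), all(R > 0), is.numeric(Q), Q > 0)
  n <- fluid$n
  2 * fluid$k * ((3 * n + 1) * Q / n)^n / R^(3 * n + 1)
}

#' Quadratic coefficient of the small-yield-stress expansion
#'
#' The dimensionless polynomial coefficient
#' \deqn{C(n) = \frac{42n^3 + 56n^2 + 26n + 4}{(2n+1)^4 (n+1)^2}}
#' entering the \eqn{\tau_y^2} term of \code{\link{q_analytical}}. It is
#' exposed as a replaceable function because the expansion's quadratic term
#' is an empirical calibration (validated against the Newton-Raphson root
#' over \eqn{\tau_y \le 2.4}) rather than a closed-form perturbation
#' result; users may inject an alternative coefficient function into
#' \code{q_analytical}.
#'
#' @param n Power-law index.
#' @return The coefficient \eqn{C(n)}; \eqn{C(0.8) \approx 0.5548}.
#' @export
hb_quadratic_coef <- function(n) {
  (42 * n^3 + 56 * n^2 + 26 * n + 4) / ((2 * n + 1)^4 * (n + 1)^2)
}

#' Small-yield-stress analytical pressure gradient
#'
#' Second-order expansion of the pressure gradient in the yield stress,
#' \deqn{q_a = q_0 + \frac{2(3n+1)}{(2n+1)R}\tau_y +
#'   C(n)\frac{n^n R^{3n-1}}{2k((3n+1)Q)^n}\tau_y^2,}
#' valid in the regime \eqn{\tau_y/\tau_w \ll 1} but accurate to about 1.5%
#' (stenotic radii) up to \eqn{\tau_y = 2.4} with the default
#' \code{\link{hb_quadratic_coef}}.
#'
#' @param R Local tube radius. Vectorised.
#' @param Q Prescribed flow rate (per \eqn{\pi}).
#' @param fluid An \code{\link{hb_fluid}}.
#' @param quad_coef Function of \code{n} returning the quadratic
#'   coefficient \eqn{C(n)}; default \code{\link{hb_quadratic_coef}}.
#' @return Approximate pressure gradient \eqn{q_a}.
#' @seealso \code{\link{solve_pressure_gradient}} for the exact root.
#' @export
q_analytical <- function(R, Q, fluid, quad_coef = hb_quadratic_coef) {
  fluid <- as_hb_fluid(fluid)
  stopifnot(is.numeric(R), all(R > 0), is.numeric(Q), Q > 0)
  n <- fluid$n; ty <- fluid$tau_y
  q0 <- q_powerlaw(R, Q, fluid)
  q1 <- 2 * (3 * n + 1) / ((2 * n + 1) * R)
  q2 <- quad_coef(n) * n^n * R^(3 * n - 1) /
    (2 * fluid$k * ((3 * n + 1) * Q)^n)
  q0 + q1 * ty + q2 * ty^2
}

#' Residual of the implicit flow-rate relation
#'
#' The implicit equation fixing the pressure gradient \eqn{x} for a
#' prescribed flow rate is written residual-form as LHS \eqn{-} RHS with
#' \deqn{\mathrm{LHS} = \frac{(3n+1)\,Q\,x^3}{n R^2}, \qquad
#'   \mathrm{RHS} = \frac{(Rx - 2\tau_y)^{(n+1)/n}}{(2k)^{1/n}}
#'   \Big[x^2 + \frac{4n}{2n+1}\frac{\tau_y x}{R} +
#'        \frac{8n^2}{(2n+1)(n+1)}\frac{\tau_y^2}{R^2}\Big].}
#' The residual vanishes exactly when \code{\link{hb_flow_rate}} with
#' \eqn{q = x} returns \code{Q}. Defined only for \eqn{x > 2\tau_y/R}
#' (flowing states).
#'
#' @param x Candidate pressure gradient, \eqn{x > 2\tau_y/R}. Vectorised.
#' @param R Local tube radius.
#' @param Q Prescribed flow rate.
#' @param fluid An \code{\link{hb_fluid}}.
#' @return Residual LHS \eqn{-} RHS, same length as \code{x}.
#' @export
flow_rate_residual <- function(x, R, Q, fluid) {
  fluid <- as_hb_fluid(fluid)
  stopifnot(is.numeric(x), is.numeric(R), all(R > 0), is.numeric(Q), Q > 0)
  if (any(x <= 2 * fluid$tau_y / R))
    stop("residual undefined: need x > 2*tau_y/R (flowing state)")
  .eq_lhs(x, R, Q, fluid) - .eq_rhs(x, R, fluid)
}

.eq_lhs <- function(x, R, Q, fluid) {
  n <- fluid$n
  (3 * n + 1) * Q * x^3 / (n * R^2)
}

.eq_rhs <- function(x, R, fluid) {
  n <- fluid$n; ty <- fluid$tau_y
  poly <- x^2 + 4 * n * ty * x / ((2 * n + 1) * R) +
    8 * n^2 * ty^2 / ((2 * n + 1) * (n + 1) * R^2)
  (R * x - 2 * ty)^((n + 1) / n) / (2 * fluid$k)^(1 / n) * poly
}

# d(RHS)/dx, analytic
.eq_rhs_deriv <- function(x, R, fluid) {
  n <- fluid$n; ty <- fluid$tau_y
  g <- (R * x - 2 * ty)^((n + 1) / n) / (2 * fluid$k)^(1 / n)
  gp <- ((n + 1) / n) * R * (R * x - 2 * ty)^(1 / n) / (2 * fluid$k)^(1 / n)
  poly <- x^2 + 4 * n * ty * x / ((2 * n + 1) * R) +
    8 * n^2 * ty^2 / ((2 * n + 1) * (n + 1) * R^2)
  polyp <- 2 * x + 4 * n * ty / ((2 * n + 1) * R)
  gp * poly + g * polyp
}

#' Solve the implicit relation for the pressure gradient
#'
#' Newton-Raphson root of \code{\link{flow_rate_residual}}: the exact
#' nondimensional pressure gradient \eqn{q = -dp/dz} driving flow rate
#' \code{Q} through local radius \code{R}. The iteration starts from the
#' first-order expansion \eqn{q_0 + q_1\tau_y}; steps that would leave the
#' admissible region \eqn{x > 2\tau_y/R} are halved until feasible.
#' Convergence requires both the relative step and the residual relative to
#' the LHS to drop below \code{tol}. Vectorised over \code{R}: all radii
#' iterate simultaneously.
#'
#' @param R Local tube radius (vector allowed).
#' @param Q Prescribed flow rate (per \eqn{\pi}).
#' @param fluid An \code{\link{hb_fluid}}.
#' @param tol Convergence tolerance on relative step and relative
#'   residual; must be below \code{1e-6}. Default \code{1e-12}.
#' @param max_iter Maximum Newton iterations (at least 10). Default 100.
#' @param initial Optional starting value(s); default is the first-order
#'   analytical approximation.
#' @return Pressure gradient(s), same length as \code{R}.
#' @examples
#' fl <- hb_fluid(0.8, 1.2, tau_y = 0.05)
#' solve_pressure_gradient(0.78, 1, fl)   # 17.9423 at the stenosis throat
#' @export
solve_pressure_gradient <- function(R, Q, fluid, tol = 1e-12,
                                    max_iter = 100L, initial = NULL) {
  fluid <- as_hb_fluid(fluid)
  stopifnot(is.numeric(R), all(R > 0), is.numeric(Q), Q > 0)
  if (!(tol > 0 && tol < 1e-6)) stop("'tol' must be in (0, 1e-6)")
  if (max_iter < 10L) stop("'max_iter' must be at least 10")
  n <- fluid$n; ty <- fluid$tau_y
  if (ty == 0 && is.null(initial)) return(q_powerlaw(R, Q, fluid))

  lo <- 2 * ty / R            # open lower bound of the admissible region
  x <- if (is.null(initial)) {
    q_powerlaw(R, Q, fluid) + 2 * (3 * n + 1) * ty / ((2 * n + 1) * R)
  } else rep_len(initial, length(R))
  if (any(x <= lo)) x <- pmax(x, lo * 1.5 + 1e-8)

  active <- rep(TRUE, length(x))
  for (iter in seq_len(max_iter)) {
    f <- .eq_lhs(x, R, Q, fluid) - .eq_rhs(x, R, fluid)
    fp <- 3 * (3 * n + 1) * Q * x^2 / (n * R^2) - .eq_rhs_deriv(x, R, fluid)
    step <- f / fp
    # damp steps that would exit the admissible region
    xn <- x - step
    bad <- active & (xn <= lo | !is.finite(xn))
    halvings <- 0L
    while (any(bad) && halvings < 60L) {
      step[bad] <- step[bad] / 2
      xn <- x - step
      bad <- active & (xn <= lo | !is.finite(xn))
      halvings <- halvings + 1L
    }
    if (any(bad))
      stop("Newton step damping failed at R = ",
           paste(R[bad], collapse = ", "))
    xn[!active] <- x[!active]
    relstep <- abs(xn - x) / pmax(abs(xn), .Machine$double.xmin)
    x <- xn
    relres <- abs(.eq_lhs(x, R, Q, fluid) - .eq_rhs(x, R, fluid)) /
      .eq_lhs(x, R, Q, fluid)
    active <- active & (relstep > tol | relres > tol)
    if (!any(active)) return(x)
  }
  stop("Newton-Raphson failed to converge within ", max_iter,
       " iterations; last iterate(s): ",
       paste(signif(x[active], 8), collapse = ", "))
}

#' Analytical wall shear stress
#'
#' Wall shear stress from the small-yield-stress pressure gradient,
#' \eqn{\tau_w = R\,q_a/2} with \eqn{q_a} from \code{\link{q_analytical}}.
#'
#' @inheritParams q_analytical
#' @return Wall shear stress.
#' @export
wall_shear_analytical <- function(R, Q, fluid, quad_coef = hb_quadratic_coef) {
  R * q_analytical(R, Q, fluid, quad_coef) / 2
}
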