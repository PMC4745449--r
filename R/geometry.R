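#' Abnormal wall segment (stenosis or dilatation)
#'
#' One cosine-shaped abnormal segment of the vessel wall. \code{delta} is
#' the maximum distance the segment projects into (positive, stenosis) or
#' out of (negative, dilatation/aneurysm) the lumen, in units of the normal
#' radius. \code{gap} is the straight-tube distance separating the start of
#' this segment from the end of the previous one (or from the inlet for the
#' first segment).
#'
#' @param delta Maximum lumen projection; \code{delta < 1} (a stenosis may
#'   not occlude the lumen), negative values give a dilatation.
#' @param length Segment length \eqn{l_i > 0}.
#' @param gap Distance \eqn{d_i \ge 0} from the end of the previous
#'   segment (or the inlet).
#' @return An object of class \code{"vessel_segment"}.
#' @examples
#' vessel_segment(delta = 0.2, length = 1, gap = 2)   # stenosis
#' vessel_segment(delta = -0.2, length = 1, gap = 2)  # dilatation
#' @export
vessel_segment <- function(delta, length, gap) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(length), base::length(length) == 1L, is.finite(length),
            is.numeric(gap), base::length(gap) == 1L, is.finite(gap))
  if (length <= 0) stop("segment 'length' must be positive, got ", length)
  if (gap < 0) stop("segment 'gap' must be nonnegative, got ", gap)
  if (delta >= 1) stop("'delta' must be < 1 (occlusion), got ", delta)
  structure(list(delta = as.numeric(delta), length = as.numeric(length),
                 gap = as.numeric(gap)),
            class = "vessel_segment")
}

#' Tapered vessel geometry with abnormal segments
#'
#' Describes the wall profile \eqn{R(z)} of a slowly tapering tube of total
#' length \eqn{L} carrying an ordered sequence of cosine-shaped abnormal
#' segments. Outside the segments the radius is the taper line
#' \eqn{1 - \zeta z}; inside segment \eqn{i} (spanning
#' \eqn{\alpha_i \le z \le \beta_i}) it is
#' \deqn{R(z) = (1-\zeta z)\,[1 - (\delta_i/2)(1 + \cos(2\pi(z - \alpha_i -
#'   l_i/2)/l_i))],}
#' which meets the taper line continuously at both ends and reaches its
#' extremum \eqn{(1-\zeta z)(1-\delta_i)} at the segment midpoint.
#'
#' @param zeta Taper slope \eqn{\zeta = \tan\phi}; positive for a
#'   converging (narrowing) tube, negative for diverging, zero for none.
#' @param segments List of \code{\link{vessel_segment}} objects (or
#'   three-element lists with fields \code{delta}, \code{length},
#'   \code{gap}), ordered along the axis. May be empty.
#' @param total_length Tube length \eqn{L > 0} in units of the normal
#'   radius.
#' @return An object of class \code{"vessel_geometry"} with components
#'   \code{zeta}, \code{segments}, \code{total_length} and the derived
#'   boundary matrix \code{bounds} (columns \code{alpha}, \code{beta}).
#' @seealso \code{\link{vessel_radius}}, \code{\link{segment_bounds}},
#'   \code{\link{default_geometry}}
#' @examples
#' geo <- vessel_geometry(zeta = 0.01,
#'                        segments = list(vessel_segment(0.2, 1, 2),
#'                                        vessel_segment(-0.2, 1, 2)),
#'                        total_length = 7)
#' vessel_radius(geo, c(2.5, 5.5))
#' @export
vessel_geometry <- function(zeta = 0, segments = list(), total_length = 7) {
  stopifnot(is.numeric(zeta), length(zeta) == 1L, is.finite(zeta),
            is.numeric(total_length), length(total_length) == 1L,
            is.finite(total_length), is.list(segments))
  if (total_length <= 0)
    stop("'total_length' must be positive, got ", total_length)
  if (1 - zeta * total_length <= 0)
    stop("taper closes the tube: need 1 - zeta*L > 0, got ",
         1 - zeta * total_length)
  segments <- lapply(segments, function(s)
    if (inherits(s, "vessel_segment")) s
    else vessel_segment(s$delta, s$length, s$gap))
  geo <- structure(list(zeta = as.numeric(zeta), segments = segments,
                        total_length = as.numeric(total_length)),
                   class = "vessel_geometry")
  geo$bounds <- segment_bounds(geo)
  geo
}

#' Segment boundary positions
#'
#' Axial positions where each abnormal segment begins and ends:
#' \eqn{\alpha_i = \sum_{j \le i} (d_j + l_j) - l_i} and
#' \eqn{\beta_i = \alpha_i + l_i}. Segments accumulate left to right, so
#' they can never overlap by construction; the only failure mode is a
#' segment extending past the end of the tube.
#'
#' @param geometry A \code{\link{vessel_geometry}}.
#' @return A numeric matrix with one row per segment and columns
#'   \code{alpha}, \code{beta}; zero rows for an empty segment list.
#' @examples
#' geo <- default_geometry()
#' segment_bounds(geo)  # stenosis [2,3], dilatation [5,6]
#' @export
segment_bounds <- function(geometry) {
  segs <- geometry$segments
  m <- length(segs)
  out <- matrix(numeric(0), nrow = 0, ncol = 2,
                dimnames = list(NULL, c("alpha", "beta")))
  if (m == 0L) return(out)
  lens <- vapply(segs, `[[`, numeric(1), "length")
  gaps <- vapply(segs, `[[`, numeric(1), "gap")
  beta <- cumsum(gaps + lens)
  alpha <- beta - lens
  for (i in seq_len(m)) {
    if (beta[i] > geometry$total_length + 1e-12)
      stop("segment ", i, " ends at z = ", beta[i],
           ", beyond the tube length L = ", geometry$total_length)
  }
  cbind(alpha = alpha, beta = beta)
}

#' Vessel wall radius
#'
#' Evaluates the wall profile \eqn{R(z)} of a tapered vessel with abnormal
#' segments. Vectorised over \code{z}; the profile is continuous
#' everywhere (the cosine bump vanishes at segment boundaries).
#'
#' @param geometry A \code{\link{vessel_geometry}}.
#' @param z Axial position(s), \eqn{0 \le z \le L}.
#' @return Numeric vector of radii, same length as \code{z}.
#' @examples
#' vessel_radius(default_geometry(), 2.5)   # 0.78 at the stenosis throat
#' vessel_radius(default_geometry(), 5.5)   # 1.134 at the dilatation crest
#' @export
vessel_radius <- function(geometry, z) {
  stopifnot(inherits(geometry, "vessel_geometry"), is.numeric(z))
  if (length(z) == 0L) return(numeric(0))
  if (any(!is.finite(z)) || any(z < -1e-12) ||
      any(z > geometry$total_length + 1e-12))
    stop("z must lie within [0, L] = [0, ", geometry$total_length, "]")
  R <- 1 - geometry$zeta * z
  b <- geometry$bounds
  for (i in seq_len(nrow(b))) {
    a <- b[i, "alpha"]; li <- b[i, "beta"] - a
    del <- geometry$segments[[i]]$delta
    inside <- z >= a & z <= b[i, "beta"]
    if (any(inside)) {
      bump <- 1 - (del / 2) * (1 + cos(2 * pi * (z[inside] - a - li / 2) / li))
      R[inside] <- R[inside] * bump
    }
  }
  R
}

#' Radius profile over a grid
#'
#' Convenience wrapper returning a two-column data frame of the wall
#' profile, ready for CSV export or plotting.
#'
#' @param geometry A \code{\link{vessel_geometry}}.
#' @param z_grid Ordered numeric vector of axial positions within
#'   \eqn{[0, L]}.
#' @return A data frame with columns \code{z} and \code{R}.
#' @export
radius_profile <- function(geometry, z_grid) {
  data.frame(z = as.numeric(z_grid), R = vessel_radius(geometry, z_grid))
}

#' Default demonstration geometry
#'
#' A tube of length 7 with a stenosis of depth 0.2 spanning \eqn{z \in
#' [2,3]} and a dilatation of depth 0.2 spanning \eqn{z \in [5,6]}
#' (segments \code{(delta, length, gap)} of \code{(0.2, 1, 2)} and
#' \code{(-0.2, 1, 2)}). With the default taper \code{zeta = 0.01} the
#' stenosis throat radius is \eqn{0.975 \times 0.8 = 0.78} and the
#' dilatation crest radius is \eqn{0.945 \times 1.2 = 1.134}.
#'
#' @param zeta Taper slope; default 0.01 (converging).
#' @return A \code{\link{vessel_geometry}}.
#' @export
default_geometry <- function(zeta = 0.01) {
  vessel_geometry(zeta = zeta,
                  segments = list(vessel_segment(0.2, 1, 2),
                                  vessel_segment(-0.2, 1, 2)),
                  total_length = 7)
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("Vessel geometry: L = %g, zeta = %g, %d abnormal segment(s)\n",
              x$total_length, x$zeta, length(x$segments)))
  b <- x$bounds
  for (i in seq_len(nrow(b))) {
    d <- x$segments[[i]]$delta
    cat(sprintf("  segment %d: %s delta = %g on z in [%g, %g]\n", i,
                if (d >= 0) "stenosis " else "dilatation", d,
                b[i, "alpha"], b[i, "beta"]))
  }
  invisible(x)
}
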