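# simple stderr logger; level set via option hbflow.log_level
.log_levels <- c(debug = 1L, info = 2L, warning = 3L)

hb_log <- function(level, ...) {
  threshold <- getOption("hbflow.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]])
    message("[", level, "] ", ...)
  invisible(NULL)
}

#' Default run configuration
#'
#' The baseline parameter set used throughout: a shear-thinning
#' Herschel-Bulkley fluid (\eqn{n = 0.8}, \eqn{k = 1.2}, \eqn{\tau_y =
#' 0.1}) flowing at \eqn{Q = 1} through the converging-tapered
#' (\eqn{\zeta = 0.01}) demonstration vessel of
#' \code{\link{default_geometry}}.
#'
#' @return A named list (class \code{"hb_config"}) with components
#'   \code{fluid}, \code{geometry}, \code{Q}, \code{grids},
#'   \code{method}, \code{log_level}.
#' @export
default_config <- function() {
  structure(list(
    fluid = list(n = 0.8, k = 1.2, tau_y = 0.1),
    geometry = list(zeta = 0.01,
                    segments = list(list(delta = 0.2, length = 1, gap = 2),
                                    list(delta = -0.2, length = 1, gap = 2)),
                    total_length = 7),
    Q = 1,
    grids = list(dz = 0.001, r_count = 50),
    method = "numerical",
    log_level = "info"), class = "hb_config")
}

.config_keys <- c("fluid", "geometry", "Q", "grids", "method", "log_level")

.validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.config_keys, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  fl <- as_hb_fluid(cfg$fluid)            # validates n, k, tau_y
  geo <- with(cfg$geometry,
              vessel_geometry(zeta, segments, total_length))
  if (!(is.numeric(cfg$Q) && cfg$Q > 0)) stop("config field 'Q' must be > 0")
  if (!(is.numeric(cfg$grids$dz) && cfg$grids$dz > 0))
    stop("config field 'grids.dz' must be > 0")
  if (!cfg$method %in% c("numerical", "analytical"))
    stop("config field 'method' must be 'numerical' or 'analytical'")
  if (!cfg$log_level %in% names(.log_levels))
    stop("config field 'log_level' must be one of ",
         paste(names(.log_levels), collapse = "/"))
  list(config = cfg, fluid = fl, geometry = geo)
}

#' Read and write run configurations
#'
#' Configurations are stored as JSON and round-trip losslessly. Unknown
#' keys are rejected (strict mode) so typos fail loudly; numeric fields
#' are validated on load.
#'
#' @param path File path.
#' @param cfg A configuration list, e.g. from \code{\link{default_config}}.
#' @return \code{load_config} returns the validated \code{"hb_config"}
#'   list; \code{save_config} returns \code{path} invisibly.
#' @examples
#' p <- tempfile(fileext = ".json")
#' save_config(default_config(), p)
#' identical(unclass(load_config(p))$fluid, default_config()$fluid)
#' @export
load_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  cfg$geometry$segments <- lapply(cfg$geometry$segments, as.list)
  .validate_config(cfg)
  structure(cfg, class = "hb_config")
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  .validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build the flow problem described by a configuration
#'
#' @param cfg An \code{"hb_config"} list.
#' @return List with validated \code{fluid} (\code{\link{hb_fluid}}) and
#'   \code{geometry} (\code{\link{vessel_geometry}}) plus the scalar
#'   settings.
#' @export
config_problem <- function(cfg) {
  v <- .validate_config(cfg)
  list(fluid = v$fluid, geometry = v$geometry, Q = cfg$Q,
       dz = cfg$grids$dz, r_count = cfg$grids$r_count,
       method = cfg$method)
}

#' Pressure gradients at the abnormal-segment midpoints
#'
#' The model's central numerical comparison: at the midpoint of each
#' abnormal segment (stenosis throat and dilatation crest), compute the
#' pressure gradient for each requested yield stress both exactly
#' (Newton-Raphson root of the implicit relation) and from the
#' small-yield-stress expansion, together with their relative deviation.
#' With the defaults this mirrors the reference tabulation for the
#' converging-tapered vessel: stenosis-throat radius 0.78 and
#' dilatation-crest radius 1.134.
#'
#' @param tau_y Yield-stress values; default
#'   \code{c(0.05, 0.1, 0.4, 0.8, 1.2, 1.6, 2, 2.4)}.
#' @param n,k Fluid indices; defaults 0.8 and 1.2.
#' @param Q Prescribed flow rate; default 1.
#' @param geometry Vessel; default \code{\link{default_geometry}()}.
#' @param quad_coef Quadratic-coefficient function for the expansion.
#' @return A data frame with columns \code{location} (\code{"stenosis"} /
#'   \code{"dilatation"}), \code{z}, \code{R}, \code{tau_y},
#'   \code{q_numerical}, \code{q_analytical}, \code{rel_error_pct}.
#' @examples
#' tab <- pressure_gradient_table(tau_y = c(0.05, 2.4))
#' subset(tab, location == "stenosis")
#' @export
pressure_gradient_table <- function(tau_y = c(0.05, 0.1, 0.4, 0.8, 1.2,
                                              1.6, 2, 2.4),
                                    n = 0.8, k = 1.2, Q = 1,
                                    geometry = default_geometry(),
                                    quad_coef = hb_quadratic_coef) {
  b <- geometry$bounds
  if (nrow(b) == 0L) stop("geometry has no abnormal segments")
  mids <- (b[, "alpha"] + b[, "beta"]) / 2
  deltas <- vapply(geometry$segments, `[[`, numeric(1), "delta")
  loc <- ifelse(deltas > 0, "stenosis", "dilatation")
  rows <- list()
  for (i in seq_along(mids)) {
    R <- vessel_radius(geometry, mids[i])
    for (ty in tau_y) {
      fl <- hb_fluid(n, k, ty)
      qn <- solve_pressure_gradient(R, Q, fl)
      qa <- q_analytical(R, Q, fl, quad_coef)
      rows[[length(rows) + 1L]] <- data.frame(
        location = loc[i], z = mids[i], R = R, tau_y = ty,
        q_numerical = qn, q_analytical = qa,
        rel_error_pct = 100 * abs(qa - qn) / qn)
    }
  }
  do.call(rbind, rows)
}

# --- CSV writers -------------------------------------------------------------

.write_csv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export results as CSV
#'
#' Writers for the package's tabular outputs. Metadata (parameters,
#' station info) goes into leading \code{#}-prefixed comment lines;
#' columns use a header row and \code{.} decimal separator.
#'
#' \itemize{
#'   \item \code{write_profile_csv}: axial profile of an
#'     \code{\link{hb_flow}} fit — columns \code{z, R, q, tau_w, lambda}.
#'   \item \code{write_radial_csv}: a \code{\link{radial_field}} —
#'     columns \code{r, w, psi}.
#'   \item \code{write_field_csv}: a \code{\link{field_grid}} in long
#'     format — columns \code{z, r_over_R, w, psi}.
#' }
#'
#' @param x The object to export.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "hb_flow"))
  f <- x$fluid
  .write_csv_meta(predict(x), path,
                  meta = c(sprintf("n=%g k=%g tau_y=%g Q=%g method=%s",
                                   f$n, f$k, f$tau_y, x$Q, x$method)))
}

#' @rdname write_profile_csv
#' @export
write_radial_csv <- function(x, path) {
  stopifnot(inherits(x, "radial_field"))
  .write_csv_meta(data.frame(r = x$r, w = x$w, psi = x$psi), path,
                  meta = sprintf("z=%g R=%g q=%.10g R_p=%.10g",
                                 x$z, x$R, x$q, x$plug_radius))
}

#' @rdname write_profile_csv
#' @export
write_field_csv <- function(x, path) {
  stopifnot(inherits(x, "hb_field_grid"))
  long <- data.frame(
    z = rep(x$z, times = length(x$r_fraction)),
    r_over_R = rep(x$r_fraction, each = length(x$z)),
    w = as.vector(x$w), psi = as.vector(x$psi))
  .write_csv_meta(long, path,
                  meta = sprintf("Q=%g method=%s", x$Q, x$method))
}
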