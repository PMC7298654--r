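# Strain-rate metrics on the meridional plane.
#
# The three scalar metrics are the planar in-plane shear rate
#   epsilon = du/dy + dv/dx,
# the planar extensional strain rate
#   eta = du/dx + dv/dy,
# and the total shear-rate magnitude built from all nine velocity gradients,
#   |gamma| = [ 2(du/dx)^2 + 2(dv/dy)^2 + 2(dw/dz)^2 + (dv/dx + du/dy)^2
#               + (dw/dy + dv/dz)^2 + (du/dz + dw/dx)^2 ]^(1/2),
# with the out-of-plane entries supplied by the convention recorded in the
# gradient tensor (see compute_gradients).

metric_field <- function(values, grad, metric) {
  structure(list(values = values, x = grad$x, sigma = grad$sigma, a = grad$a,
                 weight = grad$weight_xy, metric = metric,
                 convention = grad$convention),
            class = "metric_field")
}

#' In-plane shear rate field
#'
#' `epsilon = du/dy + dv/dx` pointwise on the sampling grid.
#'
#' @param grad A [velocity_gradients][compute_gradients()] object.
#' @return A `metric_field` (values in 1/s).
#' @export
inplane_shear <- function(grad) {
  stopifnot(inherits(grad, "velocity_gradients"))
  metric_field(grad$du_dy + grad$dv_dx, grad, "epsilon")
}

#' Extensional strain rate field
#'
#' `eta = du/dx + dv/dy` pointwise on the sampling grid.
#'
#' @inheritParams inplane_shear
#' @return A `metric_field` (values in 1/s).
#' @export
extensional_strain <- function(grad) {
  stopifnot(inherits(grad, "velocity_gradients"))
  metric_field(grad$du_dx + grad$dv_dy, grad, "eta")
}

#' Total shear-rate magnitude field
#'
#' The scalar norm of the full strain-rate tensor assembled from all nine
#' velocity gradients, with out-of-plane entries per the gradient tensor's
#' convention. Zero exactly where all nine gradients vanish.
#'
#' @inheritParams inplane_shear
#' @return A `metric_field` (values in 1/s, non-negative).
#' @export
total_shear_eq1 <- function(grad) {
  stopifnot(inherits(grad, "velocity_gradients"))
  v <- sqrt(2 * grad$du_dx^2 + 2 * grad$dv_dy^2 + 2 * grad$dw_dz^2 +
              (grad$dv_dx + grad$du_dy)^2 +
              (grad$dw_dy + grad$dv_dz)^2 +
              (grad$du_dz + grad$dw_dx)^2)
  metric_field(v, grad, "gamma_total")
}

#' Extract an analysis plane from a metric field
#'
#' `"xy_meridional"` returns the meridional field itself (optionally
#' restricted to an axial window) with cell-area weights; `"yz_cross_section"`
#' returns the transverse disk at axial position `x0`: by axisymmetry the
#' value at radius `rho` equals the meridional value at `y = rho`, and each
#' radial sample carries an annular area weight proportional to `rho`.
#'
#' @param metrics A `metric_field`.
#' @param plane `"xy_meridional"` or `"yz_cross_section"`.
#' @param x0 Axial position of the cross-section, meters (required for yz).
#' @param window Optional axial window for the xy plane.
#' @return A `plane_field`: `values` and matching area `weights`, plus
#'   provenance (`plane`, `x0`, metric name).
#' @export
extract_plane <- function(metrics, plane = c("xy_meridional",
                                             "yz_cross_section"),
                          x0 = NULL, window = NULL) {
  plane <- match.arg(plane)
  stopifnot(inherits(metrics, "metric_field"))
  if (plane == "xy_meridional") {
    keep <- seq_along(metrics$x)
    if (!is.null(window))
      keep <- which(metrics$x >= window[1] & metrics$x <= window[2])
    out <- list(values = metrics$values[keep, , drop = FALSE],
                weights = metrics$weight[keep, , drop = FALSE],
                x = metrics$x[keep], sigma = metrics$sigma,
                plane = plane, x0 = NULL, metric = metrics$metric)
  } else {
    if (is.null(x0)) stop("yz cross-section requires `x0`", call. = FALSE)
    if (x0 < min(metrics$x) || x0 > max(metrics$x))
      stop("x0 outside the sampled axial range", call. = FALSE)
    i <- which.min(abs(metrics$x - x0))
    pos <- metrics$sigma >= 0
    rho <- metrics$sigma[pos] * metrics$a[i]
    out <- list(values = metrics$values[i, pos], weights = rho,
                rho = rho, plane = plane, x0 = metrics$x[i],
                metric = metrics$metric)
  }
  structure(out, class = "plane_field")
}

#' Frequency distribution of a metric on a plane
#'
#' Area-weighted histogram of the absolute metric values: meridional cells
#' are weighted by their physical area, cross-section samples by their
#' annulus area, so the Cartesian appearance of the disk does not bias the
#' distribution. Frequencies sum to one.
#'
#' @param plane A [plane_field][extract_plane()].
#' @param bin_width Bin width in 1/s (default 100, matching the conventional
#'   100 and 600 1/s exposure breakpoints).
#' @return A `shear_histogram`: `breaks`, `mids`, `frequency` (sums to 1),
#'   and provenance.
#' @export
shear_histogram <- function(plane, bin_width = 100) {
  stopifnot(inherits(plane, "plane_field"))
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  v <- abs(as.numeric(plane$values))
  w <- as.numeric(plane$weights)
  if (length(v) == 0) stop("empty plane field", call. = FALSE)
  top <- max(v)
  breaks <- seq(0, bin_width * max(1, ceiling(top / bin_width + 1e-12)),
                by = bin_width)
  idx <- pmin(findInterval(v, breaks, rightmost.closed = TRUE,
                           left.open = FALSE), length(breaks) - 1L)
  freq <- vapply(seq_len(length(breaks) - 1L),
                 function(b) sum(w[idx == b]), numeric(1))
  freq <- freq / sum(freq)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 frequency = freq, plane = plane$plane, x0 = plane$x0,
                 metric = plane$metric, bin_width = bin_width,
                 weighting = "area"),
            class = "shear_histogram")
}

# Analysis window around a pump: the footprint extended by half a
# deformation length each side, clipped to the tube.
pump_window <- function(config, pump_index, margin = 0.5) {
  p <- config$pumps[[pump_index]]
  half <- (0.5 + margin) * p$deformation_length_m
  c(max(0, p$center_m - half), min(config$tube$length_m, p$center_m + half))
}

# Metric fields (epsilon, eta, gamma) for one pump window at time t.
window_metrics <- function(solution, pump_index, t = NULL, nx = 241L,
                           ny = 81L,
                           convention = "paper_substitution") {
  if (is.null(t))
    t <- deepest_occlusion_time(solution$config, t_min = min(solution$t))
  win <- pump_window(solution$config, pump_index)
  fld <- reconstruct_velocity(solution, t, window = win, nx = nx, ny = ny)
  g <- compute_gradients(fld, convention)
  list(epsilon = inplane_shear(g), eta = extensional_strain(g),
       gamma = total_shear_eq1(g), field = fld, t = t, window = win)
}

# Max |metric| on the meridional window of one pump (calibration observable).
max_plane_metric <- function(solution, pump_index,
                             metric = c("epsilon", "eta", "gamma"),
                             t = NULL, nx = 241L, ny = 81L,
                             convention = "paper_substitution") {
  metric <- match.arg(metric)
  wm <- window_metrics(solution, pump_index, t, nx, ny, convention)
  max(abs(wm[[metric]]$values))
}

max_with_location <- function(mf) {
  idx <- arrayInd(which.max(abs(mf$values)), dim(mf$values))
  list(value = abs(mf$values[idx]), x = mf$x[idx[1]], sigma = mf$sigma[idx[2]])
}

#' Per-scenario shear report
#'
#' Runs the lubrication solver for a configuration, reconstructs the
#' velocity field at the deepest-occlusion instant of the cycle, and reports,
#' for every pump: the maxima of the in-plane shear rate, extensional strain
#' rate and total shear-rate magnitude on the meridional (xy) window and on
#' the transverse (yz) disk at the pump center, together with area-weighted
#' frequency distributions of the total magnitude and cycle-averaged axial
#' pressure/flow profiles.
#'
#' @param config A [cascade_config()] (or a `flow_solution` to reuse).
#' @param fluid Fluid model.
#' @param nx,ny Window grid resolution.
#' @param bin_width Histogram bin width, 1/s.
#' @param convention Gradient convention, see [compute_gradients()].
#' @param ... Passed to [solve_flow()] when `config` is a configuration.
#' @return A `shear_report` object.
#' @export
shear_report <- function(config, fluid = newtonian_fluid(), nx = 241L,
                         ny = 81L, bin_width = 100,
                         convention = "paper_substitution", ...) {
  solution <- if (inherits(config, "flow_solution")) config
              else solve_flow(config, fluid, ...)
  config <- solution$config
  if (length(config$pumps) == 0) stop("no pumps to report on", call. = FALSE)
  t_deep <- deepest_occlusion_time(config, t_min = min(solution$t))
  cy <- cycle_average(solution)
  pumps <- vector("list", length(config$pumps))
  for (i in seq_along(config$pumps)) {
    wm <- window_metrics(solution, i, t_deep, nx, ny, convention)
    xc <- config$pumps[[i]]$center_m
    yz <- lapply(wm[c("epsilon", "eta", "gamma")], extract_plane,
                 plane = "yz_cross_section", x0 = xc)
    xy <- lapply(wm[c("epsilon", "eta", "gamma")], extract_plane,
                 plane = "xy_meridional")
    pumps[[i]] <- list(
      center_m = xc,
      occlusion = config$pumps[[i]]$occlusion,
      window = wm$window,
      xy = lapply(wm[c("epsilon", "eta", "gamma")], max_with_location),
      yz = lapply(yz, function(pf) list(value = max(abs(pf$values)),
                                        x0 = pf$x0)),
      hist_xy = shear_histogram(xy$gamma, bin_width),
      hist_yz = shear_histogram(yz$gamma, bin_width))
  }
  structure(list(pumps = pumps, t_deep = t_deep,
                 profiles = list(x = cy$x, p_mean = cy$p_mean,
                                 p_peak = cy$p_peak, Q_mean = cy$Q_mean,
                                 Q_peak = cy$Q_peak,
                                 sampling = "y = r/2 (pressure is radially
uniform in the lubrication limit)"),
                 p_max = max(solution$p), Q_net = cy$Q_net,
                 convention = convention, bin_width = bin_width,
                 config = config, fluid = solution$fluid,
                 calibration = attr(config, "calibration")),
            class = "shear_report")
}

# Global (over pumps) maxima of a report on one plane.
report_max <- function(report, metric = "gamma", plane = c("xy", "yz")) {
  plane <- match.arg(plane)
  max(vapply(report$pumps, function(p) p[[plane]][[metric]]$value, numeric(1)))
}

#' @export
print.shear_report <- function(x, ...) {
  cat(sprintf("<shear_report> %d pump(s), convention = %s\n",
              length(x$pumps), x$convention))
  for (p in x$pumps)
    cat(sprintf(
      "  pump %.2f m (phi %.4f): xy max eps %.4g, eta %.4g, |gamma| %.4g 1/s; yz max |gamma| %.4g\n",
      p$center_m, p$occlusion, p$xy$epsilon$value, p$xy$eta$value,
      p$xy$gamma$value, p$yz$gamma$value))
  cat(sprintf("  max pressure %.4g Pa, net flow %.4g m^3/s\n",
              x$p_max, x$Q_net))
  invisible(x)
}

#' Compare shear reports across pumping conditions
#'
#' Tabulates the per-plane maxima of two or more scenarios, their ratios
#' (first scenario / each other) and fold reductions
#' `(first - other) / other`.
#'
#' @param reports Named list of `shear_report`s (>= 2); the first is the
#'   reference (typically single pumping).
#' @return A `shear_comparison`: data frame `table` plus the histograms.
#' @export
compare_conditions <- function(reports) {
  stopifnot(length(reports) >= 2,
            all(vapply(reports, inherits, logical(1), "shear_report")))
  if (is.null(names(reports)))
    names(reports) <- paste0("scenario_", seq_along(reports))
  rows <- list()
  for (metric in c("epsilon", "eta", "gamma")) {
    for (plane in c("xy", "yz")) {
      vals <- vapply(reports, report_max, numeric(1), metric = metric,
                     plane = plane)
      rows[[paste(metric, plane, sep = "_")]] <-
        data.frame(metric = metric, plane = plane,
                   scenario = names(reports), max_value = vals,
                   ratio_to_first = vals[1] / vals,
                   fold_reduction = (vals[1] - vals) / vals,
                   row.names = NULL)
    }
  }
  pmax_ <- vapply(reports, function(r) r$p_max, numeric(1))
  rows$pressure <- data.frame(metric = "pressure", plane = "axial",
                              scenario = names(reports), max_value = pmax_,
                              ratio_to_first = pmax_[1] / pmax_,
                              fold_reduction = (pmax_[1] - pmax_) / pmax_,
                              row.names = NULL)
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 histograms = lapply(reports, function(r)
                   lapply(r$pumps, function(p) p$hist_xy))),
            class = "shear_comparison")
}

#' @export
print.shear_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
plot.shear_report <- function(x, pump = 1L, ...) {
  h <- x$pumps[[pump]]$hist_xy
  graphics::barplot(h$frequency, names.arg = round(h$mids),
                    xlab = "total shear-rate magnitude (1/s)",
                    ylab = "area-weighted frequency", ...)
  invisible(x)
}
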