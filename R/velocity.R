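# Meridional velocity reconstruction.
#
# The lubrication closure gives a locally parabolic axial profile
#   u(x, y, t) = (2 Q / (pi a^2)) (1 - y^2 / a^2),    y in [-a, a]
# and the radial velocity follows by exact radial integration of the
# axisymmetric continuity equation from the axis,
#   v(x, y) = -(1/y) d/dx [ (Q/pi) (y^2/a^2 - y^4/(2 a^4)) ],
# which satisfies v(x, +/-a) = +/- da/dt identically (wall kinematics).
# Fields are sampled on a body-fitted grid (x_i, sigma_j) with sigma = y / a.

#' Reconstruct the meridional velocity field
#'
#' Samples the axial velocity `u` and radial velocity `v` at one instant on a
#' body-fitted meridional grid: axial nodes spanning a window of the tube and
#' signed radial coordinate `y = sigma * a(x)`, `sigma` in `[-1, 1]`. The
#' axial profile is the lubrication parabola consistent with the local flow
#' rate; the radial velocity is the exact continuity integral and matches the
#' wall velocity at `y = +/- a`.
#'
#' @param solution A `flow_solution` (its config/fluid are used to recompute
#'   the flow rate at exactly time `t` on the requested axial grid).
#' @param t Time, seconds, within the solution span.
#' @param window Axial window `c(x0, x1)` in meters; default the whole tube.
#' @param nx,ny Number of axial and radial sample nodes (`ny` counts the
#'   full signed range).
#' @return A `velocity_field`: grids `x`, `sigma`, matrices `u`, `v`
#'   (rows = x, cols = sigma), wall data `a`, `adot`, `aslope`, flow rate
#'   `Q`, and metadata.
#' @export
reconstruct_velocity <- function(solution, t, window = NULL,
                                 nx = 241L, ny = 81L) {
  stopifnot(inherits(solution, "flow_solution"))
  if (t < min(solution$t) - 1e-9 || t > max(solution$t) + 1e-9)
    stop("t outside the solution time span", call. = FALSE)
  config <- solution$config
  L <- config$tube$length_m
  if (is.null(window)) window <- c(0, L)
  if (window[1] < 0 || window[2] > L || window[1] >= window[2])
    stop("window outside tube", call. = FALSE)
  # global fine solve at this instant so that Q0 (a tube-wide integral) and
  # the window values come from one consistent quadrature
  nglob <- max(2001L, solution$config$tube$n_axial)
  xg <- seq(0, L, length.out = nglob)
  snap <- flow_snapshot(config, solution$fluid, t, xg, solution$age_s)
  x <- seq(window[1], window[2], length.out = nx)
  wk <- wall_kinematics(config, x, t)
  r0 <- config$tube$inner_radius_m
  a <- wk$a; adot <- wk$adot; aslp <- wk$aslope
  # Q on the window grid: Q0 from the global solve minus the local cumulative
  # source, anchored at the window start by interpolation of the global C
  S <- wk$S
  Cw <- as.numeric(pracma::cumtrapz(x, S))
  C0 <- stats::approx(xg, snap$Q0 - snap$Q, xout = window[1])$y
  Q <- snap$Q0 - (C0 + Cw)
  Qp <- -S                                   # dQ/dx from continuity (exact)
  sigma <- seq(-1, 1, length.out = ny)
  u <- outer(2 * Q / (pi * a^2), 1 - sigma^2)
  # v(x, y) with y = sigma a:  v = -y [ (Q'/pi)(1/a^2 - y^2/(2a^4))
  #                                   + (Q/pi)(-2 a'/a^3 + 2 y^2 a'/a^5) ]
  Y <- outer(a, sigma)
  term1 <- outer(Qp / pi, rep(1, ny)) *
    (outer(1 / a^2, rep(1, ny)) - Y^2 / (2 * outer(a^4, rep(1, ny))))
  term2 <- outer(Q / pi, rep(1, ny)) *
    (outer(-2 * aslp / a^3, rep(1, ny)) + 2 * Y^2 * outer(aslp / a^5, rep(1, ny)))
  v <- -Y * (term1 + term2)
  structure(list(x = x, sigma = sigma, u = u, v = v,
                 a = a, adot = adot, aslope = aslp, Q = Q, t = t,
                 r0 = r0, config = config),
            class = "velocity_field")
}

#' Analytic test velocity fields
#'
#' Closed-form meridional fields on a straight tube of radius `a`, with their
#' known strain-rate metrics attached for use as verification oracles:
#' `"poiseuille"` (parabolic axial flow carrying flow rate `Q`), `"rigid"`
#' (uniform translation at speed `U`), and `"pure_extension"` (axisymmetric
#' uniaxial extension `u = alpha x`, `v = -alpha y / 2`).
#'
#' @param kind One of `"poiseuille"`, `"rigid"`, `"pure_extension"`.
#' @param params Named list of parameters: `Q` (m^3/s) and `a` (m) for
#'   Poiseuille; `U` (m/s) and `a` for rigid; `alpha` (1/s) and `a` for pure
#'   extension.
#' @param window Axial window `c(x0, x1)`, meters.
#' @param nx,ny Grid sizes as in [reconstruct_velocity()].
#' @return A `velocity_field` with an `oracle` attribute listing closed-form
#'   metric values (`epsilon_wall`, `eta`, `gamma_wall` under the
#'   substitution convention).
#' @export
make_fixture <- function(kind = c("poiseuille", "rigid", "pure_extension"),
                         params = list(), window = c(0, 0.02),
                         nx = 81L, ny = 61L) {
  kind <- match.arg(kind)
  a0 <- if (is.null(params$a)) 0.8e-3 else params$a
  x <- seq(window[1], window[2], length.out = nx)
  sigma <- seq(-1, 1, length.out = ny)
  a <- rep(a0, nx)
  zero <- matrix(0, nx, ny)
  if (kind == "poiseuille") {
    Q <- if (is.null(params$Q)) 1e-8 else params$Q
    u <- outer(2 * Q / (pi * a^2), 1 - sigma^2)
    v <- zero
    oracle <- list(epsilon_wall = 4 * Q / (pi * a0^3), eta = 0,
                   gamma_wall = sqrt(2) * 4 * abs(Q) / (pi * a0^3))
    Qx <- rep(Q, nx)
  } else if (kind == "rigid") {
    U <- if (is.null(params$U)) 0.01 else params$U
    u <- matrix(U, nx, ny)
    v <- zero
    oracle <- list(epsilon_wall = 0, eta = 0, gamma_wall = 0)
    Qx <- rep(U * pi * a0^2, nx)
  } else {
    alpha <- if (is.null(params$alpha)) 1 else params$alpha
    u <- matrix(rep(alpha * x, ny), nx, ny)
    v <- -alpha / 2 * outer(a, sigma)
    # eta = du/dx + dv/dy = alpha/2; eq-1 magnitude under substitution = 2 alpha
    oracle <- list(epsilon_wall = 0, eta = alpha / 2,
                   gamma_wall = 2 * abs(alpha))
    Qx <- alpha * x * pi * a0^2 / 2  # flux of the parabola-free profile (info)
  }
  structure(list(x = x, sigma = sigma, u = u, v = v, a = a,
                 adot = rep(0, nx), aslope = rep(0, nx), Q = Qx, t = 0,
                 r0 = a0, config = NULL),
            class = "velocity_field", oracle = oracle, kind = kind)
}

# Central differences along rows/cols with 2nd-order one-sided ends.
fd_d1 <- function(M, h, along = c("row", "col")) {
  along <- match.arg(along)
  if (along == "col") return(t(fd_d1(t(M), h, "row")))
  n <- nrow(M)
  if (n < 3) stop("grid too coarse for finite differences (< 3 points)",
                  call. = FALSE)
  D <- matrix(0, n, ncol(M))
  D[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) / (2 * h)
  D[1, ] <- (-3 * M[1, ] + 4 * M[2, ] - M[3, ]) / (2 * h)
  D[n, ] <- (3 * M[n, ] - 4 * M[n - 1, ] + M[n - 2, ]) / (2 * h)
  D
}

#' Nine velocity gradients of a meridional field
#'
#' Differentiates a sampled [velocity_field][reconstruct_velocity()] by
#' central differences (second-order one-sided at boundaries) on the
#' body-fitted grid, mapping back to physical derivatives via
#' `d/dy = (1/a) d/dsigma` and `d/dx|_y = d/dx|_sigma - sigma (a'/a)
#' d/dsigma`. The out-of-plane entries are filled according to the chosen
#' convention:
#'
#' * `"paper_substitution"`: the azimuthal velocity `w` is replaced by the
#'   radial one (`w := v`), and every z-derivative by its documented
#'   y-analogue: `du/dz := du/dy`, `dw/dx := dv/dx`, `dw/dy := dv/dy`,
#'   `dw/dz := dv/dy`, `dv/dz := dv/dy`.
#' * `"true_axisymmetric"`: the exact cylindrical entries for swirl-free
#'   axisymmetric flow: `w = 0`, `dw/dz = v/y` (with the axis limit
#'   `dv/dy`), `du/dz = dv/dz = dw/dx = dw/dy = 0`.
#'
#' @param field A `velocity_field`.
#' @param convention `"paper_substitution"` (default) or
#'   `"true_axisymmetric"`.
#' @return A `velocity_gradients` object: list of nine matrices `du_dx`,
#'   `du_dy`, `du_dz`, `dv_dx`, `dv_dy`, `dv_dz`, `dw_dx`, `dw_dy`, `dw_dz`
#'   (1/s), plus the grid, the convention flag and cell weights.
#' @export
compute_gradients <- function(field,
                              convention = c("paper_substitution",
                                             "true_axisymmetric")) {
  convention <- match.arg(convention)
  stopifnot(inherits(field, "velocity_field"))
  nx <- length(field$x); ny <- length(field$sigma)
  if (nx < 3 || ny < 3)
    stop("grid too coarse for gradients (< 3 points per direction)",
         call. = FALSE)
  hx <- field$x[2] - field$x[1]
  hs <- field$sigma[2] - field$sigma[1]
  ainv <- 1 / field$a
  Sg <- matrix(field$sigma, nx, ny, byrow = TRUE)
  map_x <- function(M, Msig) M - Sg * (field$aslope * ainv) * Msig
  u_sig <- fd_d1(field$u, hs, "col")
  v_sig <- fd_d1(field$v, hs, "col")
  du_dy <- ainv * u_sig
  dv_dy <- ainv * v_sig
  du_dx <- map_x(fd_d1(field$u, hx, "row"), u_sig)
  dv_dx <- map_x(fd_d1(field$v, hx, "row"), v_sig)
  if (convention == "paper_substitution") {
    g <- list(du_dx = du_dx, du_dy = du_dy, du_dz = du_dy,
              dv_dx = dv_dx, dv_dy = dv_dy, dv_dz = dv_dy,
              dw_dx = dv_dx, dw_dy = dv_dy, dw_dz = dv_dy)
  } else {
    Y <- outer(field$a, field$sigma)
    dw_dz <- field$v / Y
    on_axis <- abs(Sg) < 1e-12
    dw_dz[on_axis] <- dv_dy[on_axis]
    zero <- matrix(0, nx, ny)
    g <- list(du_dx = du_dx, du_dy = du_dy, du_dz = zero,
              dv_dx = dv_dx, dv_dy = dv_dy, dv_dz = zero,
              dw_dx = zero, dw_dy = zero, dw_dz = dw_dz)
  }
  # meridional cell area weight dx * dy = dx * a(x) dsigma (up to a constant)
  g$weight_xy <- matrix(field$a, nx, ny)
  g$x <- field$x; g$sigma = field$sigma; g$a <- field$a
  g$convention <- convention
  structure(g, class = "velocity_gradients")
}

# Discrete axisymmetric divergence du/dx + (1/y) d(y v)/dy of a field,
# evaluated away from the axis; used as a reconstruction audit.
divergence_residual <- function(field) {
  g <- compute_gradients(field, "true_axisymmetric")
  Y <- outer(field$a, field$sigma)
  div <- g$du_dx + g$dv_dy + field$v / Y
  off <- abs(matrix(field$sigma, length(field$x), length(field$sigma),
                    byrow = TRUE)) > 0.2
  scale <- max(abs(g$du_dy)) + 1e-300
  max(abs(div[off])) / scale
}
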