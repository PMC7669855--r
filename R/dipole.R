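# Equivalent current dipole modelling on a three-shell concentric sphere.
#
# The forward solution expands the dipole potential in spherical harmonics;
# for every harmonic order the radial coefficients in the brain, skull and
# scalp shells are obtained from the interface conditions (continuity of
# potential and radial current, insulating exterior) by solving a small
# linear system, so no closed-form shell formula is assumed. Potentials are
# evaluated at the scalp electrodes, average-referenced.

#' Three-shell spherical head model
#'
#' Concentric brain/skull/scalp spheres with homogeneous conductivities
#' (defaults 0.3 / 0.006 / 0.3 S/m).
#'
#' @param center sphere center (mm), default origin.
#' @param radii increasing radii (mm) of the brain, skull and scalp shells.
#' @param conductivities shell conductivities in S/m (brain, skull, scalp).
#' @return a `sphere_head_model`.
#' @export
sphere_head_model <- function(center = c(0, 0, 0),
                              radii = c(brain = 40, skull = 45, scalp = 50),
                              conductivities = c(0.3, 0.006, 0.3)) {
  radii <- unname(radii)
  if (length(radii) != 3 || any(diff(radii) <= 0) || radii[1] <= 0) {
    stopf("radii: need 0 < brain < skull < scalp")
  }
  if (length(conductivities) != 3 || any(conductivities <= 0)) {
    stopf("conductivities: three positive values required")
  }
  structure(list(center = center, radii = radii,
                 conductivities = conductivities),
            class = "sphere_head_model")
}

#' @export
print.sphere_head_model <- function(x, ...) {
  cat(sprintf(
    "<sphere_head_model> radii %s mm, conductivities %s S/m\n",
    paste(x$radii, collapse = "/"),
    paste(x$conductivities, collapse = "/")))
  invisible(x)
}

#' Idealized 7-electrode canine layout
#'
#' Electrode positions for the F3/F4/T3/T4/Cz/P3/P4 montage on the scalp
#' shell of a spherical head model: Cz at the vertex, frontal and
#' parieto-occipital pairs at 50 degrees from the vertex, temporal pairs at
#' 75 degrees. The x axis points anterior, y left, z dorsal. Positions of
#' the physical montage are not published; this layout is an explicit,
#' replaceable default.
#'
#' @param model a [sphere_head_model()].
#' @return named matrix (channels x 3) of positions in mm.
#' @export
canine_layout <- function(model = sphere_head_model()) {
  ang <- rbind(  # theta (from +z), phi (from +x toward +y), degrees
    F3 = c(50, 35), F4 = c(50, -35),
    T3 = c(75, 90), T4 = c(75, -90),
    Cz = c(0, 0),
    P3 = c(50, 145), P4 = c(50, -145)
  ) * pi / 180
  r <- model$radii[3]
  pos <- cbind(
    r * sin(ang[, 1]) * cos(ang[, 2]),
    r * sin(ang[, 1]) * sin(ang[, 2]),
    r * cos(ang[, 1])
  )
  sweep(pos, 2, model$center, "+")
}

# Per-order gain of the shell structure relative to the bare (infinite
# medium) dipole coefficient. For equal conductivities this equals
# (2n + 1) / n. Radii are scaled to the scalp radius for conditioning.
shell_gains <- function(model, n_max) {
  s <- model$radii / model$radii[3]
  sig <- model$conductivities
  s1 <- s[1]; s2 <- s[2]
  vapply(seq_len(n_max), function(n) {
    m <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # unknowns: A1, A2, B2, A3, B3
    m[1, ] <- c(s1^n, -s1^n, -s1^(-(n + 1)), 0, 0)
    rhs[1] <- -s1^(-(n + 1))
    m[2, ] <- c(sig[1] * n * s1^(n - 1), -sig[2] * n * s1^(n - 1),
                sig[2] * (n + 1) * s1^(-(n + 2)), 0, 0)
    rhs[2] <- sig[1] * (n + 1) * s1^(-(n + 2))
    m[3, ] <- c(0, s2^n, s2^(-(n + 1)), -s2^n, -s2^(-(n + 1)))
    m[4, ] <- c(0, sig[2] * n * s2^(n - 1),
                -sig[2] * (n + 1) * s2^(-(n + 2)),
                -sig[3] * n * s2^(n - 1),
                sig[3] * (n + 1) * s2^(-(n + 2)))
    m[5, ] <- c(0, 0, 0, n, -(n + 1))
    # column equilibration: the radial powers make raw columns differ by
    # many orders of magnitude at high n
    cs <- apply(abs(m), 2, max)
    z <- solve(sweep(m, 2, cs, "/"), rhs) / cs
    z[4] + z[5]     # surface coefficient A3 + B3 at scaled radius 1
  }, numeric(1))
}

# Lead vectors g(loc, elec) such that V[elec] = g . q (q in nAm, V in uV),
# vectorized over locations and electrodes via Legendre recurrences.
# Returns an array (n_elec, 3, n_loc), average-referenced across
# electrodes when average_ref = TRUE.
lead_vectors <- function(model, locations, positions, n_max = 60,
                         average_ref = TRUE) {
  locations <- matrix(locations, ncol = 3)
  loc <- sweep(locations, 2, model$center, "-") * 1e-3     # m
  pos <- sweep(positions, 2, model$center, "-") * 1e-3
  m <- nrow(loc)
  ne <- nrow(pos)
  b <- sqrt(rowSums(loc^2))
  if (any(b >= model$radii[1] * 1e-3)) {
    stopf("dipole outside the brain shell")
  }
  re <- sqrt(rowSums(pos^2))
  b_safe <- pmax(b, 1e-300)
  ur <- loc / b_safe                                  # m x 3 (0 at center)
  eu <- pos / re                                      # ne x 3 unit
  u <- tcrossprod(ur, eu)                             # m x ne, cos(gamma)
  x <- outer(b, re, "/")                              # m x ne
  gains <- shell_gains(model, n_max)
  p_prev <- matrix(1, m, ne)      # P_0
  p_cur <- u                      # P_1
  dp_prev <- matrix(0, m, ne)     # P_0'
  dp_cur <- matrix(1, m, ne)      # P_1'
  xp <- matrix(1, m, ne)          # x^(n-1), n = 1
  s_r <- gains[1] * 1 * xp * p_cur
  s_d <- gains[1] * xp * dp_cur
  for (n in 2:n_max) {
    p_new <- ((2 * n - 1) * u * p_cur - (n - 1) * p_prev) / n
    dp_new <- dp_prev + (2 * n - 1) * p_cur
    xp <- xp * x
    s_r <- s_r + gains[n] * n * xp * p_new
    s_d <- s_d + gains[n] * xp * dp_new
    p_prev <- p_cur; p_cur <- p_new
    dp_prev <- dp_cur; dp_cur <- dp_new
  }
  # g = K [ S_r ur + S_d (eu - u ur) ], K = 1 / (4 pi sigma1 R^2)
  k <- 1 / (4 * pi * model$conductivities[1] * re^2)  # per electrode
  out <- array(0, c(ne, 3, m))
  for (j in 1:3) {
    # m x ne: S_r ur_j + S_d (eu_j - u ur_j)
    gj <- s_r * ur[, j] + s_d * (matrix(eu[, j], m, ne, byrow = TRUE) -
                                   u * ur[, j])
    gj <- sweep(gj, 2, k, "*")
    out[, j, ] <- t(gj)
  }
  out <- out * 1e-9 * 1e6       # nAm in, uV out
  if (average_ref) {
    for (i in seq_len(m)) {
      out[, , i] <- sweep(out[, , i], 2, colMeans(out[, , i]), "-")
    }
  }
  out
}

#' Forward scalp potentials of a current dipole
#'
#' Analytic three-shell sphere solution, evaluated at the electrode
#' positions and average-referenced; linear in the moment vector.
#'
#' @param model a [sphere_head_model()].
#' @param location dipole location (mm), strictly inside the brain shell.
#' @param moment dipole moment vector (nAm).
#' @param positions electrode positions (n x 3, mm), e.g.
#'   [canine_layout()].
#' @param n_max series truncation order (default 60).
#' @param average_ref subtract the electrode mean (default `TRUE`).
#' @return per-electrode potentials in microvolts.
#' @export
forward_potential <- function(model, location, moment, positions,
                              n_max = 60, average_ref = TRUE) {
  L <- lead_vectors(model, matrix(location, 1), positions, n_max,
                    average_ref)[, , 1]
  as.numeric(L %*% moment)
}

#' Goodness of fit of a modeled topography
#'
#' `100 * (1 - ||observed - modeled||^2 / ||observed||^2)`, the percentage
#' of topography variance explained by the dipole model.
#'
#' @param observed,modeled numeric vectors of per-electrode potentials.
#' @return goodness of fit in percent (can be negative for a bad model).
#' @export
dipole_gof <- function(observed, modeled) {
  100 * (1 - sum((observed - modeled)^2) / sum(observed^2))
}

#' Regular source grid inside the brain shell
#'
#' Cubic grid with the given spacing, restricted to radii at most
#' `max_radius_frac` of the brain radius (the series solution degrades for
#' sources very close to the inner shell boundary).
#'
#' @param model a [sphere_head_model()].
#' @param spacing grid spacing in mm (default 2).
#' @param max_radius_frac radial cutoff as a fraction of the brain radius.
#' @return matrix (n x 3) of candidate locations in mm.
#' @export
source_grid <- function(model, spacing = 2, max_radius_frac = 0.9) {
  rmax <- model$radii[1] * max_radius_frac
  g <- seq(-rmax, rmax, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= rmax^2, , drop = FALSE]
  sweep(pts, 2, model$center, "+")
}

# Solve the moment linearly at one location and return fit quality.
solve_moment <- function(L, v) {
  q <- tryCatch(solve(crossprod(L), crossprod(L, v)),
                error = function(e) MASS_ginv_qr(L, v))
  modeled <- as.numeric(L %*% q)
  list(q = as.numeric(q), modeled = modeled,
       rss = sum((v - modeled)^2))
}

# Minimal least-squares fallback for a rank-deficient lead matrix.
MASS_ginv_qr <- function(L, v) {
  qr.coef(qr(L), v)
}

#' Fit an equivalent current dipole to one topography
#'
#' Coarse scan over a regular volumetric grid (moment solved linearly at
#' every candidate) followed by derivative-free local refinement from the
#' best `n_starts` grid points; locations leaving the brain shell during
#' refinement are projected back (with a warning).
#'
#' @param evoked an `evoked` object (2-25 Hz stream) or a numeric vector
#'   giving one topography directly.
#' @param time_ms time point to fit (ms); nearest sample is used. Ignored
#'   when `evoked` is a vector.
#' @param model a [sphere_head_model()].
#' @param positions electrode positions (channels x 3, mm).
#' @param grid_mm grid spacing for the coarse scan (default 2).
#' @param n_starts number of grid points refined (default 5).
#' @param n_max series truncation order.
#' @param max_radius_frac radial source-space cutoff.
#' @param grid,grid_L optional precomputed [source_grid()] and its lead
#'   field, to amortize the scan across time points.
#' @return a `dipole_fit`: time, location (mm), moment vector and
#'   magnitude (nAm), goodness of fit (%).
#' @export
fit_ecd <- function(evoked, time_ms = NULL, model = sphere_head_model(),
                    positions = canine_layout(model), grid_mm = 2,
                    n_starts = 5, n_max = 60, max_radius_frac = 0.9,
                    grid = NULL, grid_L = NULL) {
  if (inherits(evoked, "evoked")) {
    if (is.null(time_ms)) stopf("time_ms required with an evoked input")
    ti <- which.min(abs(evoked$times - time_ms))
    v <- evoked$data[, ti]
    t_used <- evoked$times[ti]
  } else {
    v <- as.numeric(evoked)
    t_used <- time_ms %||% NA_real_
  }
  v <- v - mean(v)
  if (sqrt(mean(v^2)) < 1e-12) {
    stopf("degenerate (all-zero) topography at %g ms", t_used)
  }
  if (is.null(grid)) grid <- source_grid(model, grid_mm, max_radius_frac)
  if (is.null(grid_L)) grid_L <- lead_vectors(model, grid, positions, n_max)
  n_g <- nrow(grid)
  rss <- numeric(n_g)
  for (i in seq_len(n_g)) {
    rss[i] <- solve_moment(grid_L[, , i], v)$rss
  }
  ord <- order(rss)[seq_len(min(n_starts, n_g))]
  rmax <- model$radii[1] * max_radius_frac
  clamp <- function(loc) {
    d <- loc - model$center
    r <- sqrt(sum(d^2))
    if (r > rmax) model$center + d * (rmax / r) else loc
  }
  objective <- function(loc) {
    d <- loc - model$center
    r <- sqrt(sum(d^2))
    pen <- if (r > rmax) (r - rmax)^2 * 1e4 else 0
    loc_in <- clamp(loc)
    L <- lead_vectors(model, matrix(loc_in, 1), positions, n_max)[, , 1]
    solve_moment(L, v)$rss + pen
  }
  best <- list(value = Inf, par = grid[ord[1], ])
  for (s in ord) {
    o <- stats::optim(grid[s, ], objective, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
    if (o$value < best$value) best <- o
  }
  left_shell <- sqrt(sum((best$par - model$center)^2)) > rmax
  if (left_shell) {
    warnf("refined location left the brain shell; projected back")
  }
  loc <- clamp(best$par)
  L <- lead_vectors(model, matrix(loc, 1), positions, n_max)[, , 1]
  fit <- solve_moment(L, v)
  gof_grid <- 100 * (1 - min(rss) / sum(v^2))
  gof <- dipole_gof(v, fit$modeled)
  structure(
    list(time_ms = t_used, location = unname(loc), moment = fit$q,
         moment_magnitude = sqrt(sum(fit$q^2)), gof = max(gof, gof_grid),
         gof_grid = gof_grid, grid_mm = grid_mm, n_grid = n_g,
         projected = left_shell),
    class = "dipole_fit"
  )
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf(
    "<dipole_fit> t = %s ms: loc (%.1f, %.1f, %.1f) mm, |q| = %.2f nAm, GOF %.2f%%\n",
    format(x$time_ms), x$location[1], x$location[2], x$location[3],
    x$moment_magnitude, x$gof))
  invisible(x)
}

#' Dipole fits at every time point of a window
#'
#' Replicates the per-time-point fitting of the dominant response window
#' (e.g. 90-110 ms): one [fit_ecd()] per sample, with the grid scan
#' computed once.
#'
#' @param evoked an `evoked` object.
#' @param window time window in ms (default `c(90, 110)`).
#' @inheritParams fit_ecd
#' @return data frame with one row per time point: time, location, moment
#'   components, magnitude, goodness of fit.
#' @export
fit_ecd_window <- function(evoked, window = c(90, 110),
                           model = sphere_head_model(),
                           positions = canine_layout(model), grid_mm = 2,
                           n_starts = 5, n_max = 60,
                           max_radius_frac = 0.9) {
  sel <- which(evoked$times >= window[1] & evoked$times <= window[2])
  if (length(sel) == 0) stopf("window contains no samples")
  grid <- source_grid(model, grid_mm, max_radius_frac)
  grid_L <- lead_vectors(model, grid, positions, n_max)
  rows <- lapply(sel, function(ti) {
    f <- fit_ecd(evoked$data[, ti], evoked$times[ti], model, positions,
                 grid_mm, n_starts, n_max, max_radius_frac,
                 grid = grid, grid_L = grid_L)
    data.frame(time_ms = evoked$times[ti],
               x = f$location[1], y = f$location[2], z = f$location[3],
               qx = f$moment[1], qy = f$moment[2], qz = f$moment[3],
               moment = f$moment_magnitude, gof = f$gof)
  })
  do.call(rbind, rows)
}

#' Moment time course at a fixed dipole location
#'
#' Keeps the location of a fitted dipole fixed and solves the moment
#' linearly at every time point of the window, reporting the moment
#' magnitude over the epoch.
#'
#' @param evoked an `evoked` object.
#' @param location fixed dipole location (mm), e.g. from [fit_ecd()].
#' @param model a [sphere_head_model()].
#' @param positions electrode positions (mm).
#' @param window time window in ms (default `c(-50, 300)`).
#' @param n_max series truncation order.
#' @return data frame with time, moment components (nAm), magnitude and
#'   goodness of fit per time point.
#' @export
moment_timecourse <- function(evoked, location,
                              model = sphere_head_model(),
                              positions = canine_layout(model),
                              window = c(-50, 300), n_max = 60) {
  sel <- which(evoked$times >= window[1] & evoked$times <= window[2])
  if (length(sel) == 0) stopf("window contains no samples")
  L <- lead_vectors(model, matrix(location, 1), positions, n_max)[, , 1]
  rows <- lapply(sel, function(ti) {
    v <- evoked$data[, ti]
    v <- v - mean(v)
    if (sqrt(mean(v^2)) < 1e-12) {
      return(data.frame(time_ms = evoked$times[ti], qx = 0, qy = 0,
                        qz = 0, moment = 0, gof = NA_real_))
    }
    fit <- solve_moment(L, v)
    data.frame(time_ms = evoked$times[ti], qx = fit$q[1], qy = fit$q[2],
               qz = fit$q[3], moment = sqrt(sum(fit$q^2)),
               gof = dipole_gof(v, fit$modeled))
  })
  do.call(rbind, rows)
}

# Independent closed-form oracle for the homogeneous sphere (equal
# conductivities): the series summed analytically via Legendre generating
# functions. Exported for validation use.

#' Closed-form homogeneous-sphere dipole potential
#'
#' Analytic surface potential of a dipole in a homogeneous conducting
#' sphere with insulating exterior, from the summed Legendre series; used
#' as an independent cross-check of the shell solution when all three
#' conductivities are equal.
#'
#' @param sigma conductivity (S/m).
#' @param radius sphere radius (mm).
#' @param center sphere center (mm).
#' @param location dipole location (mm).
#' @param moment dipole moment (nAm).
#' @param positions electrode positions on the surface (mm).
#' @param average_ref subtract the electrode mean (default `TRUE`).
#' @return per-electrode potentials in microvolts.
#' @export
homogeneous_sphere_potential <- function(sigma, radius, center = c(0, 0, 0),
                                         location, moment, positions,
                                         average_ref = TRUE) {
  loc <- (location - center) * 1e-3
  pos <- sweep(positions, 2, center, "-") * 1e-3
  q <- moment * 1e-9
  b <- sqrt(sum(loc^2))
  out <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    re <- pos[i, ]
    R <- sqrt(sum(re^2))
    eu <- re / R
    if (b < 1e-12) {
      out[i] <- 3 * sum(q * eu) / (4 * pi * sigma * R^2)
      next
    }
    ur <- loc / b
    u <- sum(ur * eu)
    x <- b / R
    s <- sqrt(1 - 2 * x * u + x^2)        # |re - loc| / R
    m_r <- sum(q * ur)
    t_vec <- eu - u * ur                   # sin(gamma) * unit tangent
    m_t <- sum(q * t_vec)                  # = |q_t| sin(gamma) cos(phi)
    # T_r = sum (2n+1) x^(n-1) P_n(u)
    #     = [2 x (u - x) / s^3 + 1/s - 1] / x
    t_r <- (2 * x * (u - x) / s^3 + 1 / s - 1) / x
    # T_t = sum (2n+1)/n x^(n-1) P_n'(u) = 2/s^3 + D1, where
    # D1 = sum x^(n-1) P_n'(u)/n = (1/x) d/du log(2 / (1 - x u + s))
    #    = (1 + 1/s) / (1 - x u + s)
    d1 <- (1 + 1 / s) / (1 - x * u + s)
    t_t <- 2 / s^3 + d1
    out[i] <- (m_r * t_r + m_t * t_t) / (4 * pi * sigma * R^2)
  }
  out <- out * 1e6
  if (average_ref) out <- out - mean(out) else out
  out
}
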