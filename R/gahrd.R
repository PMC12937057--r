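## Gaussian-accelerated hyperdynamics (GaHRD) bias potentials on analytic
## model surfaces, plus a small Langevin demonstration of transition-rate
## enhancement. Reduced units: the energy unit is that of the model surface,
## k_B = 1, so temperatures are in energy units.

#' Bias parameters for Gaussian-accelerated hyperdynamics
#'
#' The boost potential fills the potential-energy surface below the boost
#' level `E` with a harmonic well `dV = k/2 (E - V)^2` (lower-bound
#' Gaussian-accelerated form), leaving the surface untouched where `V >= E`.
#' Atom-wise spherical confinement of time-varying radius `r_conf(t)`
#' periodically pressurizes the system so reactive encounters stay frequent.
#'
#' @param boost_energy boost level `E`, in the energy units of the surface.
#' @param force_constant harmonic force constant `k` (> 0), inverse energy.
#'   Monotonicity of the biased surface on the filled region requires
#'   `k <= 1/(E - V_min)`; see [validate_bias()].
#' @param k_conf confinement force constant (per mass per length^2, so the
#'   penalty `m k_conf/2 d^2` is an energy); 0 disables confinement.
#' @param sphere_center numeric coordinate vector of the confinement center.
#' @param radius_schedule function `t -> r_conf(t) >= 0`; the default is a
#'   smoothstep-interpolated periodic contraction/expansion between `r_max`
#'   and `r_min` (see [smoothstep_schedule()]).
#' @return a `bias_parameters` list.
#' @export
bias_parameters <- function(boost_energy, force_constant, k_conf = 0,
                            sphere_center = 0,
                            radius_schedule = smoothstep_schedule()) {
  if (!is.finite(boost_energy)) stop("E must be finite", call. = FALSE)
  if (!(is.numeric(force_constant) && force_constant > 0))
    stop("force constant k must be > 0", call. = FALSE)
  if (k_conf < 0) stop("k_conf must be >= 0", call. = FALSE)
  structure(list(boost_energy = boost_energy, force_constant = force_constant,
                 k_conf = k_conf, sphere_center = sphere_center,
                 radius_schedule = radius_schedule),
            class = "bias_parameters")
}

#' Periodic smoothstep radius schedule
#'
#' Interpolates the confinement radius between `r_max` and `r_min` with the
#' C^1 smoothstep `3u^2 - 2u^3`, contracting over the first half of each
#' period and expanding over the second -- a frequent, gentle pressure piston.
#'
#' @param r_max,r_min radii at full expansion/contraction.
#' @param period duration of one contract-expand cycle (time units of the
#'   integrator).
#' @return function `t -> r_conf(t)`.
#' @export
smoothstep_schedule <- function(r_max = 2, r_min = 0.5, period = 10) {
  force(r_max); force(r_min); force(period)
  function(t) {
    ph <- (t %% period) / period
    u <- ifelse(ph < 0.5, ph * 2, 2 - ph * 2)   # 0 -> 1 -> 0 over a period
    s <- 3 * u^2 - 2 * u^3
    r_max + (r_min - r_max) * s
  }
}

#' Analytic model surface
#'
#' @param dimension number of coordinates.
#' @param energy function: numeric coordinate vector -> scalar energy.
#' @param gradient function: coordinate vector -> gradient vector.
#' @return a `model_surface` list.
#' @export
model_surface <- function(dimension, energy, gradient) {
  structure(list(dimension = as.integer(dimension), energy = energy,
                 gradient = gradient), class = "model_surface")
}

#' Symmetric double-well surfaces
#'
#' `double_well_1d()` is `V(x) = h ((x/a)^2 - 1)^2` with minima at `+/- a`
#' and barrier height `h` at the origin. `double_well_2d()` adds a harmonic
#' transverse coordinate: `V(x, y) = h ((x/a)^2 - 1)^2 + ky/2 y^2`.
#'
#' @param h barrier height; `a` half-distance between minima; `ky` transverse
#'   force constant.
#' @return a [model_surface()].
#' @export
double_well_1d <- function(h = 1, a = 1) {
  model_surface(1L,
    energy = function(x) h * ((x[1] / a)^2 - 1)^2,
    gradient = function(x) 4 * h * x[1] * ((x[1] / a)^2 - 1) / a^2)
}

#' @rdname double_well_1d
#' @export
double_well_2d <- function(h = 1, a = 1, ky = 2) {
  model_surface(2L,
    energy = function(x) h * ((x[1] / a)^2 - 1)^2 + ky / 2 * x[2]^2,
    gradient = function(x) c(4 * h * x[1] * ((x[1] / a)^2 - 1) / a^2,
                             ky * x[2]))
}

#' Boost potential at an energy value
#'
#' `dV = k/2 (E - V)^2` where the surface lies below the boost level `E`, and
#' exactly 0 where `V >= E`; the join at `V = E` is C^1 (value and slope both
#' vanish). Always non-negative.
#'
#' @param v potential energy value(s).
#' @param p a [bias_parameters()].
#' @return boost energy value(s), same length as `v`.
#' @export
boost_delta_v <- function(v, p) {
  E <- p$boost_energy
  ifelse(v < E, 0.5 * p$force_constant * (E - v)^2, 0)
}

#' Biased potential value
#'
#' `V* = V + dV`: the original surface above the boost level, the filled
#' surface below it. With `k <= 1/(E - V_min)`, `V*` is monotone
#' non-decreasing in `V` on `[V_min, E]`, preserving the ordering of the
#' surface topology.
#'
#' @inheritParams boost_delta_v
#' @return biased energy value(s).
#' @export
biased_potential <- function(v, p) v + boost_delta_v(v, p)

#' Check the Gaussian-accelerated-dynamics parameter bounds
#'
#' Warns unless `E >= V_max` of the sampled region (lower-bound form boosts
#' everywhere visited) and `k <= 1/(E - V_min)` (monotonicity of `V*`).
#'
#' @param p a [bias_parameters()].
#' @param v_min,v_max minimum and maximum surface energy over the region of
#'   interest.
#' @return `TRUE` (invisibly) if both bounds hold, else `FALSE` with warnings.
#' @export
validate_bias <- function(p, v_min, v_max) {
  ok <- TRUE
  if (p$boost_energy < v_max) {
    warning("boost energy E below V_max of the sampled region; ",
            "the surface is only partially boosted", call. = FALSE)
    ok <- FALSE
  }
  if (p$boost_energy > v_min && p$force_constant > 1 / (p$boost_energy - v_min)) {
    warning("k > 1/(E - V_min): biased potential is non-monotone on the ",
            "filled region", call. = FALSE)
    ok <- FALSE
  }
  invisible(ok)
}

#' Spherical confinement energy of one atom
#'
#' Mass-weighted harmonic penalty on the excursion beyond the confinement
#' sphere: `m k_conf / 2 * max(0, |x - center| - r_conf(t))^2`, exactly zero
#' inside the sphere. (The spherical-confinement formula is stated without
#' positional dependence in compact notation; the excursion-penalty reading
#' implemented here is the standard harmonic-wall interpretation and is the
#' one documented throughout this package.)
#'
#' @param position coordinate vector of the atom.
#' @param mass atomic mass (amu); must be > 0.
#' @param t time at which to evaluate the radius schedule.
#' @param p a [bias_parameters()].
#' @return confinement energy (scalar).
#' @export
confinement_energy <- function(position, mass, t, p) {
  if (mass <= 0) stop("domain error: mass must be positive", call. = FALSE)
  r <- p$radius_schedule(t)
  if (r < 0) stop("radius schedule returned r < 0", call. = FALSE)
  d <- sqrt(sum((position - p$sphere_center)^2))
  exc <- max(0, d - r)
  mass * p$k_conf / 2 * exc^2
}

#' Total biased energy of a configuration
#'
#' `V_total = V*(x) + sum_n V_n^sphere`: the boosted surface energy of the
#' full coordinate vector plus the per-atom spherical confinement penalties.
#'
#' @param positions matrix (atoms x dimension) or vector (single atom) of
#'   coordinates; flattened row-wise to the surface's coordinate vector.
#' @param masses numeric vector, one mass per atom.
#' @param surface a [model_surface()].
#' @param t time (for the radius schedule).
#' @param p a [bias_parameters()].
#' @return total energy (scalar).
#' @export
total_bias <- function(positions, masses, surface, t, p) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  if (nrow(positions) != length(masses))
    stop("input error: positions/masses length mismatch", call. = FALSE)
  x <- as.vector(t(positions))
  if (length(x) != surface$dimension * nrow(positions))
    stop("input error: coordinate dimension mismatch", call. = FALSE)
  vconf <- sum(vapply(seq_len(nrow(positions)), function(i)
    confinement_energy(positions[i, ], masses[i], t, p), numeric(1)))
  biased_potential(surface$energy(x), p) + vconf
}

#' Gradient of the total biased energy
#'
#' Analytic chain rule: `dV*/dx = (1 - k (E - V)) dV/dx` below the boost
#' level, `dV/dx` above it, plus the confinement wall force per atom.
#'
#' @inheritParams total_bias
#' @return gradient matrix of the same shape as `positions` (or vector).
#' @export
total_bias_gradient <- function(positions, masses, surface, t, p) {
  vec_in <- is.null(dim(positions))
  if (vec_in) positions <- matrix(positions, nrow = 1)
  x <- as.vector(t(positions))
  v <- surface$energy(x)
  gs <- surface$gradient(x)
  fac <- if (v < p$boost_energy)
    1 - p$force_constant * (p$boost_energy - v) else 1
  g <- matrix(fac * gs, nrow = nrow(positions), byrow = TRUE)
  r <- p$radius_schedule(t)
  for (i in seq_len(nrow(positions))) {
    dx <- positions[i, ] - p$sphere_center
    d <- sqrt(sum(dx^2))
    if (d > r && d > 0)
      g[i, ] <- g[i, ] + masses[i] * p$k_conf * (d - r) * dx / d
  }
  if (vec_in) as.vector(g) else g
}

#' Langevin dynamics demonstration of boost-accelerated transitions
#'
#' Integrates one particle on a 1-D or 2-D model surface with the BAOAB
#' splitting of Langevin dynamics (reduced units, k_B = 1), with or without
#' the bias, and counts well-to-well transitions. Wells are assigned by
#' `well_of`; by default the sign of the first coordinate with a hysteresis
#' band of half the well half-width, so barrier-top recrossings are not
#' counted as transitions. Fully reproducible for a given seed.
#'
#' @param surface a 1-D or 2-D [model_surface()].
#' @param p a [bias_parameters()]; ignored when `use_bias = FALSE`.
#' @param temperature thermostat temperature (energy units, k_B = 1); > 0.
#' @param friction Langevin friction (inverse time); > 0.
#' @param steps number of integration steps.
#' @param dt time step.
#' @param mass particle mass.
#' @param x0 initial coordinates (default: the `x = -1` well).
#' @param seed RNG seed for the thermostat noise.
#' @param use_bias logical: apply the boost + confinement bias.
#' @param hysteresis half-width of the no-man's band around the barrier.
#' @return list with `trajectory` (data.frame: step, time, coordinates,
#'   potential, boost, kinetic temperature estimate), `transitions` (count),
#'   `mean_temperature`.
#' @export
demo_langevin <- function(surface, p, temperature = 0.3, friction = 1,
                          steps = 5000L, dt = 0.01, mass = 1,
                          x0 = NULL, seed = 1L, use_bias = TRUE,
                          hysteresis = 0.5) {
  if (temperature <= 0 || friction <= 0)
    stop("domain error: temperature and friction must be positive",
         call. = FALSE)
  dim <- surface$dimension
  if (!dim %in% c(1L, 2L))
    stop("demo supports 1-D or 2-D surfaces", call. = FALSE)
  if (is.null(x0)) x0 <- c(-1, rep(0, dim - 1L))
  set.seed(seed)

  grad <- function(x, t) {
    if (use_bias) total_bias_gradient(x, mass, surface, t, p)
    else surface$gradient(x)
  }
  pot <- function(x, t) {
    if (use_bias) total_bias(x, mass, surface, t, p) else surface$energy(x)
  }

  c1 <- exp(-friction * dt)
  c2 <- sqrt(temperature / mass * (1 - c1^2))
  x <- x0
  vlc <- rnorm(dim, 0, sqrt(temperature / mass))
  rec_x <- matrix(NA_real_, steps, dim)
  rec_v <- rec_b <- rec_T <- numeric(steps)
  well <- if (x[1] <= -hysteresis) -1L else if (x[1] >= hysteresis) 1L else 0L
  transitions <- 0L

  for (s in seq_len(steps)) {
    tm <- (s - 1) * dt
    f <- -grad(x, tm)
    vlc <- vlc + dt / 2 * f / mass                    # B
    x <- x + dt / 2 * vlc                             # A
    vlc <- c1 * vlc + c2 * rnorm(dim)                 # O
    x <- x + dt / 2 * vlc                             # A
    f <- -grad(x, tm + dt)
    vlc <- vlc + dt / 2 * f / mass                    # B
    v0 <- surface$energy(x)
    rec_x[s, ] <- x
    rec_v[s] <- v0
    rec_b[s] <- if (use_bias) boost_delta_v(v0, p) else 0
    rec_T[s] <- mass * sum(vlc^2) / dim               # <m v^2> / dof, k_B = 1
    w <- if (x[1] <= -hysteresis) -1L else if (x[1] >= hysteresis) 1L else 0L
    if (w != 0L && well != 0L && w != well) transitions <- transitions + 1L
    if (w != 0L) well <- w
  }

  traj <- data.frame(step = seq_len(steps), time = seq_len(steps) * dt)
  for (j in seq_len(dim)) traj[[paste0("x", j)]] <- rec_x[, j]
  traj$potential <- rec_v
  traj$boost <- rec_b
  traj$temperature_estimate <- rec_T
  list(trajectory = traj, transitions = transitions,
       mean_temperature = mean(rec_T))
}

#' Write a Langevin trajectory to CSV
#' @param demo result of [demo_langevin()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(demo, path) {
  write.csv(demo$trajectory, path, row.names = FALSE)
  invisible(path)
}
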