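# Transport and reorientation dynamics: mean-square displacement with
# beta-exponent regime detection and Einstein self-diffusion, velocity
# autocorrelation with collision/randomization times, bond-vector
# reorientation, and Green-Kubo shear viscosity.

#' Unwrap periodic coordinates by accumulated minimum-image displacements
#'
#' Valid when no particle moves more than half a box edge between frames
#' (asserted); under that condition the frame-to-frame minimum-image
#' displacement is the true displacement.
#'
#' @param traj An `md_trajectory` (wrapped coordinates).
#' @return Array `[n_frames, n_atoms, 3]` of unwrapped coordinates.
#' @export
unwrap_coordinates <- function(traj) {
  box <- as.numeric(traj$box)
  nf <- n_frames(traj)
  out <- traj$coords
  if (nf < 2) return(out)
  for (k in 2:nf) {
    step <- matrix(traj$coords[k, , ] - traj$coords[k - 1, , ], ncol = 3)
    step <- wrap_displacement(step, box)
    out[k, , ] <- out[k - 1, , ] + step
  }
  out
}

# Per-molecule mass-weighted centers (positions or velocities) for one
# coordinate array; returns [n_frames, n_molecules, 3].
.com_array <- function(arr, top) {
  mols <- unique(top$molecule_id)
  nf <- dim(arr)[1]
  out <- array(0, c(nf, length(mols), 3))
  for (m in seq_along(mols)) {
    idx <- which(top$molecule_id == mols[m])
    w <- top$mass[idx] / sum(top$mass[idx])
    for (k in 1:3) {
      sub <- matrix(arr[, idx, k], nrow = nf)
      out[, m, k] <- as.numeric(sub %*% w)
    }
  }
  out
}

#' Mean-square displacement
#'
#' Multiple-time-origin average of the squared displacement
#' `<|r(t + tau) - r(t)|^2>` over all origins and group members, computed
#' on unwrapped coordinates. With `com_by_molecule = TRUE` the motion of
#' per-molecule mass-weighted centers is analyzed instead of atoms.
#'
#' @param traj An `md_trajectory` (>= 2 frames).
#' @param group Atom selection (default all atoms).
#' @param com_by_molecule Track molecular centers of mass.
#' @param max_lag_fraction Largest lag as a fraction of the trajectory
#'   length (default 0.5; long lags average few origins).
#' @param topology Optional topology override (needed for COM grouping).
#' @return Object of class `msd_result`: lags `tau` (ps, starting at 0),
#'   `msd` (Angstrom^2, `msd[1] = 0`), `dt`, `n_series`.
#' @export
msd <- function(traj, group = NULL, com_by_molecule = FALSE,
                max_lag_fraction = 0.5, topology = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop("MSD needs at least two frames")
  un <- unwrap_coordinates(traj)
  if (!is.null(group)) {
    top <- .traj_topology(traj, topology)
    idx <- .resolve_group(group, top)
    un <- un[, idx, , drop = FALSE]
    if (com_by_molecule) {
      un <- .com_array(un, top[idx, , drop = FALSE])
    }
  } else if (com_by_molecule) {
    top <- .traj_topology(traj, topology)
    un <- .com_array(un, top)
  }
  n_series <- dim(un)[2]
  max_lag <- max(1, floor((nf - 1) * max_lag_fraction))
  flat <- matrix(un, nrow = nf)  # frames x (series*3), column-major
  msd_vals <- numeric(max_lag + 1)
  for (lag in seq_len(max_lag)) {
    d <- flat[(1 + lag):nf, , drop = FALSE] - flat[1:(nf - lag), , drop = FALSE]
    msd_vals[lag + 1] <- sum(d * d) / ((nf - lag) * n_series)
  }
  structure(list(tau = (0:max_lag) * traj$dt, msd = msd_vals,
                 dt = traj$dt, n_series = n_series),
            class = "msd_result")
}

#' Build an MSD result from a tabulated curve
#'
#' Wraps externally computed (or analytic) MSD values so the regime
#' detection and diffusion estimators can be applied to them.
#'
#' @param tau Lag times (ps), starting at 0.
#' @param msd MSD values (Angstrom^2).
#' @return `msd_result`.
#' @export
msd_from_table <- function(tau, msd) {
  structure(list(tau = tau, msd = msd,
                 dt = if (length(tau) > 1) diff(tau)[1] else NA_real_,
                 n_series = NA_integer_),
            class = "msd_result")
}

#' Local log-log slope (beta exponent) of the MSD
#'
#' `beta(tau) = d log10 MSD / d log10 tau` by centered finite differences,
#' smoothed with a moving average: beta = 2 marks ballistic motion, beta =
#' 1 the diffusive (Einstein) regime.
#'
#' @param msd_result An `msd_result`.
#' @param smooth_window Moving-average window (points, odd; 1 disables).
#' @return data.frame with `tau` and `beta` (`NA` where MSD or the
#'   difference is undefined; zero-MSD points are skipped).
#' @export
beta_exponent <- function(msd_result, smooth_window = 5) {
  tau <- msd_result$tau
  m <- msd_result$msd
  ok <- tau > 0 & m > 0
  lt <- log10(tau[ok])
  lm <- log10(m[ok])
  n <- length(lt)
  if (n < 3) return(data.frame(tau = tau[ok], beta = rep(NA_real_, n)))
  beta <- rep(NA_real_, n)
  beta[2:(n - 1)] <- (lm[3:n] - lm[1:(n - 2)]) / (lt[3:n] - lt[1:(n - 2)])
  beta[1] <- (lm[2] - lm[1]) / (lt[2] - lt[1])
  beta[n] <- (lm[n] - lm[n - 1]) / (lt[n] - lt[n - 1])
  if (smooth_window > 1) {
    w <- rep(1 / smooth_window, smooth_window)
    sm <- as.numeric(stats::filter(beta, w, sides = 2))
    beta[!is.na(sm)] <- sm[!is.na(sm)]
  }
  data.frame(tau = tau[ok], beta = beta)
}

#' Einstein self-diffusion coefficient from the diffusive regime
#'
#' Locates the longest contiguous run of lags with `|beta - 1| <=
#' beta_tol` (at least `min_points` points required) and fits the MSD
#' there by least squares; `D = slope / 6`, reported in Angstrom^2/ns.
#'
#' @param msd_result An `msd_result`.
#' @param beta_tol Tolerance around beta = 1 (default 0.1).
#' @param min_points Minimum diffusive-window length (default 10).
#' @param smooth_window Passed to [beta_exponent()].
#' @return List of class `self_diffusion`: `found`, `D` (Angstrom^2/ns,
#'   `NA` when no diffusive window exists), `window` (lag range, ps),
#'   `n_points`.
#' @export
self_diffusion <- function(msd_result, beta_tol = 0.1, min_points = 10,
                           smooth_window = 5) {
  nodiff <- structure(list(found = FALSE, D = NA_real_,
                           window = c(NA_real_, NA_real_), n_points = 0L),
                      class = "self_diffusion")
  be <- beta_exponent(msd_result, smooth_window)
  if (!nrow(be)) return(nodiff)
  good <- !is.na(be$beta) & abs(be$beta - 1) <= beta_tol
  if (!any(good)) return(nodiff)
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= min_points)
  if (!length(runs)) return(nodiff)
  best <- runs[which.max(r$lengths[runs])]
  taus <- be$tau[starts[best]:ends[best]]
  sel <- msd_result$tau %in% taus
  fit <- stats::lm(msd_result$msd[sel] ~ msd_result$tau[sel])
  slope <- unname(stats::coef(fit)[2])       # A^2 / ps
  structure(list(found = TRUE, D = slope / 6 * 1000,  # A^2 / ns
                 window = range(taus), n_points = sum(sel)),
            class = "self_diffusion")
}

# Direct multiple-origin autocorrelation of a columns-as-components
# series: acf_k = mean over origins of sum_j x_j(t) x_j(t + k).
.multi_origin_acf <- function(x, max_lag) {
  x <- as.matrix(x)
  n <- nrow(x)
  vapply(0:max_lag, function(l) {
    sum(x[1:(n - l), , drop = FALSE] * x[(1 + l):n, , drop = FALSE]) / (n - l)
  }, 0)
}

# First n zero crossings of a series by sign change + linear interpolation.
.zero_crossings <- function(t, y, n = 2) {
  out <- rep(NA_real_, n)
  found <- 0
  for (i in seq_len(length(y) - 1)) {
    if (found == n) break
    if (y[i] != 0 && sign(y[i]) != sign(y[i + 1])) {
      tc <- if (y[i + 1] == 0) t[i + 1]
            else t[i] + (t[i + 1] - t[i]) * y[i] / (y[i] - y[i + 1])
      found <- found + 1
      out[found] <- tc
    }
  }
  out
}

#' Normalized velocity autocorrelation function
#'
#' `C_v(t) = <V(t) . V(0)> / <V(0) . V(0)>` with the average taken over all
#' time origins (and molecules for trajectory input, where center-of-mass
#' velocities are used). The first zero crossing is reported as the mean
#' collision time, the second as the velocity randomization time.
#'
#' @param x A `velocity_series` (see [gen_ou_velocity()]), a numeric matrix
#'   of per-frame velocity components, or an `md_trajectory` with
#'   velocities.
#' @param group Atom selection (trajectory input).
#' @param com_by_molecule Use molecular center-of-mass velocities
#'   (trajectory input; default TRUE).
#' @param max_lag_fraction Largest lag as a fraction of series length.
#' @param dt Timestep (ps) for matrix input.
#' @param topology Optional topology override.
#' @return Object of class `vacf_result`: lags `t` (ps), normalized `cv`
#'   (`cv[1] = 1`), `t1` (mean collision time), `t2` (randomization time);
#'   crossings are `NA` when absent.
#' @export
vacf <- function(x, group = NULL, com_by_molecule = TRUE,
                 max_lag_fraction = 0.5, dt = NULL, topology = NULL) {
  if (inherits(x, "md_trajectory")) {
    if (is.null(x$velocities)) stop("trajectory carries no velocities")
    vel <- x$velocities
    if (!is.null(group)) {
      top <- .traj_topology(x, topology)
      idx <- .resolve_group(group, top)
      vel <- vel[, idx, , drop = FALSE]
      if (com_by_molecule) vel <- .com_array(vel, top[idx, , drop = FALSE])
    } else if (com_by_molecule && !is.null(x$topology)) {
      vel <- .com_array(vel, x$topology)
    }
    series <- matrix(vel, nrow = dim(vel)[1])
    dt <- x$dt
  } else if (inherits(x, "velocity_series")) {
    series <- x$v
    dt <- x$dt
  } else {
    series <- as.matrix(x)
    if (is.null(dt)) stop("dt must be given for matrix input")
  }
  n <- nrow(series)
  max_lag <- max(1, floor((n - 1) * max_lag_fraction))
  raw <- .multi_origin_acf(series, max_lag)
  cv <- raw / raw[1]
  t <- (0:max_lag) * dt
  zc <- .zero_crossings(t, cv, 2)
  structure(list(t = t, cv = cv, t1 = zc[1], t2 = zc[2], dt = dt),
            class = "vacf_result")
}

#' Bond-vector reorientation dynamics
#'
#' Autocorrelation of molecular bond unit vectors: unit vectors at lag tau
#' are dotted with their time-origin values, averaged over molecules and
#' all origins, and normalized so `VRD(0) = 1`. For trajectory input the
#' vector runs between two sites (e.g. the hydroxyl O1-HA of a fatty acid)
#' within each molecule of the reference type.
#'
#' @param x A `vector_series` (see [gen_rigid_rotor()]), an array
#'   `[n_frames, n_vectors, 3]`, or an `md_trajectory`.
#' @param ref_type Molecule type carrying the bond (trajectory input).
#' @param sites Length-2 site labels `(from, to)` (trajectory input).
#' @param max_lag_fraction Largest lag as a fraction of series length.
#' @param dt Timestep (ps) for array input.
#' @param normalize_vectors Normalize each vector to unit length (skipping
#'   zero-length instances, counted in `skipped`).
#' @param topology Optional topology override.
#' @return Object of class `vrd_result`: lags `tau` (ps), `vrd`
#'   (`vrd[1] = 1`), `skipped`.
#' @export
vrd <- function(x, ref_type = NULL, sites = NULL, max_lag_fraction = 0.5,
                dt = NULL, normalize_vectors = TRUE, topology = NULL) {
  skipped <- 0L
  if (inherits(x, "md_trajectory")) {
    top <- .traj_topology(x, topology)
    if (is.null(ref_type) || is.null(sites)) {
      stop("ref_type and sites are required for trajectory input")
    }
    i_from <- .ref_site_atoms(top, ref_type, sites[1])
    i_to <- .ref_site_atoms(top, ref_type, sites[2])
    nf <- n_frames(x)
    vec <- array(0, c(nf, length(i_from), 3))
    box <- as.numeric(x$box)
    for (k in seq_len(nf)) {
      d <- wrap_displacement(
        matrix(x$coords[k, i_to, ], ncol = 3) -
          matrix(x$coords[k, i_from, ], ncol = 3), box)
      vec[k, , ] <- d
    }
    dt <- x$dt
  } else if (inherits(x, "vector_series")) {
    vec <- x$vectors
    dt <- x$dt
  } else {
    vec <- x
    if (length(dim(vec)) != 3) stop("vector input must be [frames, vectors, 3]")
    if (is.null(dt)) stop("dt must be given for array input")
  }
  nf <- dim(vec)[1]
  nv <- dim(vec)[2]
  if (normalize_vectors) {
    nrm <- sqrt(vec[, , 1]^2 + vec[, , 2]^2 + vec[, , 3]^2)
    nrm <- matrix(nrm, nf, nv)
    zero <- nrm < 1e-12
    skipped <- sum(zero)
    nrm[zero] <- 1
    for (k in 1:3) vec[, , k] <- matrix(vec[, , k], nf, nv) / nrm
    if (any(zero)) for (k in 1:3) vec[, , k][zero] <- 0
  }
  flat <- matrix(vec, nrow = nf)
  max_lag <- max(1, floor((nf - 1) * max_lag_fraction))
  raw <- .multi_origin_acf(flat, max_lag)
  structure(list(tau = (0:max_lag) * dt, vrd = raw / raw[1],
                 skipped = skipped),
            class = "vrd_result")
}

#' Green-Kubo shear viscosity from an off-diagonal stress series
#'
#' `eta = V / (k_B T) * integral <P_ab(0) P_ab(t)> dt`, with the stress
#' autocorrelation estimated over all time origins for each of the three
#' off-diagonal components (xy, xz, yz), averaged, and integrated by
#' trapezoid. The plateau is the mean of the running integral over the
#' window where the averaged autocorrelation has decayed below 2% of its
#' initial value; when it never decays that far, a "no plateau" warning is
#' issued and the running integral is still returned.
#'
#' @param stress A `stress_series` (see [gen_stress_series()]) or a matrix
#'   / data.frame with columns xy, xz, yz.
#' @param volume System volume V (Angstrom^3).
#' @param temperature Temperature T (K).
#' @param dt Timestep (ps) for matrix input.
#' @param max_lag Largest correlation lag in steps (default n/5).
#' @param stress_unit Unit of the stress values: `"kcal_molA3"`
#'   (kcal mol^-1 A^-3, the MD energy-density convention), `"atm"`,
#'   `"bar"`, or `"Pa"`.
#' @return Object of class `viscosity_result`: lags `t` (ps), averaged
#'   `acf`, running integral `eta_t` (mPa s, `eta_t[1] = 0`), plateau
#'   `eta` (mPa s, `NA` without plateau), `volume`, `temperature`.
#' @export
gk_viscosity <- function(stress, volume, temperature, dt = NULL,
                         max_lag = NULL, stress_unit = "kcal_molA3") {
  if (volume <= 0 || temperature <= 0) stop("volume and temperature must be positive")
  if (inherits(stress, "stress_series")) {
    P <- stress$P
    dt <- stress$dt
  } else {
    P <- as.matrix(stress)
    if (is.null(dt)) stop("dt must be given for matrix input")
  }
  if (ncol(P) != 3) stop("stress series must have three components (xy, xz, yz)")
  conv <- .PRESS_TO_PA[stress_unit]
  if (is.na(conv)) stop("unknown stress unit: ", stress_unit)
  n <- nrow(P)
  if (is.null(max_lag)) max_lag <- max(2, floor(n / 5))
  max_lag <- min(max_lag, n - 1)
  acfs <- sapply(1:3, function(j) .multi_origin_acf(P[, j, drop = FALSE], max_lag))
  acf_mean <- rowMeans(acfs)
  t <- (0:max_lag) * dt
  # running trapezoid integral of the ACF
  integ <- c(0, cumsum((acf_mean[-1] + acf_mean[-length(acf_mean)]) / 2 * diff(t)))
  # V/(kB T) * integral, converted: stress^2 -> Pa^2, ps -> s, A^3 -> m^3,
  # kB T in J; result in mPa s
  kbt_joule <- .KB_KCAL_MOL * temperature * 4184 / 6.02214076e23
  eta_t <- (volume * 1e-30) / kbt_joule * integ * conv^2 * 1e-12 * 1e3
  dec <- which(abs(acf_mean) < 0.02 * abs(acf_mean[1]))
  if (length(dec)) {
    eta <- mean(eta_t[dec[1]:length(eta_t)])
  } else {
    warning("stress ACF has not decayed below 2% of its initial value: no plateau")
    eta <- NA_real_
  }
  structure(list(t = t, acf = acf_mean, eta_t = eta_t, eta = eta,
                 volume = volume, temperature = temperature,
                 stress_unit = stress_unit),
            class = "viscosity_result")
}
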