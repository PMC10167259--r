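# Synthetic configurations, trajectories and stationary series with known
# ground truth. These stand in for force-field MD so that every analysis
# stage can be verified against planted parameters at desk scale.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state
#'
#' All generators route their randomness through this helper so that a fixed
#' seed gives bit-reproducible output without disturbing the caller's RNG
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Ideal-gas (uncorrelated) trajectory
#'
#' Positions are i.i.d. uniform in the box in every frame: the null model
#' for which the radial distribution function is exactly 1 in expectation.
#'
#' @param n_atoms Number of atoms (>= 2).
#' @param box Box edge lengths (Angstrom) or [simulation_box()].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param dt Timestep in ps.
#' @return `md_trajectory` whose metadata records the number density
#'   `rho = n/V` (A^-3).
#' @export
gen_ideal_gas <- function(n_atoms, box, n_frames = 1, seed = 1, dt = 1) {
  if (n_atoms < 2) stop("n_atoms must be >= 2")
  box <- .as_box(box)
  vol <- .box_volume(box)
  if (vol <= 0) stop("box volume must be positive")
  coords <- with_seed(seed, {
    a <- array(stats::runif(n_frames * n_atoms * 3), c(n_frames, n_atoms, 3))
    for (k in 1:3) a[, , k] <- a[, , k] * box[k]
    a
  })
  top <- topology(site_label = rep("X", n_atoms),
                  element = rep("X", n_atoms),
                  molecule_id = seq_len(n_atoms))
  md_trajectory(coords, box = box, dt = dt, topology = top,
                metadata = list(kind = "ideal_gas", seed = seed,
                                density = n_atoms / vol))
}

# Random unit vector(s), n x 3.
.rand_unit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v * v))
}

# A unit vector perpendicular to each row of u (random azimuth).
.rand_perp <- function(u) {
  w <- .rand_unit(nrow(u))
  p <- w - u * rowSums(w * u)
  n <- sqrt(rowSums(p * p))
  bad <- n < 1e-8
  while (any(bad)) {
    w2 <- .rand_unit(sum(bad))
    p[bad, ] <- w2 - u[bad, , drop = FALSE] * rowSums(w2 * u[bad, , drop = FALSE])
    n <- sqrt(rowSums(p * p))
    bad <- n < 1e-8
  }
  p / n
}

#' Planted donor-H-acceptor geometries
#'
#' Places `count` D-H...A triples at a prescribed H...A distance and
#' D-H...A angle (at the hydrogen), each triple isolated on its own grid
#' cell with a random orientation, plus optional decoy triples far outside
#' any hydrogen-bond criterion. Ground truth for geometric hydrogen-bond
#' detection.
#'
#' @param count Number of planted triples.
#' @param distance H...A distance (Angstrom, > 0).
#' @param angle D-H...A angle in degrees, in (0, 180).
#' @param box Box edge lengths; must be large enough to hold
#'   `count + n_decoys` non-interacting triples (error otherwise).
#' @param jitter Gaussian sigma (Angstrom) added to the H...A distance.
#' @param n_decoys Decoy triples planted at 5.5 Angstrom / 60 degrees.
#' @param seed Integer seed.
#' @param donor_label,h_label,acceptor_label Site labels written into the
#'   topology (defaults OA, HA, Cl: a fatty-acid hydroxyl donating to
#'   chloride).
#' @param dh_bond Covalent D-H bond length (Angstrom).
#' @return List with `frame` (`md_frame`), `topology`, and `truth`
#'   (the planted parameters).
#' @export
gen_planted_geometry <- function(count, distance = 2.0, angle = 160, box = 100,
                                 jitter = 0, n_decoys = 0, seed = 1,
                                 donor_label = "OA", h_label = "HA",
                                 acceptor_label = "Cl", dh_bond = 0.97) {
  if (distance <= 0) stop("distance must be positive")
  if (angle <= 0 || angle >= 180) stop("angle must lie in (0, 180)")
  box <- .as_box(box)
  n_tot <- count + n_decoys
  cell <- 8  # one triple per 8 A cell keeps triples out of each other's cutoffs
  ncell <- floor(as.numeric(box) / cell)
  if (prod(ncell) < n_tot) {
    stop("box too small to place ", n_tot, " isolated triples")
  }
  with_seed(seed, {
    slots <- sample(prod(ncell), n_tot)
    ix <- (slots - 1) %% ncell[1]
    iy <- ((slots - 1) %/% ncell[1]) %% ncell[2]
    iz <- (slots - 1) %/% (ncell[1] * ncell[2])
    centers <- cbind(ix, iy, iz) * cell + cell / 2
    u <- .rand_unit(n_tot)       # H -> A direction
    v <- .rand_perp(u)           # in-plane perpendicular
    d <- rep(c(distance, 5.5), c(count, n_decoys))
    if (jitter > 0 && count > 0) {
      d[seq_len(count)] <- d[seq_len(count)] + stats::rnorm(count, 0, jitter)
    }
    ang <- rep(c(angle, 60), c(count, n_decoys)) * pi / 180
    hpos <- centers
    apos <- hpos + u * d
    w <- u * cos(ang) + v * sin(ang)  # H -> D direction at the planted angle
    dpos <- hpos + w * dh_bond
    pos <- matrix(0, 3 * n_tot, 3)
    pos[seq(1, 3 * n_tot, 3), ] <- dpos
    pos[seq(2, 3 * n_tot, 3), ] <- hpos
    pos[seq(3, 3 * n_tot, 3), ] <- apos
    top <- topology(
      site_label = rep(c(donor_label, h_label, acceptor_label), n_tot),
      element = rep(c("O", "H", "Cl"), n_tot),
      molecule_id = as.vector(rbind(2 * seq_len(n_tot) - 1,
                                    2 * seq_len(n_tot) - 1,
                                    2 * seq_len(n_tot))),
      molecule_type = rep(c("OTHER", "OTHER", "CL"), n_tot)
    )
    list(frame = md_frame(pos, box = box),
         topology = top,
         truth = list(count = count, distance = distance, angle = angle,
                      jitter = jitter, n_decoys = n_decoys, seed = seed))
  })
}

#' Brownian (or frozen) particle trajectory
#'
#' Unwrapped per-axis increments are Gaussian with variance `2 D dt`; the
#' trajectory stores wrapped coordinates and keeps the unwrapped ground
#' truth in metadata, so displacement unwrapping is itself testable.
#'
#' @param n_particles Number of independent particles.
#' @param D Diffusion coefficient in Angstrom^2/ns (>= 0).
#' @param dt Timestep in ps.
#' @param n_frames Number of frames.
#' @param box Box edge lengths.
#' @param seed Integer seed.
#' @return `md_trajectory` (wrapped coordinates); metadata holds `D`,
#'   and `unwrapped` (the true coordinate array).
#' @export
gen_brownian <- function(n_particles, D, dt, n_frames, box, seed = 1) {
  if (D < 0) stop("D must be >= 0")
  box <- .as_box(box)
  sig <- sqrt(2 * D * dt / 1000)  # D is per ns, dt in ps
  unwrapped <- with_seed(seed, {
    start <- matrix(stats::runif(n_particles * 3), n_particles, 3) %*% diag(as.numeric(box))
    a <- array(0, c(n_frames, n_particles, 3))
    a[1, , ] <- start
    if (n_frames > 1 && sig > 0) {
      steps <- array(stats::rnorm((n_frames - 1) * n_particles * 3, 0, sig),
                     c(n_frames - 1, n_particles, 3))
      for (k in 2:n_frames) a[k, , ] <- a[k - 1, , ] + steps[k - 1, , ]
    } else if (n_frames > 1) {
      for (k in 2:n_frames) a[k, , ] <- a[1, , ]
    }
    a
  })
  wrapped <- unwrapped
  for (k in 1:3) {
    wrapped[, , k] <- wrapped[, , k] %% as.numeric(box)[k]
  }
  top <- topology(site_label = rep("X", n_particles),
                  element = rep("X", n_particles),
                  molecule_id = seq_len(n_particles))
  md_trajectory(wrapped, box = box, dt = dt, topology = top,
                metadata = list(kind = "brownian", D = D, seed = seed,
                                unwrapped = unwrapped))
}

#' Ballistic (constant-velocity) trajectory
#'
#' Every particle moves with a constant random velocity of speed `v`; the
#' mean-square displacement is exactly `v^2 tau^2` (beta = 2 at all lags).
#'
#' @param n_particles Number of particles.
#' @param v Speed (Angstrom/ps).
#' @param dt Timestep (ps).
#' @param n_frames Number of frames.
#' @param box Box edge lengths.
#' @param seed Integer seed.
#' @return `md_trajectory` with velocities set; metadata holds `v` and the
#'   unwrapped coordinates.
#' @export
gen_ballistic <- function(n_particles, v, dt, n_frames, box, seed = 1) {
  box <- .as_box(box)
  out <- with_seed(seed, {
    start <- matrix(stats::runif(n_particles * 3), n_particles, 3) %*% diag(as.numeric(box))
    vel <- .rand_unit(n_particles) * v
    list(start = start, vel = vel)
  })
  unwrapped <- array(0, c(n_frames, n_particles, 3))
  vels <- array(0, c(n_frames, n_particles, 3))
  for (k in seq_len(n_frames)) {
    unwrapped[k, , ] <- out$start + out$vel * (k - 1) * dt
    vels[k, , ] <- out$vel
  }
  wrapped <- unwrapped
  for (k in 1:3) wrapped[, , k] <- wrapped[, , k] %% as.numeric(box)[k]
  top <- topology(site_label = rep("X", n_particles),
                  element = rep("X", n_particles),
                  molecule_id = seq_len(n_particles))
  md_trajectory(wrapped, box = box, dt = dt, velocities = vels, topology = top,
                metadata = list(kind = "ballistic", v = v, seed = seed,
                                unwrapped = unwrapped))
}

# Stationary AR(1) (discretized Ornstein-Uhlenbeck) columns with marginal
# variance `var` and autocorrelation phi = exp(-dt/tau) per step.
.ou_columns <- function(n, ncol, var, phi) {
  innov_sd <- sqrt(var * (1 - phi^2))
  out <- matrix(0, n, ncol)
  for (j in seq_len(ncol)) {
    x0 <- stats::rnorm(1, 0, sqrt(var))
    e <- stats::rnorm(n - 1, 0, innov_sd)
    x <- stats::filter(e, phi, method = "recursive", init = x0)
    out[, j] <- c(x0, as.numeric(x))
  }
  out
}

#' Ornstein-Uhlenbeck velocity series
#'
#' A stationary Gaussian velocity process whose normalized autocorrelation
#' is `exp(-gamma t)`: the classic Langevin model against which the velocity
#' autocorrelation estimator is checked.
#'
#' @param gamma Relaxation rate (1/ps, > 0).
#' @param kT_over_m Per-axis velocity variance (Angstrom^2/ps^2).
#' @param dt Timestep (ps).
#' @param n_frames Number of steps.
#' @param seed Integer seed.
#' @return Object of class `velocity_series`: list with `v`
#'   (`n_frames` x 3 matrix, Angstrom/ps), `dt`, and ground-truth metadata.
#' @export
gen_ou_velocity <- function(gamma, kT_over_m = 1, dt = 0.01, n_frames = 1000,
                            seed = 1) {
  if (gamma <= 0) stop("gamma must be positive")
  phi <- exp(-gamma * dt)
  v <- with_seed(seed, .ou_columns(n_frames, 3, kT_over_m, phi))
  colnames(v) <- c("x", "y", "z")
  structure(list(v = v, dt = dt,
                 metadata = list(kind = "ou_velocity", gamma = gamma,
                                 kT_over_m = kT_over_m, seed = seed)),
            class = "velocity_series")
}

#' Synthetic off-diagonal stress series
#'
#' Three mutually independent stationary components (xy, xz, yz), each an
#' Ornstein-Uhlenbeck process with autocovariance `A exp(-t/tau_c)`. The
#' analytic Green-Kubo integral of this autocovariance is `A tau_c`, so the
#' shear viscosity implied by the series is known exactly.
#'
#' @param A Stationary variance of each component (squared stress units, > 0).
#' @param tau_c Correlation time (ps, > 0).
#' @param dt Timestep (ps).
#' @param n_frames Number of steps.
#' @param seed Integer seed.
#' @return Object of class `stress_series`: list with `P` (`n_frames` x 3
#'   matrix, columns xy/xz/yz), `dt`, and ground-truth metadata.
#' @export
gen_stress_series <- function(A, tau_c, dt = 0.01, n_frames = 10000, seed = 1) {
  if (A <= 0 || tau_c <= 0) stop("A and tau_c must be positive")
  phi <- exp(-dt / tau_c)
  P <- with_seed(seed, .ou_columns(n_frames, 3, A, phi))
  colnames(P) <- c("xy", "xz", "yz")
  structure(list(P = P, dt = dt,
                 metadata = list(kind = "stress_series", A = A, tau_c = tau_c,
                                 seed = seed)),
            class = "stress_series")
}

#' Rigid planar rotor unit-vector series
#'
#' A unit vector rotating uniformly in the xy-plane at angular speed
#' `omega`; its reorientation correlation is exactly `cos(omega tau)`.
#' Deterministic (no seed).
#'
#' @param omega Angular speed (rad/ps, >= 0).
#' @param dt Timestep (ps).
#' @param n_frames Number of steps.
#' @return Object of class `vector_series`: array `[n_frames, 1, 3]` of unit
#'   vectors plus `dt` and metadata.
#' @export
gen_rigid_rotor <- function(omega, dt = 0.1, n_frames = 100) {
  if (omega < 0) stop("omega must be >= 0")
  t <- (seq_len(n_frames) - 1) * dt
  a <- array(0, c(n_frames, 1, 3))
  a[, 1, 1] <- cos(omega * t)
  a[, 1, 2] <- sin(omega * t)
  structure(list(vectors = a, dt = dt,
                 metadata = list(kind = "rigid_rotor", omega = omega)),
            class = "vector_series")
}

# Rigid body templates for the toy mixture (local coordinates, Angstrom).
.TOY_FA_SITES <- list(
  labels = c("C1", "O1", "O2", "OA", "HA"),
  elements = c("C", "O", "O", "O", "H"),
  xyz = rbind(
    c(0.00, 0.00, 0.00),    # C1 carboxyl carbon
    c(1.10, 0.60, 0.00),    # O1 carbonyl oxygen
    c(0.05, -1.25, 0.45),   # O2 second carboxyl oxygen
    c(-1.15, 0.70, 0.00),   # OA hydroxyl oxygen
    c(-1.15, 1.67, 0.00)    # HA hydroxyl hydrogen (0.97 A above OA)
  )
)
.TOY_CH_SITES <- list(
  labels = c("N", "O", "HO"),
  elements = c("N", "O", "H"),
  xyz = rbind(
    c(0.00, 0.00, 0.00),    # quaternary nitrogen (bead)
    c(2.50, 0.00, 0.00),    # hydroxyl oxygen
    c(3.20, 0.65, 0.00)     # hydroxyl hydrogen
  )
)
.TOY_WAT_SITES <- list(
  labels = c("OW", "HW1", "HW2"),
  elements = c("O", "H", "H"),
  xyz = rbind(
    c(0.00, 0.00, 0.00),
    c(0.96, 0.00, 0.00),
    c(-0.24, 0.93, 0.00)
  )
)

.toy_params_path <- function() {
  system.file("extdata", "toy_params.csv", package = "destraj", mustWork = TRUE)
}

# Rotate template rows by a random rotation matrix and translate.
.place_template <- function(tmpl, center, rot) {
  sweep(tmpl %*% t(rot), 2, center, "+")
}

.rand_rotation <- function() {
  z <- .rand_unit(1)[1, ]
  x <- .rand_perp(matrix(z, 1))[1, ]
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  cbind(x, y, z)
}

#' Coarse toy choline-chloride / fatty-acid mixture
#'
#' Builds a desk-scale stand-in for an equilibrated DES box: rigid coarse
#' molecules (choline with a hydroxyl O-H, chloride anions, fatty acids
#' with a full carboxyl site set C1/O1/O2/OA/HA, optional water) placed on
#' a non-overlapping grid. A controllable fraction of the fatty acids is
#' planted in a hydrogen-bond contact FA.HA...Cl at `contact_distance`
#' with an OA-HA...Cl angle of 112.5 degrees (the chloride-acceptor
#' geometry). The first waters, if any, are planted next to the remaining
#' chlorides so salt-water interactions are nonzero. Charges and
#' Lennard-Jones parameters come from the packaged toy parameter table.
#'
#' @param n_salt Number of choline chloride ion pairs (>= 0).
#' @param n_fa Number of fatty-acid molecules (>= 0).
#' @param fa_type `"CAP"` (caprylic) or `"LUA"` (lauric).
#' @param box Box edge lengths; must fit all molecules on an 8-Angstrom
#'   grid (error otherwise).
#' @param planted_fraction Fraction of fatty acids given a planted
#'   HA...Cl contact (requires enough chlorides).
#' @param n_water Number of water molecules.
#' @param n_frames Number of (static) frames.
#' @param contact_distance Planted H...A distance (Angstrom).
#' @param seed Integer seed.
#' @return List with `trajectory`, `topology`, and `truth` (planted counts
#'   and geometry).
#' @export
gen_toy_des_mixture <- function(n_salt, n_fa, fa_type = c("CAP", "LUA"),
                                box = NULL, planted_fraction = 0.5,
                                n_water = 0, n_frames = 1,
                                contact_distance = 2.0, seed = 1) {
  fa_type <- match.arg(fa_type)
  if (n_salt < 0 || n_fa < 0 || n_water < 0) stop("counts must be >= 0")
  n_planted <- round(planted_fraction * n_fa)
  if (n_planted > n_salt) stop("not enough chlorides for the planted contacts")
  # grid cells: FA(+planted Cl), choline, free Cl, water each get a cell
  n_entities <- n_fa + n_salt + (n_salt - n_planted) + n_water
  cell <- 8
  if (is.null(box)) {
    side <- cell * ceiling(max(2, n_entities)^(1 / 3) + 1e-9)
    box <- simulation_box(side)
  } else {
    box <- .as_box(box)
  }
  ncell <- floor(as.numeric(box) / cell)
  if (prod(ncell) < n_entities) stop("packing failure: box too small for grid placement")

  params <- utils::read.csv(.toy_params_path(), stringsAsFactors = FALSE)

  with_seed(seed, {
    slots <- sample(prod(ncell), n_entities)
    ix <- (slots - 1) %% ncell[1]
    iy <- ((slots - 1) %/% ncell[1]) %% ncell[2]
    iz <- (slots - 1) %/% (ncell[1] * ncell[2])
    centers <- cbind(ix, iy, iz) * cell + cell / 2

    pos <- list(); lab <- list(); ele <- list(); mid <- list(); mty <- list()
    mol <- 0L; ci <- 0L
    add_mol <- function(sites, center, rot, type) {
      mol <<- mol + 1L
      p <- .place_template(sites$xyz, center, rot)
      pos[[length(pos) + 1]] <<- p
      lab[[length(lab) + 1]] <<- sites$labels
      ele[[length(ele) + 1]] <<- sites$elements
      mid[[length(mid) + 1]] <<- rep(mol, length(sites$labels))
      mty[[length(mty) + 1]] <<- rep(type, length(sites$labels))
      p
    }

    cl_used <- 0L
    # fatty acids; the first n_planted carry a chloride in contact geometry
    for (f in seq_len(n_fa)) {
      ci <- ci + 1L
      rot <- .rand_rotation()
      p <- add_mol(.TOY_FA_SITES, centers[ci, ], rot, fa_type)
      if (f <= n_planted) {
        oa <- p[4, ]; ha <- p[5, ]
        u <- (ha - oa) / sqrt(sum((ha - oa)^2))   # OA -> HA direction
        perp <- .rand_perp(matrix(u, 1))[1, ]
        th <- 112.5 * pi / 180
        # direction HA -> Cl making the planted OA-HA...Cl angle
        dcl <- -u * cos(th) + perp * sin(th)
        clp <- ha + dcl * contact_distance
        mol <- mol + 1L
        pos[[length(pos) + 1]] <- matrix(clp, 1)
        lab[[length(lab) + 1]] <- "Cl"
        ele[[length(ele) + 1]] <- "Cl"
        mid[[length(mid) + 1]] <- mol
        mty[[length(mty) + 1]] <- "CL"
        cl_used <- cl_used + 1L
      }
    }
    # cholines
    for (s in seq_len(n_salt)) {
      ci <- ci + 1L
      add_mol(.TOY_CH_SITES, centers[ci, ], .rand_rotation(), "CH")
    }
    # free chlorides, each optionally with an adjacent planted water
    n_free_cl <- n_salt - n_planted
    free_cl_pos <- matrix(0, n_free_cl, 3)
    for (s in seq_len(n_free_cl)) {
      ci <- ci + 1L
      mol <- mol + 1L
      free_cl_pos[s, ] <- centers[ci, ]
      pos[[length(pos) + 1]] <- matrix(centers[ci, ], 1)
      lab[[length(lab) + 1]] <- "Cl"
      ele[[length(ele) + 1]] <- "Cl"
      mid[[length(mid) + 1]] <- mol
      mty[[length(mty) + 1]] <- "CL"
    }
    # waters: the first min(n_water, n_free_cl) sit 3 A from a free chloride
    # with one O-H pointing at it (stable salt-water interaction energy)
    for (w in seq_len(n_water)) {
      if (w <= n_free_cl) {
        cl <- free_cl_pos[w, ]
        u <- .rand_unit(1)[1, ]
        ow <- cl + u * 3.0
        rot <- diag(3)
        # orient HW1 from OW toward the chloride
        hdir <- -u
        perp <- .rand_perp(matrix(hdir, 1))[1, ]
        p <- rbind(ow, ow + hdir * 0.96, ow + 0.96 * (hdir * cos(104.5 * pi / 180) +
                                                        perp * sin(104.5 * pi / 180)))
      } else {
        ci <- ci + 1L
        p <- .place_template(.TOY_WAT_SITES$xyz, centers[ci, ], .rand_rotation())
      }
      mol <- mol + 1L
      pos[[length(pos) + 1]] <- p
      lab[[length(lab) + 1]] <- .TOY_WAT_SITES$labels
      ele[[length(ele) + 1]] <- .TOY_WAT_SITES$elements
      mid[[length(mid) + 1]] <- rep(mol, 3)
      mty[[length(mty) + 1]] <- rep("WAT", 3)
    }

    allpos <- do.call(rbind, pos)
    top <- topology(site_label = unlist(lab), element = unlist(ele),
                    molecule_id = unlist(mid), molecule_type = unlist(mty))
    top <- .apply_params(top, params)
    coords <- array(0, c(n_frames, nrow(allpos), 3))
    for (k in seq_len(n_frames)) coords[k, , ] <- allpos
    traj <- md_trajectory(coords, box = box, dt = 1, topology = top,
                          metadata = list(kind = "toy_des_mixture",
                                          seed = seed,
                                          n_salt = n_salt, n_fa = n_fa,
                                          fa_type = fa_type,
                                          n_water = n_water,
                                          planted_fraction = planted_fraction,
                                          n_planted = n_planted,
                                          contact_distance = contact_distance))
    list(trajectory = traj, topology = top,
         truth = list(n_planted = n_planted,
                      contact_distance = contact_distance,
                      contact_angle = 112.5))
  })
}
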