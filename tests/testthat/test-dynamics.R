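test_that("static particles have identically zero MSD and no diffusive regime", {
  tr <- gen_brownian(10, D = 0, dt = 10, n_frames = 50, box = 30, seed = 1)
  m <- msd(tr)
  expect_equal(m$msd, rep(0, length(m$msd)))
  sd0 <- self_diffusion(m)
  expect_false(sd0$found)
  expect_true(is.na(sd0$D))
})

test_that("ballistic MSD is exactly v^2 tau^2 with beta = 2", {
  tr <- gen_ballistic(30, v = 0.3, dt = 2, n_frames = 80, box = 1000, seed = 3)
  m <- msd(tr)
  expect_equal(m$msd, 0.09 * m$tau^2, tolerance = 1e-9)
  be <- beta_exponent(m)
  expect_true(all(abs(be$beta - 2) < 0.01))
})

test_that("beta of a tabulated power law recovers the exponent exactly", {
  tau <- seq(0, 100, by = 0.5)
  for (k in c(0.5, 1, 1.7)) {
    m <- msd_from_table(tau, 0.3 * tau^k)
    be <- beta_exponent(m, smooth_window = 1)
    expect_lt(max(abs(be$beta - k)), 1e-6)
  }
})

test_that("MSD multiple-origin estimator equals the naive double loop", {
  tr <- gen_brownian(5, D = 3, dt = 5, n_frames = 40, box = 30, seed = 17)
  m <- msd(tr, max_lag_fraction = 0.5)
  oracle <- brute_msd(unwrap_coordinates(tr), max_lag = 19)
  expect_equal(m$msd, oracle, tolerance = 1e-9)
})

test_that("unwrapping recovers the generator's true coordinates", {
  tr <- gen_brownian(20, D = 5, dt = 10, n_frames = 100, box = 15, seed = 23)
  un <- unwrap_coordinates(tr)
  truth <- tr$metadata$unwrapped
  # both start from the same wrapped-in-box first frame
  shift <- un[1, , ] - truth[1, , ]
  for (k in seq_len(dim(un)[1])) truth[k, , ] <- truth[k, , ] + shift
  expect_lt(max(abs(un - truth)), 1e-9)
})

test_that("Brownian self-diffusion is recovered with beta near 1", {
  tr <- gen_brownian(200, D = 1, dt = 10, n_frames = 500, box = 50, seed = 29)
  m <- msd(tr)
  est <- self_diffusion(m)
  expect_true(est$found)
  expect_equal(est$D, 1, tolerance = 0.1)
  be <- beta_exponent(m)
  expect_lt(abs(mean(be$beta[be$tau > 100], na.rm = TRUE) - 1), 0.1)
  # determinism: same seed, same answer
  tr2 <- gen_brownian(200, D = 1, dt = 10, n_frames = 500, box = 50, seed = 29)
  expect_identical(self_diffusion(msd(tr2))$D, est$D)
})

test_that("constant velocities give a flat VACF with no zero crossings", {
  v <- matrix(1, 500, 3)
  res <- vacf(v, dt = 0.1)
  expect_equal(res$cv, rep(1, length(res$cv)))
  expect_true(is.na(res$t1) && is.na(res$t2))
})

test_that("cosine VACF crossings sit at odd quarter-periods", {
  om <- 0.8
  t <- seq(0, 60, 0.05)
  v <- cbind(cos(om * t), 0, 0)  # autocorrelation of cos is cos
  res <- vacf(v, dt = 0.05, max_lag_fraction = 0.3)
  expect_equal(res$t1, pi / (2 * om), tolerance = 0.06)
  expect_equal(res$t2, 3 * pi / (2 * om), tolerance = 0.06)
})

test_that("VACF and VRD are invariant under a global rotation", {
  ou <- gen_ou_velocity(gamma = 1, dt = 0.05, n_frames = 2000, seed = 5)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  r1 <- vacf(ou$v, dt = 0.05)
  r2 <- vacf(ou$v %*% t(R), dt = 0.05)
  expect_equal(r1$cv, r2$cv, tolerance = 1e-9)
  rr <- gen_rigid_rotor(omega = 0.4, dt = 0.1, n_frames = 100)
  rot <- rr
  for (k in seq_len(dim(rr$vectors)[1])) {
    rot$vectors[k, 1, ] <- R %*% rr$vectors[k, 1, ]
  }
  expect_equal(vrd(rr)$vrd, vrd(rot)$vrd, tolerance = 1e-12)
})

test_that("independent random reorientation decorrelates immediately", {
  set.seed(61)
  n <- 400; nv <- 50
  vec <- array(rnorm(n * nv * 3), c(n, nv, 3))
  res <- vrd(vec, dt = 1)
  expect_equal(res$vrd[1], 1)
  expect_lt(max(abs(res$vrd[-1])), 4 / sqrt(nv * n / 2))
})

test_that("VRD on a trajectory tracks planted bond vectors", {
  mix <- gen_toy_des_mixture(n_salt = 20, n_fa = 20, planted_fraction = 0,
                             n_frames = 5, seed = 9)
  res <- vrd(mix$trajectory, ref_type = "CAP", sites = c("OA", "HA"))
  expect_equal(res$vrd, rep(1, length(res$vrd)), tolerance = 1e-12)
  expect_equal(res$skipped, 0)
})

test_that("Green-Kubo viscosity matches the analytic value for an OU stress", {
  A <- 0.02; tau_c <- 1; V <- 5e3; T_ <- 353
  ss <- gen_stress_series(A = A, tau_c = tau_c, dt = 0.02, n_frames = 3e5,
                          seed = 43)
  res <- gk_viscosity(ss, volume = V, temperature = T_, max_lag = 400)
  kbt_j <- 0.0019872041 * T_ * 4184 / 6.02214076e23
  conv <- 4184 / (6.02214076e23 * 1e-30)
  eta_true <- V * 1e-30 / kbt_j * A * tau_c * conv^2 * 1e-12 * 1e3
  expect_equal(res$eta, eta_true, tolerance = 0.1)
  expect_equal(res$eta_t[1], 0)
  # linearity: doubling A doubles eta (same seed scales the same noise)
  ss2 <- ss
  ss2$P <- ss$P * sqrt(2)
  res2 <- gk_viscosity(ss2, volume = V, temperature = T_, max_lag = 400)
  expect_equal(res2$eta, 2 * res$eta, tolerance = 1e-9)
})

test_that("zero stress gives zero viscosity and a non-decaying ACF warns", {
  z <- matrix(0, 1000, 3)
  colnames(z) <- c("xy", "xz", "yz")
  res <- suppressWarnings(gk_viscosity(z, volume = 1e3, temperature = 300,
                                       dt = 0.1))
  expect_true(all(res$eta_t == 0))
  const <- matrix(1, 500, 3)
  expect_warning(gk_viscosity(const, volume = 1e3, temperature = 300,
                              dt = 0.1), "plateau")
})

test_that("stress-unit conversion follows the declared constants", {
  # 1 kcal/mol/A^3 = 4184 / (N_A * 1e-30) Pa
  conv <- 4184 / (6.02214076e23 * 1e-30)
  expect_equal(conv, 6.9477e9, tolerance = 1e-4)
  # eta scales with conv^2 between unit declarations
  ss <- gen_stress_series(A = 1, tau_c = 0.5, dt = 0.02, n_frames = 5e4,
                          seed = 3)
  e1 <- gk_viscosity(ss, volume = 1e3, temperature = 300, max_lag = 200,
                     stress_unit = "Pa")$eta
  e2 <- gk_viscosity(ss, volume = 1e3, temperature = 300, max_lag = 200,
                     stress_unit = "kcal_molA3")$eta
  expect_equal(e2 / e1, conv^2, tolerance = 1e-9)
})
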