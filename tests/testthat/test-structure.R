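test_that("two fixed atoms give a single RDF bin and CN(4 A) = 1", {
  top <- atoms_topology(2)
  tr <- traj_from_positions(list(rbind(c(0, 0, 0), c(3, 0, 0))), box = 50,
                            top = top)
  r <- rdf(tr, 1, 2, dr = 0.05, r_max = 10)
  expect_equal(sum(r$g > 0), 1)
  expect_equal(r$r[which(r$g > 0)], 3.025)  # bin [3.0, 3.05)
  expect_equal(coordination_number(r, 4), 1, tolerance = 1e-12)
  expect_error(rdf(tr, 1, 2, r_max = 30), "half")
})

test_that("ideal-gas RDF is 1 within binomial error in every bin", {
  tr <- gen_ideal_gas(400, 20, 30, seed = 5)
  r <- rdf(tr, 1:400, 1:400, dr = 0.25, r_max = 8)
  sel <- r$r >= 2 & r$r <= 8
  # per-bin count is ~Poisson; sigma of g estimate = 1/sqrt(expected count)
  shell <- 4 / 3 * pi * (r$edges[-1]^3 - r$edges[-length(r$edges)]^3)
  expected <- r$rho * shell * r$n_a * r$n_frames
  sigma_g <- 1 / sqrt(expected)
  expect_true(all(abs(r$g[sel] - 1) < 3.5 * sigma_g[sel]))
  expect_equal(mean(r$g[sel]), 1, tolerance = 0.01)
})

test_that("CN(r) equals brute-force neighbor counting at bin edges", {
  set.seed(42)
  top <- atoms_topology(40)
  tr <- gen_ideal_gas(40, 15, 5, seed = 77)
  r <- rdf(tr, 1:40, 1:40, dr = 0.25, r_max = 7)
  box <- as.numeric(tr$box)
  for (edge in sample(r$edges[-1], 20)) {
    cnt <- 0
    for (k in 1:5) {
      for (i in 1:40) for (j in 1:40) {
        if (i == j) next
        d <- tr$coords[k, j, ] - tr$coords[k, i, ]
        d <- d - box * round(d / box)
        if (sqrt(sum(d^2)) < edge) cnt <- cnt + 1
      }
    }
    expect_equal(coordination_number(r, edge), cnt / (5 * 40),
                 tolerance = 1e-9)
  }
})

test_that("first minimum is found on an analytic double-Gaussian curve", {
  r <- seq(0.025, 8, by = 0.05)
  g <- 1 + exp(-(r - 2)^2 / 0.02) - 0.5 * exp(-(r - 3)^2 / 0.02)
  fm <- first_minimum(list(r = r, g = g))
  expect_true(fm$found)
  expect_equal(fm$r_min1, 3.0, tolerance = 0.05)
  # featureless g -> no shell
  flat <- first_minimum(list(r = r, g = rep(1, length(r))))
  expect_false(flat$found)
  expect_true(is.na(flat$r_min1))
})

test_that("ideal gas has no solvation shell", {
  tr <- gen_ideal_gas(300, 20, 10, seed = 19)
  r <- rdf(tr, 1:300, 1:300, dr = 0.25, r_max = 8)
  fm <- first_minimum(r)
  expect_false(fm$found)
})

test_that("toy-DES planted shell puts the HA-Cl RDF maximum at 2.0 A", {
  mix <- gen_toy_des_mixture(n_salt = 80, n_fa = 80, planted_fraction = 0.6,
                             seed = 23)
  r <- rdf(mix$trajectory, list(site = "HA", type = "CAP"), "Cl",
           dr = 0.07, r_max = 8)
  peak_bin <- which.max(r$g)
  expect_lte(r$edges[peak_bin], 2.0)
  expect_gt(r$edges[peak_bin + 1], 2.0)
  fm <- first_minimum(r)
  expect_true(fm$found)
  expect_gt(fm$r_min1, 2.0)
  expect_lt(fm$r_min1, 4.0)
})

test_that("ADF puts exact geometries in the right bins", {
  top <- topology(c("A", "B", "C"), c("C", "C", "C"), 1:3)
  right <- traj_from_positions(
    list(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))), box = 30, top = top)
  a <- adf(right, "A", "B", "C", 5, 5, bin = 1)
  expect_equal(a$alpha[a$counts > 0], 90.5)  # bin [90, 91)
  lin <- traj_from_positions(
    list(rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))), box = 30, top = top)
  al <- adf(lin, "A", "B", "C", 5, 5, bin = 1)
  expect_equal(al$alpha[al$counts > 0], 179.5)
  # normalization: unit trapezoid integral
  tot <- sum((a$density[-1] + a$density[-length(a$density)]) / 2 *
               diff(a$alpha))
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("isotropic triples give a flat ADF after the 1/sin correction", {
  set.seed(7)
  n <- 20000
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pos <- rbind(c(3, 0, 0), c(0, 0, 0), 2 * dirs)
  top <- topology(c("A", "B", rep("C", n)), c("C", "C", rep("C", n)),
                  1:(n + 2))
  tr <- traj_from_positions(list(pos), box = 100, top = top)
  a <- adf(tr, "A", "B", "C", 5, 5, bin = 5)
  # raw angle counts follow the sin(alpha) measure
  edges <- seq(0, 180, 5)
  p_sin <- (cos(edges[-length(edges)] * pi / 180) - cos(edges[-1] * pi / 180)) / 2
  keep <- a$alpha > 15 & a$alpha < 165
  chi <- suppressWarnings(
    chisq.test(a$counts[keep], p = p_sin[keep] / sum(p_sin[keep])))
  expect_gt(chi$p.value, 0.01)
  # corrected density is flat: relative spread small away from the poles
  expect_lt(sd(a$density[keep]) / mean(a$density[keep]), 0.1)
})

test_that("ADF is invariant under global rotation and translation", {
  set.seed(8)
  n <- 200
  pos <- matrix(runif(3 * (n + 2)) * 10 + 40, ncol = 3)
  top <- topology(c("A", "B", rep("C", n)), rep("C", n + 2), 1:(n + 2))
  tr <- traj_from_positions(list(pos), box = 200, top = top)
  a1 <- adf(tr, "A", "B", "C", 8, 8, bin = 2)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos2 <- sweep(pos %*% t(R), 2, c(5, 5, 5), "+")
  tr2 <- traj_from_positions(list(pos2), box = 200, top = top)
  a2 <- adf(tr2, "A", "B", "C", 8, 8, bin = 2)
  expect_equal(a1$counts, a2$counts)
  expect_equal(a1$density, a2$density, tolerance = 1e-9)
})

test_that("combined distance/angle histogram resolves planted populations", {
  pg <- gen_planted_geometry(20, distance = 2.0, angle = 160, box = 80, seed = 3)
  tr <- traj_from_positions(list(pg$frame$positions), box = 80,
                            top = pg$topology)
  # breaks chosen with the planted values interior to a bin
  cd <- cdf_dist_angle(tr, ref_type = "OTHER", pair = c("HA", "Cl"),
                       triple = c("OA", "HA", "Cl"), target_site = "Cl",
                       dist_breaks = seq(0, 3.9, 0.3),
                       angle_breaks = seq(0, 180, 7.5), r_max = 3.9)
  occupied <- which(cd$counts > 0, arr.ind = TRUE)
  expect_equal(nrow(occupied), 1)
  expect_equal(cd$x[occupied[1, 1]], 1.95)    # bin [1.8, 2.1)
  expect_equal(cd$y[occupied[1, 2]], 161.25)  # bin [157.5, 165)
  expect_equal(max(cd$density), 1)
})

test_that("CDF marginal over angle equals the plain distance histogram", {
  mix <- gen_toy_des_mixture(n_salt = 40, n_fa = 40, planted_fraction = 0.5,
                             seed = 31)
  breaks <- seq(0, 6, 0.2)
  cd <- cdf_dist_angle(mix$trajectory, ref_type = "CAP",
                       pair = c("HA", "Cl"), triple = c("OA", "HA", "Cl"),
                       target_site = "Cl", dist_breaks = breaks,
                       angle_breaks = seq(0, 180, 5), r_max = 6)
  marg <- rowSums(cd$counts)
  # direct histogram over the same instances
  top <- mix$topology
  ha <- which(top$site_label == "HA" & top$molecule_type == "CAP")
  cl <- which(top$site_label == "Cl")
  box <- as.numeric(mix$trajectory$box)
  d <- c()
  p <- get_frame(mix$trajectory, 1)$positions
  for (i in ha) for (j in cl) {
    if (top$molecule_id[i] == top$molecule_id[j]) next
    dv <- p[j, ] - p[i, ]
    dv <- dv - box * round(dv / box)
    r <- sqrt(sum(dv^2))
    if (r <= 6) d <- c(d, r)
  }
  href <- tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                   nbins = length(breaks) - 1)
  expect_equal(unname(marg), href, tolerance = 1e-9)
})

test_that("swapping the two distance specs transposes the CDF matrix", {
  mix <- gen_toy_des_mixture(n_salt = 30, n_fa = 30, planted_fraction = 0.5,
                             seed = 37)
  b <- seq(0, 12, 0.5)
  cd1 <- cdf_dist_dist(mix$trajectory, ref_type = "CAP", target_type = "CH",
                       pair_a = c("HA", "O"), pair_b = c("OA", "N"),
                       breaks_a = b, breaks_b = b)
  cd2 <- cdf_dist_dist(mix$trajectory, ref_type = "CAP", target_type = "CH",
                       pair_a = c("OA", "N"), pair_b = c("HA", "O"),
                       breaks_a = b, breaks_b = b)
  expect_equal(cd1$counts, t(cd2$counts))
})

test_that("planted distance pairs occupy a single distance/distance cell", {
  # one reference CAP and one choline at controlled distances
  mix <- gen_toy_des_mixture(n_salt = 25, n_fa = 25, planted_fraction = 0,
                             seed = 5)
  b <- seq(0, 16, 0.5)
  cd <- cdf_dist_dist(mix$trajectory, ref_type = "CAP", target_type = "CH",
                      pair_a = c("C1", "N"), pair_b = c("C1", "N"),
                      breaks_a = b, breaks_b = b)
  expect_true(all(cd$counts == t(cd$counts)))  # same spec twice: symmetric
  expect_true(all(diag(cd$counts) >= 0))
})

test_that("SDF concentrates planted targets in the right voxel", {
  # references with anchors along x, target always at local (2, 0, 0)
  n_ref <- 30
  pos <- NULL; lab <- NULL; mid <- NULL; mty <- NULL
  set.seed(11)
  for (m in seq_len(n_ref)) {
    center <- runif(3) * 30 + 15
    th <- runif(1) * 2 * pi
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    a1 <- center
    a2 <- center + R %*% c(1.5, 0, 0)
    a3 <- center + R %*% c(0, 0, 1.5)
    tgt <- center + R %*% c(2.2, 0.1, -0.1)  # interior to a voxel
    pos <- rbind(pos, a1, t(a2), t(a3), t(tgt))
    lab <- c(lab, "A1", "A2", "A3", "T")
    mid <- c(mid, rep(2 * m - 1, 3), 2 * m)
    mty <- c(mty, rep("CAP", 3), "CL")
  }
  top <- topology(lab, rep("C", length(lab)), mid, mty)
  tr <- traj_from_positions(list(pos), box = 60, top = top)
  g <- sdf(tr, ref_type = "CAP", anchors = c("A1", "A2", "A3"),
           target = "T", voxel = 0.5, extent = 4)
  peak <- which(g$density == max(g$density), arr.ind = TRUE)
  centers <- (g$edges[-1] + g$edges[-length(g$edges)]) / 2
  expect_equal(centers[peak[1, 1]], 2.25, tolerance = 1e-9)
  expect_equal(centers[peak[1, 2]], 0.25, tolerance = 1e-9)
  expect_equal(centers[peak[1, 3]], -0.25, tolerance = 1e-9)
  expect_equal(g$n_instances, n_ref)
  # rigid rotation of the whole frame leaves the SDF unchanged
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  tr2 <- traj_from_positions(list(sweep(pos, 2, c(30, 30, 30)) %*% t(R) +
                                    matrix(30, nrow(pos), 3)), box = 60,
                             top = top)
  g2 <- sdf(tr2, ref_type = "CAP", anchors = c("A1", "A2", "A3"),
            target = "T", voxel = 0.5, extent = 4)
  expect_equal(g$density, g2$density, tolerance = 1e-9)
})

test_that("an isotropic target shell maps to a spherical SDF shell", {
  set.seed(13)
  n <- 20000
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  center <- c(50, 50, 50)
  pos <- rbind(center, center + c(1.5, 0, 0), center + c(0, 1.5, 0),
               sweep(3 * dirs, 2, center, "+"))
  top <- topology(c("A1", "A2", "A3", rep("T", n)), rep("C", n + 3),
                  c(1, 1, 1, 1 + seq_len(n)),
                  c(rep("CAP", 3), rep("CL", n)))
  tr <- traj_from_positions(list(pos), box = 100, top = top)
  g <- sdf(tr, "CAP", c("A1", "A2", "A3"), "T", voxel = 1, extent = 5)
  centers <- (g$edges[-1] + g$edges[-length(g$edges)]) / 2
  rad <- array(0, dim(g$density))
  for (i in seq_along(centers)) for (j in seq_along(centers))
    for (k in seq_along(centers))
      rad[i, j, k] <- sqrt(centers[i]^2 + centers[j]^2 + centers[k]^2)
  shell <- g$density[rad > 2.5 & rad < 3.5]
  shell <- shell[shell > 0]
  expect_gt(length(shell), 50)
  expect_lt(max(shell) / stats::median(shell), 4)
  expect_equal(sum(g$density[rad < 2]), 0)
})
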