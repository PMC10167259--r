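# Shared in-code fixtures for the test suite.

# A trajectory with explicit coordinates: pos_list is a list of n x 3
# matrices (one per frame).
traj_from_positions <- function(pos_list, box, top = NULL, dt = 1) {
  nf <- length(pos_list)
  na <- nrow(pos_list[[1]])
  coords <- array(0, c(nf, na, 3))
  for (k in seq_len(nf)) coords[k, , ] <- pos_list[[k]]
  md_trajectory(coords, box = box, dt = dt, topology = top)
}

# Minimal topology of n single-atom molecules labelled "X".
atoms_topology <- function(n, label = "X") {
  topology(site_label = rep(label, n), element = rep("X", n),
           molecule_id = seq_len(n))
}

# Brute-force minimum-image distance via the 27 periodic images.
brute_min_image_dist <- function(p1, p2, box) {
  best <- Inf
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
    d <- p2 + c(sx, sy, sz) * box - p1
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# Brute-force hydrogen-bond triple enumeration (independent of the
# package's pair-matrix path): loops over every donor-H pair and acceptor.
brute_hbonds <- function(frame, top, crit) {
  don <- which(top$site_label == crit$donor)
  acc <- which(top$site_label == crit$acceptor)
  p <- frame$positions
  box <- as.numeric(frame$box)
  n <- 0L
  for (d in don) {
    hyd <- which(top$site_label == crit$hydrogen &
                   top$molecule_id == top$molecule_id[d])
    for (h in hyd) {
      for (a in acc) {
        if (top$molecule_id[a] == top$molecule_id[h]) next
        dv <- p[a, ] - p[h, ]
        dv <- dv - box * round(dv / box)
        r <- sqrt(sum(dv^2))
        if (r >= crit$dmax) next
        u <- p[d, ] - p[h, ]
        u <- u - box * round(u / box)
        ang <- acos(max(-1, min(1, sum(u * dv) /
                                  (sqrt(sum(u^2)) * r)))) * 180 / pi
        if (ang >= crit$angle[1] && ang <= crit$angle[2]) n <- n + 1L
      }
    }
  }
  n
}

# Brute-force Coulomb / Lennard-Jones double loops.
brute_coulomb <- function(frame, top, ia, ib) {
  p <- frame$positions
  box <- as.numeric(frame$box)
  e <- 0
  for (i in ia) for (j in ib) {
    if (top$molecule_id[i] == top$molecule_id[j]) next
    d <- p[j, ] - p[i, ]
    d <- d - box * round(d / box)
    e <- e + 332.0636 * top$charge[i] * top$charge[j] / sqrt(sum(d^2))
  }
  e
}

brute_vdw <- function(frame, top, ia, ib) {
  p <- frame$positions
  box <- as.numeric(frame$box)
  e <- 0
  for (i in ia) for (j in ib) {
    if (top$molecule_id[i] == top$molecule_id[j]) next
    d <- p[j, ] - p[i, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d^2))
    d0 <- sqrt(top$d0[i] * top$d0[j])
    r0 <- (top$r0[i] + top$r0[j]) / 2
    e <- e + d0 * ((r0 / r)^12 - 2 * (r0 / r)^6)
  }
  e
}

# Naive two-loop MSD estimator (all origins), independent oracle.
brute_msd <- function(unwrapped, max_lag) {
  nf <- dim(unwrapped)[1]
  np <- dim(unwrapped)[2]
  out <- numeric(max_lag + 1)
  for (lag in seq_len(max_lag)) {
    tot <- 0
    for (t0 in seq_len(nf - lag)) {
      d <- unwrapped[t0 + lag, , , drop = FALSE] - unwrapped[t0, , , drop = FALSE]
      tot <- tot + sum(d^2)
    }
    out[lag + 1] <- tot / ((nf - lag) * np)
  }
  out
}

toy_energy_pairs <- function(fa_type = "CAP") {
  list(
    salt_water = list(a = list(type = c("CH", "CL")), b = list(type = "WAT")),
    salt_fas = list(a = list(type = c("CH", "CL")), b = list(type = fa_type)),
    fas_water = list(a = list(type = fa_type), b = list(type = "WAT"))
  )
}

table2_path <- function() {
  system.file("extdata", "table2_energies.csv", package = "destraj")
}
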