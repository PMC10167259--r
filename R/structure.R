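# Structural correlation functions: site-site RDF with coordination
# numbers, angular distribution functions, combined (2D) distribution
# functions, and spatial distribution functions in a molecule-fixed frame.

.traj_topology <- function(traj, topology = NULL) {
  top <- if (!is.null(topology)) topology else traj$topology
  if (is.null(top)) stop("a topology is required (attach one to the trajectory)")
  top
}

#' Site-site radial distribution function with coordination number
#'
#' Computes the intermolecular pair distribution `g(r)` between two site
#' groups under minimum-image periodic boundary conditions, normalized so a
#' homogeneous uncorrelated system gives 1, together with the running
#' coordination number `CN(r)` (the mean number of B sites within `r` of an
#' A site). `CN` is accumulated from the exact per-bin pair counts, i.e. the
#' binned form of `4 pi rho int g(s) s^2 ds`, and therefore agrees with
#' direct neighbor counting to machine precision at bin edges.
#'
#' @param traj An `md_trajectory`.
#' @param group_a,group_b Atom selections: integer indices, site-label
#'   character vectors, or `list(site=, type=)`.
#' @param dr Bin width (Angstrom); bins are half-open `[r, r+dr)`.
#' @param r_max Histogram range; must not exceed half the shortest box edge
#'   (default exactly that).
#' @param exclude_intramolecular Drop pairs within the same molecule
#'   (site-site RDFs in mixtures are intermolecular correlations).
#' @param topology Optional topology overriding the trajectory's.
#' @return Object of class `rdf_result`: bin centers `r`, `g`, cumulative
#'   `cn` (at upper bin edges), density `rho` of group B, bin `edges`, and
#'   normalization metadata.
#' @export
rdf <- function(traj, group_a, group_b, dr = 0.05, r_max = NULL,
                exclude_intramolecular = TRUE, topology = NULL) {
  top <- .traj_topology(traj, topology)
  ia <- .resolve_group(group_a, top)
  ib <- .resolve_group(group_b, top)
  box <- as.numeric(traj$box)
  half <- min(box) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) stop("r_max exceeds half the shortest box edge")
  n_bins <- ceiling(r_max / dr - 1e-12)
  edges <- (0:n_bins) * dr
  same_group <- identical(sort(ia), sort(ib))
  mol <- top$molecule_id
  counts <- numeric(n_bins)
  nf <- n_frames(traj)
  for (k in seq_len(nf)) {
    pa <- matrix(traj$coords[k, ia, ], ncol = 3)
    pb <- matrix(traj$coords[k, ib, ], ncol = 3)
    dm <- .pair_dist_matrix(pa, pb, box)
    # drop self pairs and (optionally) intramolecular pairs
    self <- outer(ia, ib, "==")
    dm[self] <- NA
    if (exclude_intramolecular) {
      dm[outer(mol[ia], mol[ib], "==")] <- NA
    }
    d <- dm[!is.na(dm) & dm < r_max]
    if (length(d)) {
      bin <- pmin(floor(d / dr) + 1L, n_bins)
      counts <- counts + tabulate(bin, nbins = n_bins)
    }
  }
  vol <- prod(box)
  n_a <- length(ia)
  n_b_eff <- if (same_group) length(ib) - 1L else length(ib)
  rho <- n_b_eff / vol
  mean_counts <- counts / (nf * n_a)          # mean B neighbors per A per bin
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(n_bins + 1)]^3)
  g <- mean_counts / (rho * shell_vol)
  structure(list(
    r = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    g = g,
    cn = cumsum(mean_counts),
    edges = edges,
    rho = rho,
    dr = dr,
    n_a = n_a,
    n_b = length(ib),
    n_frames = nf,
    same_group = same_group,
    exclude_intramolecular = exclude_intramolecular
  ), class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("RDF: %d bins, dr = %g A, rho_B = %.6g A^-3\n",
              length(x$r), x$dr, x$rho))
  invisible(x)
}

#' Coordination number at a radius
#'
#' Reads the running coordination number at radius `r` from an
#' [rdf()] result (exact at bin edges, interpolated within a bin).
#'
#' @param rdf_result An `rdf_result`.
#' @param r Radius (Angstrom).
#' @return Mean neighbor count within `r`.
#' @export
coordination_number <- function(rdf_result, r) {
  stats::approx(rdf_result$edges, c(0, rdf_result$cn), xout = r,
                rule = 2)$y
}

#' First minimum of the radial distribution function
#'
#' Finds the first local minimum of the (moving-average smoothed) `g(r)`
#' after the first peak exceeding `min_peak_height`, the conventional outer
#' edge of the first solvation shell, and reports the coordination number
#' there. The peak threshold keeps statistical ripple around g = 1 (an
#' uncorrelated fluid) from being mistaken for a shell.
#'
#' @param rdf_result An `rdf_result` (or a list with `r`, `g`, and
#'   optionally `edges`/`cn` for tabulated curves).
#' @param smooth_window Moving-average window in bins (odd; default 5).
#' @param min_peak_height Minimum smoothed g at the first peak (default
#'   1.05).
#' @return List of class `first_min`: `found` flag, `r_min1` (Angstrom,
#'   `NA` when no shell is detected), `peak_r`, `peak_g`, and
#'   `cn_at_first_min` (`NA` if the input carries no `cn`).
#' @export
first_minimum <- function(rdf_result, smooth_window = 5,
                          min_peak_height = 1.05) {
  g <- rdf_result$g
  r <- rdf_result$r
  if (smooth_window > 1) {
    w <- rep(1 / smooth_window, smooth_window)
    gs <- as.numeric(stats::filter(g, w, sides = 2))
    # keep raw values at the edges the filter cannot reach
    gs[is.na(gs)] <- g[is.na(gs)]
  } else {
    gs <- g
  }
  n <- length(gs)
  no_shell <- structure(list(found = FALSE, r_min1 = NA_real_,
                             peak_r = NA_real_, peak_g = NA_real_,
                             cn_at_first_min = NA_real_),
                        class = "first_min")
  if (n < 3) return(no_shell)
  # shell threshold: at least min_peak_height, and at least 3 sigma above 1
  # where the result carries its own counting statistics (sparse small-r
  # bins of a dilute system are individually noisy)
  thresh <- rep(min_peak_height, n)
  if (!is.null(rdf_result$rho) && !is.null(rdf_result$edges) &&
      !is.null(rdf_result$n_a) && !is.null(rdf_result$n_frames)) {
    shell <- 4 / 3 * pi * diff(rdf_result$edges^3)
    expected <- rdf_result$rho * shell * rdf_result$n_a * rdf_result$n_frames
    sig <- 1 / sqrt(pmax(expected, 1)) / sqrt(max(1, smooth_window))
    thresh <- pmax(thresh, 1 + 3 * sig)
  }
  # first local maximum clearing the shell threshold
  peak <- NA_integer_
  for (i in 2:(n - 1)) {
    if (gs[i] > thresh[i] && gs[i] >= gs[i - 1] && gs[i] >= gs[i + 1]) {
      peak <- i
      break
    }
  }
  if (is.na(peak)) return(no_shell)
  min_i <- NA_integer_
  for (i in (peak + 1):(n - 1)) {
    if (i < 2) next
    if (gs[i] <= gs[i - 1] && gs[i] <= gs[i + 1] && gs[i] < gs[peak]) {
      min_i <- i
      break
    }
  }
  if (is.na(min_i)) return(no_shell)
  cn <- if (!is.null(rdf_result$cn) && !is.null(rdf_result$edges)) {
    coordination_number(rdf_result, r[min_i])
  } else NA_real_
  structure(list(found = TRUE, r_min1 = r[min_i], peak_r = r[peak],
                 peak_g = gs[peak], cn_at_first_min = cn),
            class = "first_min")
}

#' Angular distribution function over site triples
#'
#' Histograms the vertex angle a-b-c over all site triples whose a-b and
#' b-c minimum-image distances pass the cutoffs, corrects the counts by
#' `1/sin(alpha)` (evaluated at bin centers, so the 0/180-degree edges stay
#' finite) to remove the solid-angle measure, and normalizes to unit
#' trapezoid integral over the angle axis.
#'
#' @param traj An `md_trajectory`.
#' @param group_a,group_b,group_c Selections for the outer, vertex, and
#'   outer sites.
#' @param cutoff_ab,cutoff_bc Distance cutoffs (Angstrom, at most half-box).
#' @param bin Bin width in degrees.
#' @param topology Optional topology override.
#' @return Object of class `adf_result`: bin centers `alpha` (degrees),
#'   normalized `density`, raw `counts`, number of `skipped` degenerate
#'   triples.
#' @export
adf <- function(traj, group_a, group_b, group_c, cutoff_ab, cutoff_bc,
                bin = 1, topology = NULL) {
  top <- .traj_topology(traj, topology)
  ia <- .resolve_group(group_a, top)
  ib <- .resolve_group(group_b, top)
  ic <- .resolve_group(group_c, top)
  box <- as.numeric(traj$box)
  half <- min(box) / 2
  if (cutoff_ab > half + 1e-9 || cutoff_bc > half + 1e-9) {
    stop("cutoffs must not exceed half the shortest box edge")
  }
  n_bins <- ceiling(180 / bin)
  edges <- seq(0, 180, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  skipped <- 0L
  for (k in seq_len(n_frames(traj))) {
    pa <- matrix(traj$coords[k, ia, ], ncol = 3)
    pb <- matrix(traj$coords[k, ib, ], ncol = 3)
    pc <- matrix(traj$coords[k, ic, ], ncol = 3)
    dab <- .pair_dist_matrix(pa, pb, box)
    dbc <- .pair_dist_matrix(pb, pc, box)
    dab[outer(ia, ib, "==")] <- NA
    dbc[outer(ib, ic, "==")] <- NA
    pab <- which(dab <= cutoff_ab & dab > 1e-8, arr.ind = TRUE)  # (a, b)
    pbc <- which(dbc <= cutoff_bc & dbc > 1e-8, arr.ind = TRUE)  # (b, c)
    skipped <- skipped + sum(dab < 1e-8, na.rm = TRUE) +
      sum(dbc < 1e-8, na.rm = TRUE)
    if (!nrow(pab) || !nrow(pbc)) next
    # join on the shared vertex b
    sp <- split(pbc[, 2], pbc[, 1])
    bs <- intersect(unique(pab[, 2]), as.integer(names(sp)))
    if (!length(bs)) next
    tri_a <- integer(0); tri_b <- integer(0); tri_c <- integer(0)
    for (b in bs) {
      as_ <- pab[pab[, 2] == b, 1]
      cs_ <- sp[[as.character(b)]]
      grid <- expand.grid(a = as_, c = cs_)
      keep <- ia[grid$a] != ic[grid$c]
      tri_a <- c(tri_a, grid$a[keep])
      tri_b <- c(tri_b, rep(b, sum(keep)))
      tri_c <- c(tri_c, grid$c[keep])
    }
    if (!length(tri_a)) next
    ang <- .angle_at(pa[tri_a, , drop = FALSE], pb[tri_b, , drop = FALSE],
                     pc[tri_c, , drop = FALSE], box)
    idx <- pmin(floor(ang / bin) + 1L, n_bins)
    counts <- counts + tabulate(idx, nbins = n_bins)
  }
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  # solid-angle correction applied at bin centers (finite at 0/180 edges)
  dens <- counts / sin(centers * pi / 180) / bin
  tot <- sum((dens[-1] + dens[-n_bins]) / 2 * diff(centers))
  if (tot > 0) dens <- dens / tot
  structure(list(alpha = centers, density = dens, counts = counts,
                 bin = bin, skipped = skipped),
            class = "adf_result")
}

# ---- combined distribution functions -------------------------------------

# Map a site label to positions within each reference molecule (one atom of
# that label per molecule required), returning a matrix aligned to mol ids.
.ref_site_atoms <- function(top, ref_type, site) {
  idx <- which(top$molecule_type == ref_type & top$site_label == site)
  if (!length(idx)) stop("no atoms with site '", site, "' in type ", ref_type)
  mols <- top$molecule_id[idx]
  if (anyDuplicated(mols)) {
    stop("site '", site, "' is not unique within molecules of type ", ref_type)
  }
  idx[order(mols)]
}

#' Combined distance/angle distribution function
#'
#' Joint 2D histogram of a site-site distance and a three-site angle over
#' matched instances. An instance is a (reference molecule, target atom)
#' pair: labels in `pair` and `triple` equal to `target_site` refer to the
#' matched target atom; all other labels are sites of the reference
#' molecule. Normalized to unit maximum (display convention), with raw
#' counts retained.
#'
#' @param traj An `md_trajectory`.
#' @param ref_type Molecule type of the reference molecules (e.g. `"CAP"`).
#' @param pair Length-2 character vector `(site_1, site_2)` defining the
#'   distance axis.
#' @param triple Length-3 character vector defining the angle axis (vertex
#'   is the middle label).
#' @param target_site The label designating the matched partner atom.
#' @param target_type Optional molecule type restricting target atoms.
#' @param dist_breaks,angle_breaks Histogram breaks (Angstrom / degrees).
#' @param r_max Instances with distance beyond `r_max` are dropped
#'   (defaults to `max(dist_breaks)`).
#' @param topology Optional topology override.
#' @return Object of class `cdf2d_result`: `x` (distance centers), `y`
#'   (angle centers), `density` (unit-maximum), `counts`, axis labels.
#' @export
cdf_dist_angle <- function(traj, ref_type, pair, triple, target_site,
                           target_type = NULL,
                           dist_breaks = seq(0, 8, 0.1),
                           angle_breaks = seq(0, 180, 2.5),
                           r_max = NULL, topology = NULL) {
  top <- .traj_topology(traj, topology)
  if (sum(triple == target_site) + sum(pair == target_site) < 2) {
    stop("pair and triple must share the anchor label '", target_site, "'")
  }
  tgt <- if (is.null(target_type)) which(top$site_label == target_site)
         else which(top$site_label == target_site & top$molecule_type == target_type)
  if (!length(tgt)) stop("no target atoms with site '", target_site, "'")
  ref_sites <- unique(c(pair[pair != target_site], triple[triple != target_site]))
  ref_idx <- lapply(ref_sites, function(s) .ref_site_atoms(top, ref_type, s))
  names(ref_idx) <- ref_sites
  n_ref <- length(ref_idx[[1]])
  box <- as.numeric(traj$box)
  if (is.null(r_max)) r_max <- max(dist_breaks)

  nx <- length(dist_breaks) - 1
  ny <- length(angle_breaks) - 1
  counts <- matrix(0, nx, ny)
  col_pos <- function(k, label, inst_ref, inst_tgt) {
    if (label == target_site) {
      matrix(traj$coords[k, tgt[inst_tgt], ], ncol = 3)
    } else {
      matrix(traj$coords[k, ref_idx[[label]][inst_ref], ], ncol = 3)
    }
  }
  for (k in seq_len(n_frames(traj))) {
    p1 <- matrix(traj$coords[k, ref_idx[[pair[pair != target_site][1]]], ], ncol = 3)
    pt <- matrix(traj$coords[k, tgt, ], ncol = 3)
    dm <- .pair_dist_matrix(p1, pt, box)
    # exclude targets belonging to the reference molecule itself
    ref_site1 <- ref_idx[[pair[pair != target_site][1]]]
    dm[outer(top$molecule_id[ref_site1], top$molecule_id[tgt], "==")] <- NA
    inst <- which(!is.na(dm) & dm <= r_max, arr.ind = TRUE)
    if (!nrow(inst)) next
    dist <- dm[inst]
    a <- col_pos(k, triple[1], inst[, 1], inst[, 2])
    b <- col_pos(k, triple[2], inst[, 1], inst[, 2])
    cc <- col_pos(k, triple[3], inst[, 1], inst[, 2])
    ang <- .angle_at(a, b, cc, box)
    ixd <- findInterval(dist, dist_breaks, rightmost.closed = TRUE)
    ixa <- findInterval(ang, angle_breaks, rightmost.closed = TRUE)
    ok <- ixd >= 1 & ixd <= nx & ixa >= 1 & ixa <= ny
    if (any(ok)) {
      tt <- table(factor(ixd[ok], levels = seq_len(nx)),
                  factor(ixa[ok], levels = seq_len(ny)))
      counts <- counts + unclass(tt)
    }
  }
  if (!sum(counts)) {
    warning("no matched (pair, triple) instances found")
  }
  dens <- if (max(counts) > 0) counts / max(counts) else counts
  structure(list(
    x = (dist_breaks[-1] + dist_breaks[-(nx + 1)]) / 2,
    y = (angle_breaks[-1] + angle_breaks[-(ny + 1)]) / 2,
    density = dens, counts = counts,
    xlab = sprintf("%s-%s distance (A)", pair[1], pair[2]),
    ylab = sprintf("%s-%s-%s angle (deg)", triple[1], triple[2], triple[3])
  ), class = "cdf2d_result")
}

#' Combined distance/distance distribution function
#'
#' Joint histogram of two site-site distances over matched (reference
#' molecule, target molecule) instances: distance A between `pair_a[1]` of
#' the reference and `pair_a[2]` of the target, distance B likewise from
#' `pair_b`.
#'
#' @param traj An `md_trajectory`.
#' @param ref_type,target_type Molecule types of the two molecules.
#' @param pair_a,pair_b Length-2 character vectors
#'   `(reference site, target site)`.
#' @param breaks_a,breaks_b Histogram breaks (Angstrom).
#' @param topology Optional topology override.
#' @return `cdf2d_result` (axis 1 = pair_a distance, axis 2 = pair_b).
#' @export
cdf_dist_dist <- function(traj, ref_type, target_type, pair_a, pair_b,
                          breaks_a = seq(0, 8, 0.1),
                          breaks_b = seq(0, 8, 0.1), topology = NULL) {
  top <- .traj_topology(traj, topology)
  ra <- .ref_site_atoms(top, ref_type, pair_a[1])
  rb <- .ref_site_atoms(top, ref_type, pair_b[1])
  ta <- .ref_site_atoms(top, target_type, pair_a[2])
  tb <- .ref_site_atoms(top, target_type, pair_b[2])
  box <- as.numeric(traj$box)
  nx <- length(breaks_a) - 1
  ny <- length(breaks_b) - 1
  counts <- matrix(0, nx, ny)
  same <- outer(top$molecule_id[ra], top$molecule_id[ta], "==")
  for (k in seq_len(n_frames(traj))) {
    da <- .pair_dist_matrix(matrix(traj$coords[k, ra, ], ncol = 3),
                            matrix(traj$coords[k, ta, ], ncol = 3), box)
    db <- .pair_dist_matrix(matrix(traj$coords[k, rb, ], ncol = 3),
                            matrix(traj$coords[k, tb, ], ncol = 3), box)
    da[same] <- NA
    ixa <- findInterval(da, breaks_a, rightmost.closed = TRUE)
    ixb <- findInterval(db, breaks_b, rightmost.closed = TRUE)
    ok <- !is.na(da) & ixa >= 1 & ixa <= nx & ixb >= 1 & ixb <= ny
    if (any(ok)) {
      tt <- table(factor(ixa[ok], levels = seq_len(nx)),
                  factor(ixb[ok], levels = seq_len(ny)))
      counts <- counts + unclass(tt)
    }
  }
  if (!sum(counts)) warning("no matched instances found")
  dens <- if (max(counts) > 0) counts / max(counts) else counts
  structure(list(
    x = (breaks_a[-1] + breaks_a[-(nx + 1)]) / 2,
    y = (breaks_b[-1] + breaks_b[-(ny + 1)]) / 2,
    density = dens, counts = counts,
    xlab = sprintf("%s-%s distance (A)", pair_a[1], pair_a[2]),
    ylab = sprintf("%s-%s distance (A)", pair_b[1], pair_b[2])
  ), class = "cdf2d_result")
}

#' Spatial distribution function in a molecule-fixed frame
#'
#' For every reference molecule and frame, target positions are expressed
#' in a local frame anchored on three reference sites (origin at anchor 1,
#' x-axis toward anchor 2, anchor 3 fixing the xz half-plane) and
#' accumulated on a cubic voxel grid; densities are averaged over
#' references and frames.
#'
#' @param traj An `md_trajectory`.
#' @param ref_type Molecule type carrying the anchor sites.
#' @param anchors Length-3 character vector of anchor site labels.
#' @param target Target atom selection (indices, labels, or list).
#' @param voxel Voxel edge (Angstrom).
#' @param extent Half-width of the grid (Angstrom) in each direction.
#' @param topology Optional topology override.
#' @return Object of class `sdf_grid`: `density` (3D array, A^-3), voxel
#'   `edges`, `counts`, `n_instances`, and `skipped` (near-collinear anchor
#'   instances dropped).
#' @export
sdf <- function(traj, ref_type, anchors, target, voxel = 0.5, extent = 8,
                topology = NULL) {
  top <- .traj_topology(traj, topology)
  a1 <- .ref_site_atoms(top, ref_type, anchors[1])
  a2 <- .ref_site_atoms(top, ref_type, anchors[2])
  a3 <- .ref_site_atoms(top, ref_type, anchors[3])
  it <- .resolve_group(target, top)
  box <- as.numeric(traj$box)
  n_side <- ceiling(2 * extent / voxel)
  edges <- seq(-extent, -extent + n_side * voxel, by = voxel)
  counts <- array(0, c(n_side, n_side, n_side))
  skipped <- 0L
  n_inst <- 0L
  tgt_mol <- top$molecule_id[it]
  for (k in seq_len(n_frames(traj))) {
    pt <- matrix(traj$coords[k, it, ], ncol = 3)
    for (m in seq_along(a1)) {
      p1 <- traj$coords[k, a1[m], ]
      u <- wrap_displacement(traj$coords[k, a2[m], ] - p1, box)
      w <- wrap_displacement(traj$coords[k, a3[m], ] - p1, box)
      nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
      if (nu < 1e-8 || nw < 1e-8) { skipped <- skipped + 1L; next }
      cosang <- sum(u * w) / (nu * nw)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang < 5 || ang > 175) { skipped <- skipped + 1L; next }
      ex <- u / nu
      wz <- w - ex * sum(w * ex)
      ez <- wz / sqrt(sum(wz^2))
      ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
              ez[3] * ex[1] - ez[1] * ex[3],
              ez[1] * ex[2] - ez[2] * ex[1])
      n_inst <- n_inst + 1L
      d <- wrap_displacement(sweep(pt, 2, p1, "-"), box)
      keep <- tgt_mol != top$molecule_id[a1[m]]
      d <- d[keep, , drop = FALSE]
      loc <- cbind(d %*% ex, d %*% ey, d %*% ez)
      ix <- floor((loc[, 1] + extent) / voxel) + 1L
      iy <- floor((loc[, 2] + extent) / voxel) + 1L
      iz <- floor((loc[, 3] + extent) / voxel) + 1L
      ok <- ix >= 1 & ix <= n_side & iy >= 1 & iy <= n_side &
        iz >= 1 & iz <= n_side
      if (any(ok)) {
        flat <- (iz[ok] - 1L) * n_side * n_side + (iy[ok] - 1L) * n_side + ix[ok]
        tb <- tabulate(flat, nbins = n_side^3)
        counts <- counts + array(tb, dim(counts))
      }
    }
  }
  dens <- if (n_inst > 0) counts / (n_inst * voxel^3) else counts
  structure(list(density = dens, edges = edges, voxel = voxel,
                 counts = counts, n_instances = n_inst, skipped = skipped,
                 anchors = anchors),
            class = "sdf_grid")
}

#' Export an SDF grid as a long-format voxel table
#'
#' @param grid An `sdf_grid`.
#' @param drop_zero Drop empty voxels.
#' @return data.frame with voxel centers x, y, z (Angstrom) and density.
#' @export
sdf_table <- function(grid, drop_zero = TRUE) {
  centers <- (grid$edges[-1] + grid$edges[-length(grid$edges)]) / 2
  df <- expand.grid(x = centers, y = centers, z = centers)
  df$density <- as.vector(aperm(grid$density, c(1, 2, 3)))
  if (drop_zero) df <- df[df$density > 0, ]
  df
}
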