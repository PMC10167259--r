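# Geometric hydrogen-bond detection, per-frame count series, Gaussian
# count statistics, and per-pair percent occupancy.

#' Geometric hydrogen-bond criterion
#'
#' A hydrogen bond D-H...A is counted when the minimum-image H...A distance
#' is below `dmax` and the D-H...A angle at the hydrogen lies inside the
#' (inclusive) window. The distance is hydrogen-acceptor, not
#' donor-acceptor: the first-shell RDF peak between the acid hydroxyl
#' hydrogen and chloride sits at ~2.0 Angstrom, a H...A separation.
#'
#' @param donor,hydrogen,acceptor Site labels; donor and hydrogen are
#'   paired within a molecule, the acceptor belongs to another molecule.
#' @param dmax Maximum H...A distance (Angstrom, > 0).
#' @param angle Length-2 numeric window for the D-H...A angle in degrees,
#'   `0 <= lo < hi <= 180`, endpoints included.
#' @return Object of class `hbond_criterion`.
#' @seealso [hbond_preset()] for the chloride- and oxygen-acceptor windows.
#' @export
hbond_criterion <- function(donor, hydrogen, acceptor, dmax = 3.5,
                            angle = c(120, 180)) {
  if (dmax <= 0) stop("dmax must be positive")
  if (length(angle) != 2 || angle[1] < 0 || angle[2] > 180 ||
      angle[1] >= angle[2]) {
    stop("angle window must satisfy 0 <= lo < hi <= 180")
  }
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                 dmax = dmax, angle = as.numeric(angle)),
            class = "hbond_criterion")
}

#' Hydrogen-bond criterion presets
#'
#' Presets for the two acceptor chemistries of choline-chloride/fatty-acid
#' mixtures, from the combined distance/angle distribution ledger:
#' `cl_acceptor` (chloride accepting from the acid hydroxyl, 105-120
#' degrees within 2.5 Angstrom), `o_acceptor` (hydroxyl oxygen accepting,
#' 150-180 degrees within 2.5 Angstrom), and `loose` (3.5 Angstrom,
#' 120-180 degrees).
#'
#' @param name One of `"cl_acceptor"`, `"o_acceptor"`, `"loose"`.
#' @param donor,hydrogen,acceptor Site labels (defaults: acid hydroxyl
#'   OA-HA donating; acceptor Cl or O by preset).
#' @return An [hbond_criterion()].
#' @export
hbond_preset <- function(name = c("cl_acceptor", "o_acceptor", "loose"),
                         donor = "OA", hydrogen = "HA", acceptor = NULL) {
  name <- match.arg(name)
  switch(name,
    cl_acceptor = hbond_criterion(donor, hydrogen,
                                  if (is.null(acceptor)) "Cl" else acceptor,
                                  dmax = 2.5, angle = c(105, 120)),
    o_acceptor = hbond_criterion(donor, hydrogen,
                                 if (is.null(acceptor)) "O" else acceptor,
                                 dmax = 2.5, angle = c(150, 180)),
    loose = hbond_criterion(donor, hydrogen,
                            if (is.null(acceptor)) "Cl" else acceptor,
                            dmax = 3.5, angle = c(120, 180))
  )
}

# Donor-hydrogen covalent pairs: all (donor atom, hydrogen atom)
# combinations within each molecule.
.donor_h_pairs <- function(top, criterion) {
  don <- which(top$site_label == criterion$donor)
  hyd <- which(top$site_label == criterion$hydrogen)
  if (!length(don) || !length(hyd)) {
    return(matrix(integer(0), 0, 2))
  }
  pairs <- NULL
  hs <- split(hyd, top$molecule_id[hyd])
  for (d in don) {
    h <- hs[[as.character(top$molecule_id[d])]]
    if (length(h)) pairs <- rbind(pairs, cbind(d, h))
  }
  if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs
}

#' Detect hydrogen bonds in one frame
#'
#' Enumerates all intermolecular D-H...A triples meeting the geometric
#' criterion (minimum-image H...A distance strictly below `dmax`, angle in
#' the inclusive window).
#'
#' @param frame An `md_frame` (see [get_frame()]).
#' @param top An `md_topology`.
#' @param criterion An [hbond_criterion()].
#' @return data.frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor` (atom indices), `donor_mol`, `acceptor_mol`, `distance`
#'   (Angstrom), `angle` (degrees).
#' @export
detect_hbonds <- function(frame, top, criterion) {
  box <- as.numeric(frame$box)
  if (criterion$dmax > min(box) / 2 + 1e-9) {
    stop("distance cutoff exceeds half the shortest box edge")
  }
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_mol = integer(0),
                      acceptor_mol = integer(0), distance = numeric(0),
                      angle = numeric(0))
  dh <- .donor_h_pairs(top, criterion)
  acc <- which(top$site_label == criterion$acceptor)
  if (!nrow(dh) || !length(acc)) return(empty)
  p <- frame$positions
  dm <- .pair_dist_matrix(p[dh[, 2], , drop = FALSE],
                          p[acc, , drop = FALSE], box)
  # intramolecular donor/acceptor pairs excluded
  dm[outer(top$molecule_id[dh[, 2]], top$molecule_id[acc], "==")] <- NA
  hit <- which(!is.na(dm) & dm < criterion$dmax, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- dh[hit[, 1], 1]
  hi <- dh[hit[, 1], 2]
  ai <- acc[hit[, 2]]
  ang <- .angle_at(p[di, , drop = FALSE], p[hi, , drop = FALSE],
                   p[ai, , drop = FALSE], box)
  keep <- ang >= criterion$angle[1] & ang <= criterion$angle[2]
  data.frame(donor = di[keep], hydrogen = hi[keep], acceptor = ai[keep],
             donor_mol = top$molecule_id[di[keep]],
             acceptor_mol = top$molecule_id[ai[keep]],
             distance = dm[hit][keep], angle = ang[keep])
}

#' Per-frame hydrogen-bond count series with pair presence matrix
#'
#' Runs [detect_hbonds()] on every frame and tracks, for each unique
#' (donor molecule, acceptor atom) pair, in which frames its bond is
#' present. Each frame's count equals the column sum of the presence
#' matrix by construction.
#'
#' @param traj An `md_trajectory` with a topology.
#' @param criterion An [hbond_criterion()].
#' @param topology Optional topology override.
#' @return Object of class `hbond_series`: integer `counts` per frame and
#'   logical `presence` matrix (pairs x frames, rownames
#'   `"<donor_mol>:<acceptor_atom>"`).
#' @export
hbond_count_series <- function(traj, criterion, topology = NULL) {
  top <- .traj_topology(traj, topology)
  nf <- n_frames(traj)
  if (!nf) stop("trajectory is empty")
  per_frame <- vector("list", nf)
  for (k in seq_len(nf)) {
    hb <- detect_hbonds(get_frame(traj, k), top, criterion)
    per_frame[[k]] <- if (nrow(hb)) {
      unique(paste0(hb$donor_mol, ":", hb$acceptor))
    } else character(0)
  }
  counts <- lengths(per_frame)
  keys <- unique(unlist(per_frame))
  presence <- matrix(FALSE, length(keys), nf,
                     dimnames = list(keys, NULL))
  for (k in seq_len(nf)) presence[per_frame[[k]], k] <- TRUE
  structure(list(counts = counts, presence = presence, n_frames = nf),
            class = "hbond_series")
}

#' @export
print.hbond_series <- function(x, ...) {
  cat(sprintf("hbond series: %d frames, mean count %.2f, %d unique pairs\n",
              x$n_frames, mean(x$counts), nrow(x$presence)))
  invisible(x)
}

#' Gaussian fit to the hydrogen-bond count distribution
#'
#' Fits `F(X) = a/(sigma sqrt(2 pi)) exp(-(X - Xbar)^2 / (2 sigma^2))` to
#' the unit-bin histogram of per-frame counts by nonlinear least squares,
#' initialized at the sample mean and standard deviation. `Xbar` is the
#' average number of hydrogen bonds; both the fitted width `sigma` and the
#' standard error of the mean are reported.
#'
#' @param series An `hbond_series` or a numeric vector of counts
#'   (>= 30 frames required).
#' @return Object of class `hbond_gaussian_fit`: `a`, `mean`, `sigma`,
#'   `se_mean`, `residual` (RSS), `degenerate` flag (TRUE for a
#'   zero-variance series, in which case `mean` is the constant and
#'   `sigma` 0).
#' @export
fit_gaussian_counts <- function(series) {
  counts <- if (inherits(series, "hbond_series")) series$counts else series
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n < 30) stop("at least 30 frames are required for a stable fit")
  if (stats::var(counts) == 0) {
    return(structure(list(a = n, mean = counts[1], sigma = 0,
                          se_mean = 0, residual = 0, degenerate = TRUE),
                     class = "hbond_gaussian_fit"))
  }
  lo <- floor(min(counts)); hi <- ceiling(max(counts))
  x <- lo:hi
  y <- as.numeric(table(factor(round(counts), levels = x)))
  start <- list(a = n, xbar = mean(counts), sigma = stats::sd(counts))
  fit <- minpack.lm::nlsLM(
    y ~ a / (sigma * sqrt(2 * pi)) * exp(-(x - xbar)^2 / (2 * sigma^2)),
    start = start,
    lower = c(a = 1e-8, xbar = lo - 10, sigma = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), mean = unname(cf["xbar"]),
                 sigma = unname(cf["sigma"]),
                 se_mean = unname(cf["sigma"]) / sqrt(n),
                 residual = sum(stats::resid(fit)^2), degenerate = FALSE),
            class = "hbond_gaussian_fit")
}

#' @export
print.hbond_gaussian_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("degenerate fit: constant count %.0f (sigma -> 0)\n", x$mean))
  } else {
    cat(sprintf("Gaussian fit: mean %.3f, sigma %.3f (se of mean %.4f)\n",
                x$mean, x$sigma, x$se_mean))
  }
  invisible(x)
}

#' Per-pair hydrogen-bond percent occupancy
#'
#' For each unique (donor molecule, acceptor atom) pair, the percentage of
#' frames in which its hydrogen bond is present, sorted descending: the
#' persistence of each individual bond over the trajectory.
#'
#' @param series An `hbond_series`.
#' @return data.frame with columns `pair` and `occupancy` (percent).
#' @export
hbond_occupancy <- function(series) {
  if (!nrow(series$presence)) {
    return(data.frame(pair = character(0), occupancy = numeric(0)))
  }
  occ <- 100 * rowMeans(series$presence)
  ord <- order(occ, decreasing = TRUE)
  data.frame(pair = rownames(series$presence)[ord],
             occupancy = unname(occ[ord]))
}
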