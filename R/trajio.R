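#' Orthorhombic simulation box
#'
#' Constructs a periodic, orthorhombic (all angles 90 degrees) simulation box.
#' Only orthorhombic cells are supported; the cubic boxes typical of bulk
#' solvent simulations are a special case.
#'
#' @param lengths Numeric vector of box edge lengths in Angstrom. A single
#'   value is recycled to a cubic box.
#' @return An object of class `sim_box`: a length-3 numeric vector of edge
#'   lengths (Angstrom).
#' @examples
#' simulation_box(20)          # cubic, 20 A
#' simulation_box(c(20, 30, 40))
#' @export
simulation_box <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 1) lengths <- rep(lengths, 3)
  if (length(lengths) != 3) stop("box must have 3 edge lengths")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("box lengths must be positive and finite")
  }
  structure(lengths, class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("orthorhombic box: %.4f x %.4f x %.4f A\n", x[1], x[2], x[3]))
  invisible(x)
}

.box_volume <- function(box) prod(as.numeric(box))

.as_box <- function(box) {
  if (inherits(box, "sim_box")) box else simulation_box(box)
}

#' Molecular topology table
#'
#' A topology assigns each atom a site label (e.g. `HA`, `OA`, `O1`, `Cl`),
#' an element, a molecule id, a molecule type, a partial charge and
#' Lennard-Jones parameters (well depth `D0`, kcal/mol; minimum-energy
#' separation `R0`, Angstrom). Molecule types follow the field's naming for
#' choline-chloride/fatty-acid mixtures: `CH` (choline cation), `CL`
#' (chloride anion), `CAP` (caprylic acid), `LUA` (lauric acid), `WAT`
#' (water), `OTHER`.
#'
#' @param site_label Character vector of per-atom site labels (kept verbatim).
#' @param element Character vector of element symbols.
#' @param molecule_id Integer vector; equal ids group atoms into molecules.
#' @param molecule_type Character vector of molecule type codes.
#' @param charge Numeric partial charges (e).
#' @param d0 Numeric Lennard-Jones well depths (kcal/mol).
#' @param r0 Numeric Lennard-Jones minimum positions (Angstrom).
#' @return A `data.frame` of class `md_topology` with one row per atom and a
#'   derived `mass` column (amu).
#' @export
topology <- function(site_label, element = NULL, molecule_id,
                     molecule_type = "OTHER", charge = 0, d0 = 0, r0 = 0) {
  n <- length(site_label)
  if (is.null(element)) element <- sub("[0-9].*$", "", site_label)
  top <- data.frame(
    site_label = as.character(site_label),
    element = as.character(element),
    molecule_id = as.integer(molecule_id),
    molecule_type = rep_len(as.character(molecule_type), n),
    charge = rep_len(as.numeric(charge), n),
    d0 = rep_len(as.numeric(d0), n),
    r0 = rep_len(as.numeric(r0), n),
    stringsAsFactors = FALSE
  )
  top$mass <- .element_mass(top$element)
  .validate_topology(top)
  class(top) <- c("md_topology", "data.frame")
  top
}

.MOL_TYPES <- c("CAP", "LUA", "CH", "CL", "WAT", "OTHER")

.validate_topology <- function(top) {
  if (any(!is.finite(top$charge))) stop("topology validation: non-finite charge")
  if (any(is.na(top$molecule_id))) stop("topology validation: missing molecule_id")
  bad <- setdiff(unique(top$molecule_type), .MOL_TYPES)
  if (length(bad)) {
    stop("topology validation: unknown molecule_type(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(top)
}

#' @export
print.md_topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d molecules\n",
              nrow(x), length(unique(x$molecule_id))))
  tab <- table(x$molecule_type[!duplicated(x$molecule_id)])
  cat("molecule types:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Count molecules per molecule type
#'
#' @param top An `md_topology`.
#' @return Named integer vector: number of molecules of each type present.
#' @export
molecule_type_counts <- function(top) {
  first <- !duplicated(top$molecule_id)
  tab <- table(top$molecule_type[first])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Select atom indices by site label and/or molecule type
#'
#' @param top An `md_topology`.
#' @param site Character vector of site labels to keep (NULL keeps all).
#' @param type Character vector of molecule types to keep (NULL keeps all).
#' @return Integer vector of atom indices.
#' @export
select_sites <- function(top, site = NULL, type = NULL) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(site)) keep <- keep & top$site_label %in% site
  if (!is.null(type)) keep <- keep & top$molecule_type %in% type
  idx <- which(keep)
  if (!length(idx)) {
    stop("empty selection (site=", paste(site, collapse = ","),
         " type=", paste(type, collapse = ","), ")")
  }
  idx
}

.resolve_group <- function(group, top) {
  if (is.numeric(group)) {
    idx <- as.integer(group)
    if (any(idx < 1L) || any(idx > nrow(top))) stop("atom index out of range")
    if (anyDuplicated(idx)) stop("duplicate atom indices in group")
    return(idx)
  }
  if (is.character(group)) return(select_sites(top, site = group))
  if (is.list(group)) {
    return(select_sites(top, site = group$site, type = group$type))
  }
  stop("group must be atom indices, site labels, or list(site=, type=)")
}

#' Load a site parameter table (charges and Lennard-Jones parameters)
#'
#' The table is CSV or whitespace-separated with (case-insensitive) columns
#' `site_label`, `charge`, `D0`, `R0`.
#'
#' @param path Path to the parameter table.
#' @return data.frame with columns site_label, charge, d0, r0.
#' @export
load_params_table <- function(path) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           strip.white = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  names(tab) <- tolower(names(tab))
  need <- c("site_label", "charge", "d0", "r0")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("parameter table validation: missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab[need]
}

#' Load a topology from a PDB file or a plain topology table
#'
#' For `format = "pdb"`, ATOM/HETATM records provide site labels (atom
#' names), elements, and molecule ids (residue sequence numbers); molecule
#' types are inferred from residue names (`CAP`, `LUA`, `CH`/`CHL`, `CL`,
#' `WAT`/`HOH`/`TIP`/`SPC`, else `OTHER`). Charges and Lennard-Jones
#' parameters are not read from PDB (it has no standard field for them);
#' supply them via `params` (see [load_params_table()]).
#'
#' For `format = "table"`, the file is a CSV with one row per atom and
#' columns `site_label`, `element` (optional), `molecule_id`,
#' `molecule_type`, `charge`, `d0`, `r0` (an optional `index` column must be
#' a permutation of 1..n).
#'
#' @param path File path.
#' @param format `"pdb"` or `"table"`.
#' @param params Optional parameter table (path or data.frame) keyed by
#'   site_label, merged onto PDB-derived topologies.
#' @return An `md_topology`.
#' @export
load_topology <- function(path, format = c("pdb", "table"), params = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("topology file not found: ", path)
  if (format == "pdb") {
    top <- .topology_from_pdb_lines(readLines(path))
  } else {
    tab <- utils::read.csv(path, strip.white = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
    names(tab) <- tolower(names(tab))
    need <- c("site_label", "molecule_id", "molecule_type", "charge", "d0", "r0")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      stop("topology table validation: missing column(s): ",
           paste(miss, collapse = ", "))
    }
    if ("index" %in% names(tab)) {
      idx <- as.integer(tab$index)
      if (anyDuplicated(idx)) {
        stop("topology table validation: duplicate atom index ",
             idx[duplicated(idx)][1])
      }
      tab <- tab[order(idx), ]
    }
    top <- topology(tab$site_label,
                    element = if ("element" %in% names(tab)) tab$element else NULL,
                    molecule_id = tab$molecule_id,
                    molecule_type = tab$molecule_type,
                    charge = tab$charge, d0 = tab$d0, r0 = tab$r0)
  }
  if (!is.null(params)) top <- .apply_params(top, params)
  top
}

.RESNAME_TYPES <- c(CAP = "CAP", LUA = "LUA", CH = "CH", CHL = "CH",
                    CHO = "CH", CL = "CL", CLA = "CL", WAT = "WAT",
                    HOH = "WAT", TIP = "WAT", SPC = "WAT")

.topology_from_pdb_lines <- function(lines) {
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("PDB parse error: no ATOM/HETATM records")
  # stop at first model only
  end1 <- which(startsWith(lines, "ENDMDL"))
  if (length(end1)) {
    keep <- lines[seq_len(end1[1] - 1)]
    rec <- keep[startsWith(keep, "ATOM") | startsWith(keep, "HETATM")]
  }
  parse_one <- function(ln, k) {
    if (nchar(ln) < 54) stop("PDB parse error at line ", k, ": record too short")
    name <- trimws(substr(ln, 13, 16))
    resn <- trimws(substr(ln, 18, 20))
    resi <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
    elem <- trimws(substr(ln, 77, 78))
    if (is.na(resi)) stop("PDB parse error at line ", k, ": bad residue number")
    if (!nzchar(elem)) elem <- sub("[0-9].*$", "", name)
    list(name = name, resn = resn, resi = resi, elem = elem)
  }
  parsed <- lapply(seq_along(rec), function(k) parse_one(rec[k], k))
  resn <- vapply(parsed, `[[`, "", "resn")
  mtype <- .RESNAME_TYPES[toupper(resn)]
  mtype[is.na(mtype)] <- "OTHER"
  topology(
    site_label = vapply(parsed, `[[`, "", "name"),
    element = vapply(parsed, `[[`, "", "elem"),
    molecule_id = vapply(parsed, `[[`, 0L, "resi"),
    molecule_type = unname(mtype)
  )
}

.apply_params <- function(top, params) {
  if (is.character(params)) params <- load_params_table(params)
  names(params) <- tolower(names(params))
  m <- match(top$site_label, params$site_label)
  hit <- !is.na(m)
  top$charge[hit] <- params$charge[m[hit]]
  top$d0[hit] <- params$d0[m[hit]]
  top$r0[hit] <- params$r0[m[hit]]
  .validate_topology(top)
  top
}

#' Trajectory container
#'
#' Holds time-ordered periodic configurations: a coordinate array
#' `[n_frames, n_atoms, 3]` in Angstrom, optional velocities (Angstrom/ps),
#' per-trajectory orthorhombic box, frame times (ps) with uniform spacing,
#' and the associated topology.
#'
#' @param coords Numeric array `[n_frames, n_atoms, 3]` (Angstrom).
#' @param box A [simulation_box()] (or lengths) shared by all frames.
#' @param times Frame times in ps (default `0, dt, 2 dt, ...`).
#' @param dt Timestep in ps (default 1) used when `times` is missing.
#' @param velocities Optional array like `coords`, in Angstrom/ps.
#' @param topology Optional `md_topology` with `n_atoms` rows.
#' @param metadata Free-form list (generators record ground truth here).
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, box, times = NULL, dt = 1,
                          velocities = NULL, topology = NULL,
                          metadata = list()) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be an [n_frames, n_atoms, 3] array")
  }
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  box <- .as_box(box)
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * dt
  if (length(times) != n_frames) stop("times length must equal n_frames")
  if (any(times < 0)) stop("frame times must be non-negative")
  if (n_frames > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    dt <- dts[1]
    if (any(abs(dts - dt) > 1e-9 * max(dt, 1))) {
      stop("frame times must be uniformly spaced (tolerance 1e-9 relative)")
    }
  }
  if (!is.null(velocities) && !identical(dim(velocities), dim(coords))) {
    stop("velocities must have the same dimensions as coords")
  }
  if (!is.null(topology) && nrow(topology) != n_atoms) {
    stop("topology atom count (", nrow(topology),
         ") does not match coordinates (", n_atoms, ")")
  }
  structure(list(coords = coords, box = box, times = as.numeric(times),
                 dt = dt, velocities = velocities, topology = topology,
                 metadata = metadata),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %g ps\n",
              n_frames(x), n_atoms(x), x$dt))
  print(x$box)
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj An `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname md_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame from a trajectory
#'
#' @param traj An `md_trajectory`.
#' @param i Frame index (1-based).
#' @return A list of class `md_frame` with `positions` (n_atoms x 3 matrix),
#'   optional `velocities`, `box`, and `time` (ps).
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  structure(list(
    positions = matrix(traj$coords[i, , ], ncol = 3),
    velocities = if (!is.null(traj$velocities))
      matrix(traj$velocities[i, , ], ncol = 3) else NULL,
    box = traj$box,
    time = traj$times[i]
  ), class = "md_frame")
}

#' Build a single-frame object
#'
#' @param positions n x 3 matrix of coordinates (Angstrom).
#' @param box A [simulation_box()] or edge lengths.
#' @param time Frame time in ps.
#' @param velocities Optional n x 3 matrix (Angstrom/ps).
#' @export
md_frame <- function(positions, box, time = 0, velocities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (time < 0) stop("frame time must be non-negative")
  structure(list(positions = positions, velocities = velocities,
                 box = .as_box(box), time = time), class = "md_frame")
}

# ---- periodic geometry primitives ----------------------------------------

#' Wrap displacement components to the minimum image
#'
#' Maps each displacement component into `(-L/2, L/2]` for an orthorhombic
#' box.
#'
#' @param d Numeric vector/matrix of displacement components; if a matrix,
#'   columns are x, y, z.
#' @param box A [simulation_box()] or edge lengths.
#' @return Wrapped displacements, same shape as `d`.
#' @export
wrap_displacement <- function(d, box) {
  box <- as.numeric(.as_box(box))
  if (is.matrix(d)) {
    for (k in 1:3) {
      d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
      low <- d[, k] <= -box[k] / 2
      d[low, k] <- d[low, k] + box[k]
    }
    return(d)
  }
  d <- d - box * round(d / box)
  low <- d <= -box / 2
  d[low] <- d[low] + box[low]
  d
}

#' Minimum-image displacement between two atoms
#'
#' Returns the minimum-image displacement vector from atom `i` to atom `j`
#' (`r_j - r_i`, wrapped), whose norm is the minimum-image distance.
#'
#' @param frame An `md_frame`.
#' @param i,j Atom indices.
#' @return Length-3 numeric vector (Angstrom), each component in
#'   `(-L/2, L/2]`.
#' @examples
#' f <- md_frame(rbind(c(1, 0, 0), c(19, 0, 0)), box = 20)
#' minimum_image_displacement(f, 1, 2)  # c(-2, 0, 0)
#' @export
minimum_image_displacement <- function(frame, i, j) {
  p <- frame$positions
  if (i < 1 || j < 1 || i > nrow(p) || j > nrow(p)) stop("atom index out of range")
  wrap_displacement(p[j, ] - p[i, ], frame$box)
}

# Minimum-image distance matrix between two position sets (nA x nB).
.pair_dist_matrix <- function(posA, posB, box) {
  box <- as.numeric(.as_box(box))
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(posA[, k], posB[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# Angle (degrees) at vertex b for point triples; stable via atan2.
# a, b, c: n x 3 matrices; displacements taken minimum-image.
.angle_at <- function(a, b, c, box) {
  u <- wrap_displacement(a - b, box)
  v <- wrap_displacement(c - b, box)
  dotp <- rowSums(u * v)
  crossx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  crossy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  crossz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  crossn <- sqrt(crossx^2 + crossy^2 + crossz^2)
  atan2(crossn, dotp) * 180 / pi
}

# ---- extended XYZ I/O -----------------------------------------------------

#' Read a trajectory from extended XYZ or multi-model PDB
#'
#' The extended-XYZ dialect stores, per frame, the atom count, then a
#' comment line carrying `time=<ps>` and `box=<Lx>,<Ly>,<Lz>` (Angstrom),
#' then one `element x y z [vx vy vz]` line per atom. Multi-model PDB uses
#' MODEL/ENDMDL blocks and an optional CRYST1 record for the box.
#'
#' @param path File path.
#' @param format `"xyz"` or `"pdb"`.
#' @param topology Optional `md_topology`; per-frame atom counts are checked
#'   against it.
#' @param box Global box (lengths or [simulation_box()]) used when the file
#'   carries none.
#' @param dt Timestep in ps for formats without times (PDB).
#' @return An `md_trajectory`.
#' @export
load_trajectory <- function(path, format = c("xyz", "pdb"), topology = NULL,
                            box = NULL, dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  if (format == "xyz") {
    .parse_xyz(lines, topology, box)
  } else {
    .parse_pdb_traj(lines, topology, box, dt)
  }
}

.parse_xyz <- function(lines, topology, global_box) {
  pos <- 1L
  frames <- list()
  times <- c()
  boxes <- list()
  vels <- list()
  fidx <- 0L
  n_lines <- length(lines)
  while (pos <= n_lines && nzchar(trimws(lines[pos]))) {
    fidx <- fidx + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat)) stop("XYZ parse error at frame ", fidx, ": bad atom count")
    if (!is.null(topology) && nat != nrow(topology)) {
      stop("XYZ structural error at frame ", fidx, ": ", nat,
           " atoms, topology has ", nrow(topology))
    }
    if (pos + 1L + nat > n_lines + 1L) {
      stop("XYZ structural error at frame ", fidx, ": truncated frame")
    }
    comment <- lines[pos + 1L]
    tm <- .xyz_kv(comment, "time")
    bx <- .xyz_kv(comment, "box")
    times <- c(times, if (is.na(tm[1])) fidx - 1 else tm[1])
    if (is.na(bx[1])) {
      if (is.null(global_box)) {
        stop("XYZ frame ", fidx, " has no box= entry and no global box given")
      }
      boxes[[fidx]] <- as.numeric(.as_box(global_box))
    } else {
      if (length(bx) != 3) stop("XYZ parse error at frame ", fidx, ": bad box=")
      boxes[[fidx]] <- bx
    }
    body <- lines[pos + 1L + seq_len(nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    nf <- lengths(toks)
    if (any(nf < 4)) {
      stop("XYZ parse error at frame ", fidx, ", atom ",
           which(nf < 4)[1], ": expected element + 3 coordinates")
    }
    m <- matrix(NA_real_, nat, 3)
    v <- if (all(nf >= 7)) matrix(NA_real_, nat, 3) else NULL
    for (a in seq_len(nat)) {
      tk <- toks[[a]]
      m[a, ] <- as.numeric(tk[2:4])
      if (!is.null(v)) v[a, ] <- as.numeric(tk[5:7])
    }
    if (any(!is.finite(m))) stop("XYZ parse error at frame ", fidx, ": bad coordinate")
    frames[[fidx]] <- m
    vels[fidx] <- list(v)  # may be NULL; keep list slot
    pos <- pos + 2L + nat
  }
  if (!fidx) stop("XYZ parse error: empty file")
  nat <- nrow(frames[[1]])
  for (k in seq_len(fidx)) {
    if (nrow(frames[[k]]) != nat) {
      stop("XYZ structural error at frame ", k, ": atom count changed")
    }
  }
  b1 <- boxes[[1]]
  for (k in seq_len(fidx)) {
    if (max(abs(boxes[[k]] - b1)) > 1e-9) {
      stop("XYZ structural error at frame ", k,
           ": box changes between frames (only constant boxes supported)")
    }
  }
  coords <- array(0, c(fidx, nat, 3))
  for (k in seq_len(fidx)) coords[k, , ] <- frames[[k]]
  velocities <- NULL
  if (!is.null(vels[[1]])) {
    velocities <- array(0, c(fidx, nat, 3))
    for (k in seq_len(fidx)) velocities[k, , ] <- vels[[k]]
  }
  md_trajectory(coords, box = simulation_box(b1), times = times,
                velocities = velocities, topology = topology)
}

.xyz_kv <- function(comment, key) {
  m <- regmatches(comment,
                  regexpr(paste0(key, "=[^ \t]+"), comment))
  if (!length(m)) return(NA_real_)
  as.numeric(strsplit(sub(paste0(key, "="), "", m), ",")[[1]])
}

.parse_pdb_traj <- function(lines, topology, global_box, dt) {
  cry <- lines[startsWith(lines, "CRYST1")]
  box <- global_box
  if (length(cry)) {
    v <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                      substr(cry[1], 25, 33)))
    if (all(is.finite(v)) && all(v > 0)) box <- v
  }
  if (is.null(box)) stop("PDB trajectory has no CRYST1 and no global box given")
  starts <- which(startsWith(lines, "MODEL"))
  ends <- which(startsWith(lines, "ENDMDL"))
  if (!length(starts)) {
    starts <- 1L
    ends <- length(lines)
  }
  if (length(starts) != length(ends)) stop("PDB parse error: unbalanced MODEL/ENDMDL")
  frames <- list()
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:ends[k]]
    rec <- blk[startsWith(blk, "ATOM") | startsWith(blk, "HETATM")]
    if (!is.null(topology) && length(rec) != nrow(topology)) {
      stop("PDB structural error at frame ", k, ": ", length(rec),
           " atoms, topology has ", nrow(topology))
    }
    m <- matrix(NA_real_, length(rec), 3)
    for (a in seq_along(rec)) {
      m[a, ] <- as.numeric(c(substr(rec[a], 31, 38), substr(rec[a], 39, 46),
                             substr(rec[a], 47, 54)))
    }
    if (any(!is.finite(m))) stop("PDB parse error at frame ", k, ": bad coordinate")
    frames[[k]] <- m
  }
  nat <- nrow(frames[[1]])
  coords <- array(0, c(length(frames), nat, 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  md_trajectory(coords, box = box, dt = dt, topology = topology)
}

#' Write a trajectory as extended XYZ
#'
#' Writes the dialect read by [load_trajectory()]: per frame an atom count,
#' a comment line `time=<ps> box=<Lx>,<Ly>,<Lz>`, then
#' `element x y z [vx vy vz]` records at 8 decimal places (round-trip
#' lossless well below 1e-6 Angstrom).
#'
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(traj, path) {
  elements <- if (!is.null(traj$topology)) traj$topology$element
              else rep("X", n_atoms(traj))
  box <- as.numeric(traj$box)
  con <- file(path, "w")
  on.exit(close(con))
  hasv <- !is.null(traj$velocities)
  for (k in seq_len(n_frames(traj))) {
    writeLines(as.character(n_atoms(traj)), con)
    writeLines(sprintf("time=%.8f box=%.8f,%.8f,%.8f",
                       traj$times[k], box[1], box[2], box[3]), con)
    m <- matrix(traj$coords[k, , ], ncol = 3)
    if (hasv) {
      v <- matrix(traj$velocities[k, , ], ncol = 3)
      writeLines(sprintf("%s %.8f %.8f %.8f %.8f %.8f %.8f", elements,
                         m[, 1], m[, 2], m[, 3], v[, 1], v[, 2], v[, 3]), con)
    } else {
      writeLines(sprintf("%s %.8f %.8f %.8f", elements,
                         m[, 1], m[, 2], m[, 3]), con)
    }
  }
  invisible(path)
}

#' Write an analysis result table as CSV with a commented header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param header Named list written as `# key: value` comment lines.
#' @return Invisibly, `path`.
#' @export
write_result_csv <- function(df, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header)) {
    writeLines(sprintf("# %s: %s", nm,
                       paste(format(header[[nm]], digits = 12), collapse = " ")),
               con)
  }
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
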