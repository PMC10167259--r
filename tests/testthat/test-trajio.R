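test_that("simulation box validates lengths", {
  expect_equal(as.numeric(simulation_box(20)), c(20, 20, 20))
  expect_error(simulation_box(c(1, -2, 3)), "positive")
  expect_error(simulation_box(c(0, 1)), "3 edge")
})

test_that("minimum-image displacement wraps across the boundary", {
  f <- md_frame(rbind(c(1, 0, 0), c(19, 0, 0)), box = 20)
  expect_equal(minimum_image_displacement(f, 1, 2), c(-2, 0, 0))
  expect_equal(sqrt(sum(minimum_image_displacement(f, 1, 2)^2)), 2)
  f2 <- md_frame(rbind(c(5, 5, 5), c(5, 5, 5)), box = 20)
  expect_equal(minimum_image_displacement(f2, 1, 2), c(0, 0, 0))
})

test_that("minimum-image distance matches the 27-image brute force and is symmetric", {
  set.seed(101)
  box <- c(12, 17, 23)
  for (rep in 1:100) {
    p1 <- runif(3) * box
    p2 <- runif(3) * box
    f <- md_frame(rbind(p1, p2), box = box)
    d12 <- minimum_image_displacement(f, 1, 2)
    d21 <- minimum_image_displacement(f, 2, 1)
    expect_equal(sqrt(sum(d12^2)), brute_min_image_dist(p1, p2, box),
                 tolerance = 1e-12)
    expect_equal(d12, -d21)
    expect_lte(sqrt(sum(d12^2)), sqrt(3) / 2 * max(box) + 1e-12)
  }
})

test_that("topology loads from a table and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_label,element,molecule_id,molecule_type,charge,d0,r0",
               "OW,O,1,WAT,-0.834,0.152,3.55",
               "HW1,H,1,WAT,0.417,0.046,0.8",
               "HW2,H,1,WAT,0.417,0.046,0.8"), tmp)
  top <- load_topology(tmp, format = "table")
  expect_equal(nrow(top), 3)
  expect_equal(length(unique(top$molecule_id)), 1)
  expect_equal(molecule_type_counts(top), c(WAT = 1L))

  # missing charge column
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_label,molecule_id,molecule_type,d0,r0",
               "OW,1,WAT,0.152,3.55"), bad)
  expect_error(load_topology(bad, format = "table"), "charge")

  # duplicate atom index
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("index,site_label,molecule_id,molecule_type,charge,d0,r0",
               "1,OW,1,WAT,-0.8,0.1,3.5",
               "1,HW1,1,WAT,0.4,0.05,0.8"), dup)
  expect_error(load_topology(dup, format = "table"), "duplicate")
})

test_that("PDB topology parsing picks up names, residues and side-table parameters", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            1, "OW", "WAT", 1, 0, 0, 0),
    sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            2, "HW1", "WAT", 1, 0.96, 0, 0),
    sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            3, "HW2", "WAT", 1, -0.24, 0.93, 0),
    "END"), tmp)
  ptab <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_label,charge,D0,R0", "OW,-0.834,0.152,3.55",
               "HW1,0.417,0.046,0.8", "HW2,0.417,0.046,0.8"), ptab)
  top <- load_topology(tmp, format = "pdb", params = ptab)
  expect_equal(nrow(top), 3)
  expect_equal(top$molecule_type, rep("WAT", 3))
  expect_equal(top$charge, c(-0.834, 0.417, 0.417))
  expect_equal(sum(top$charge), 0)
})

test_that("toy mixture composition matches the requested HBA:HBD ratio", {
  mix <- gen_toy_des_mixture(n_salt = 70, n_fa = 30, fa_type = "CAP",
                             planted_fraction = 0, seed = 1)
  counts <- molecule_type_counts(mix$topology)
  expect_equal(counts[["CH"]], 70L)
  expect_equal(counts[["CL"]], 70L)
  expect_equal(counts[["CAP"]], 30L)
  mix2 <- gen_toy_des_mixture(n_salt = 30, n_fa = 70, fa_type = "LUA",
                              planted_fraction = 0, seed = 1)
  counts2 <- molecule_type_counts(mix2$topology)
  expect_equal(counts2[["CH"]], 30L)
  expect_equal(counts2[["LUA"]], 70L)
})

test_that("XYZ write/read round-trip is lossless to declared precision", {
  tr <- gen_ideal_gas(10, box = c(20, 25, 30), n_frames = 2, seed = 9, dt = 0.5)
  tmp <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, tmp)
  back <- load_trajectory(tmp, format = "xyz", topology = tr$topology)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-6)
  expect_equal(back$times, tr$times, tolerance = 1e-8)
  expect_equal(as.numeric(back$box), as.numeric(tr$box), tolerance = 1e-8)
  expect_equal(back$dt, 0.5, tolerance = 1e-8)
})

test_that("XYZ reader reports structural errors with the frame index", {
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "time=0 box=20,20,20", "X 1 1 1", "X 2 2 2",
               "1", "time=1 box=20,20,20", "X 1 1 1"), tmp)
  top <- atoms_topology(2)
  expect_error(load_trajectory(tmp, topology = top), "frame 2")
  # no box and no global box
  tmp2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "time=0", "X 1 1 1"), tmp2)
  expect_error(load_trajectory(tmp2), "box")
  expect_equal(n_frames(load_trajectory(tmp2, box = 20)), 1)
})

test_that("trajectory construction enforces uniform, increasing times", {
  co <- array(0, c(3, 1, 3))
  expect_error(md_trajectory(co, box = 10, times = c(0, 1, 1.5)), "uniform")
  expect_error(md_trajectory(co, box = 10, times = c(0, -1, 1)),
               "non-negative|increasing")
  tr <- md_trajectory(co, box = 10, times = c(0, 2, 4))
  expect_equal(tr$dt, 2)
})

test_that("multi-model PDB trajectories load with CRYST1 box", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  atom <- function(i, x) {
    sprintf("ATOM  %5d %-4s %-3s  %4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, "X", "UNK", i, x, 0, 0)
  }
  writeLines(c("CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
               "MODEL     1", atom(1, 1), atom(2, 2), "ENDMDL",
               "MODEL     2", atom(1, 1.5), atom(2, 2.5), "ENDMDL"), tmp)
  tr <- load_trajectory(tmp, format = "pdb")
  expect_equal(n_frames(tr), 2)
  expect_equal(as.numeric(tr$box), c(20, 20, 20))
  expect_equal(tr$coords[2, 1, 1], 1.5)
})
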