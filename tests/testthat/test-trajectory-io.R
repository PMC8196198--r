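make_traj <- function(n_frames = 3, seed = 1, ...) {
  generate_trajectory(synth_config(lattice_nx = 4, lattice_ny = 4,
                                   composition = c(DPPC = 0.5, DLiPC = 0.5),
                                   n_frames = n_frames, order_noise_sigma = 0.2,
                                   seed = seed, ...))
}

test_that("built-in topology matches CHARMM36 conventions", {
  topo <- default_topology()
  dppc <- topo$DPPC
  expect_identical(dppc$role, "phospholipid")
  expect_length(dppc$chain_atoms, 2)
  expect_identical(lengths(dppc$chain_atoms), c(16L, 16L))
  expect_identical(dppc$chain_atoms[[1]][1], "C21")
  expect_identical(dppc$chain_atoms[[2]][16], "C316")
  expect_identical(dppc$phosphate_atom, "P")
  expect_identical(topo$CHOL$sterol_ref_atom, "C3")
  # DLiPC carries two 18-carbon (di-linoleoyl) chains
  expect_identical(lengths(topo$DLiPC$chain_atoms), c(18L, 18L))
})

test_that("topology validation catches schema errors", {
  expect_error(topology_spec(list(CHOL = list(role = "sterol",
                                              sterol_ref_atom = "C3"))),
               "axis")
  expect_error(topology_spec(list(X = list(role = "banana"))), "role")
  expect_error(topology_spec(list(DPPC = list(role = "phospholipid",
    chain_atoms = list(c("C1", "C2", "C3", "C4"))))), "phosphate")
  expect_error(topology_spec(list(DPPC = list(role = "phospholipid",
    chain_atoms = list(c("C1", "C2")), phosphate_atom = "P"))), ">= 4")
})

test_that("topology YAML round-trips through read/write", {
  topo <- default_topology()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_topology(topo, path)
  back <- read_topology(path)
  expect_identical(names(back), names(topo))
  expect_identical(back$DPPC$chain_atoms[[2]], topo$DPPC$chain_atoms[[2]])
  expect_identical(back$CHIM$sterol_axis_atoms, topo$CHIM$sterol_axis_atoms)
})

test_that("multi-frame readers return ordered trajectories", {
  traj <- make_traj(5)
  topo <- attr(traj, "topology")
  gro <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj, gro)
  back <- read_frames(gro, topology = topo)
  expect_length(back, 5)
  times <- vapply(back, function(f) f$time, numeric(1))
  expect_true(all(diff(times) > 0))
  expect_lt(max(abs(back[[5]]$coords - traj[[5]]$coords)), 5e-4)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, pdb)
  back <- read_frames(pdb, topology = topo)
  expect_length(back, 5)
  expect_true(all(diff(vapply(back, function(f) f$time, numeric(1))) > 0))
  expect_lt(max(abs(back[[3]]$coords - traj[[3]]$coords)), 1e-4)
})

test_that("round-tripping many random frames is idempotent within precision", {
  for (s in 1:100) {
    f <- generate_frame(synth_config(lattice_nx = 2, lattice_ny = 2,
                                     composition = c(DPPC = 0.5, DLiPC = 0.5),
                                     order_noise_sigma = runif(1, 0, 0.6),
                                     leaflet_tilt_deg = runif(1, 0, 40),
                                     seed = s),
                        chain_template(n_carbons = 6))
    path <- tempfile(fileext = ".gro")
    write_frame(f, path)
    b1 <- read_frames(path, topology = attr(f, "topology"))[[1]]
    write_frame(b1, path)
    b2 <- read_frames(path, topology = attr(f, "topology"))[[1]]
    unlink(path)
    if (max(abs(b1$coords - b2$coords)) > 0) {
      fail(sprintf("round-trip not idempotent at seed %d", s))
      break
    }
  }
  succeed()
})

test_that("malformed or unsupported inputs are rejected", {
  traj <- make_traj(1)
  gro <- withr::local_tempfile(fileext = ".gro")
  write_frame(traj[[1]], gro)
  # triclinic GRO box
  lines <- readLines(gro)
  lines[length(lines)] <- paste(lines[length(lines)],
                                " 0.00000 0.00000 1.50000")
  tric <- withr::local_tempfile(fileext = ".gro")
  writeLines(lines, tric)
  expect_error(read_frames(tric, topology = attr(traj, "topology")),
               "triclinic")
  # PDB without CRYST1
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_frame(traj[[1]], pdb)
  writeLines(grep("^CRYST1", readLines(pdb), value = TRUE, invert = TRUE),
             pdb)
  expect_error(read_frames(pdb, topology = attr(traj, "topology")), "CRYST1")
  # XTC unsupported; atom-count mismatches caught
  expect_error(read_frames(gro, "traj.xtc"), "XTC")
  small <- generate_frame(synth_config(lattice_nx = 2, lattice_ny = 2,
                                       composition = c(DPPC = 1), seed = 1))
  gro2 <- withr::local_tempfile(fileext = ".gro")
  write_frame(small, gro2)
  expect_error(read_frames(gro, gro2, topology = attr(traj, "topology")),
               "mismatch")
  expect_error(write_frame(traj[[1]], "x.xyz"), "unsupported")
  # species in file but absent from topology
  topo <- topology_spec(list(DPPC = default_topology()$DPPC))
  expect_error(read_frames(gro, topology = topo), "not in topology")
})

test_that("DCD trajectories written by MDAnalysis are read back", {
  py <- Sys.which("python")
  if (py == "") skip("python not on PATH")
  traj <- make_traj(4)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(traj, pdb)
  box <- traj[[1]]$box * 10
  script <- sprintf(
    "import MDAnalysis as mda\nu = mda.Universe(%s)\nw = mda.Writer(%s, u.atoms.n_atoms)\nfor ts in u.trajectory:\n    u.dimensions = [%f, %f, %f, 90, 90, 90]\n    w.write(u.atoms)\nw.close()\n",
    deparse(pdb), deparse(dcd), box[1], box[2], box[3])
  pyfile <- withr::local_tempfile(fileext = ".py")
  writeLines(script, pyfile)
  status <- system2(py, pyfile, stdout = FALSE, stderr = FALSE)
  if (status != 0) skip("MDAnalysis unavailable")
  back <- read_frames(pdb, dcd, topology = attr(traj, "topology"))
  expect_length(back, 4)
  expect_lt(max(abs(back[[4]]$coords - traj[[4]]$coords)), 1e-3)
})

test_that("leaflet assignment is translation-invariant and partitions lipids", {
  f <- generate_frame(synth_config(lattice_nx = 5, lattice_ny = 5,
                                   composition = c(DPPC = 0.6, CHOL = 0.4),
                                   seed = 9))
  lm <- assign_leaflets(f)
  expect_setequal(lm$residue_id, unique(f$atoms$residue_id))
  expect_false(anyDuplicated(lm$residue_id) > 0)
  shifted <- f
  shifted$coords <- wrap_shift(f$coords, c(1.3, -0.7, 3.0), f$box)
  shifted <- bilayer_frame(shifted$coords, f$atoms, f$box,
                           topology = attr(f, "topology"))
  lm2 <- assign_leaflets(shifted)
  expect_identical(lm$leaflet[order(lm$residue_id)],
                   lm2$leaflet[order(lm2$residue_id)])
})

test_that("a reference atom exactly on the midplane goes to the upper leaflet", {
  coords <- rbind(c(1, 1, 2), c(1, 1, 1.8), c(1, 1, 1.6), c(1, 1, 1.4),
                  c(1, 1, 1.2),
                  c(3, 3, 0.5), c(3, 3, 0.7), c(3, 3, 0.9), c(3, 3, 1.1),
                  c(3, 3, 1.3),
                  c(2, 2, 1.25))                # sterol ref at the midplane
  atoms <- data.frame(
    residue_id = c(rep(1, 5), rep(2, 5), 3),
    species = c(rep("DPPC", 10), "CHOL"),
    atom_name = c(rep(c("P", "C1", "C2", "C3", "C4"), 2), "C3"))
  topo <- topology_spec(list(
    DPPC = list(role = "phospholipid",
                chain_atoms = list(c("C1", "C2", "C3", "C4")),
                phosphate_atom = "P"),
    CHOL = list(role = "sterol", sterol_ref_atom = "C3",
                sterol_axis_atoms = c("C17", "C3"))))
  f <- bilayer_frame(coords, atoms, box = c(5, 5, 4), topology = topo)
  lm <- assign_leaflets(f)
  expect_equal(attr(lm, "midplane_z"), 1.25)
  expect_identical(lm$leaflet[lm$residue_id == 3], "upper")
})

test_that("degenerate bilayers are rejected", {
  f <- generate_frame(synth_config(lattice_nx = 3, lattice_ny = 3,
                                   composition = c(DPPC = 1), seed = 2))
  squashed <- f$coords
  squashed[, 3] <- 1                  # all atoms on one plane
  flat <- bilayer_frame(squashed, f$atoms, f$box,
                        topology = attr(f, "topology"))
  expect_error(assign_leaflets(flat), "degenerate")
})
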