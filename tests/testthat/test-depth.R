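# Minimal hand-built frame: phospholipids with phosphates at given z values
# and sterols with explicit reference/axis atoms.
make_depth_frame <- function(p_upper = 2.0, p_lower = 0.4, sterol_z = 1.3,
                             sterol_axis = c(0, 0, 1), box = c(6, 6, 3)) {
  coords <- list(); atoms <- list(); rid <- 0
  add_pl <- function(x, y, zp, inward) {
    rid <<- rid + 1
    coords[[rid]] <<- rbind(c(x, y, zp), c(x, y, zp + inward * 0.2),
                            c(x, y, zp + inward * 0.4),
                            c(x, y, zp + inward * 0.6),
                            c(x, y, zp + inward * 0.8))
    atoms[[rid]] <<- data.frame(residue_id = rid, species = "DPPC",
                                atom_name = c("P", "C1", "C2", "C3", "C4"))
  }
  add_sterol <- function(x, y, z, axis) {
    rid <<- rid + 1
    coords[[rid]] <<- rbind(c(x, y, z), c(x, y, z) - 0.9 * axis)
    atoms[[rid]] <<- data.frame(residue_id = rid, species = "CHOL",
                                atom_name = c("C3", "C17"))
  }
  for (x in c(1, 3, 5)) {
    add_pl(x, 1, p_upper, -1)
    add_pl(x, 3, p_lower, 1)
  }
  add_sterol(2, 2, sterol_z, sterol_axis)
  topo <- topology_spec(list(
    DPPC = list(role = "phospholipid",
                chain_atoms = list(c("C1", "C2", "C3", "C4")),
                phosphate_atom = "P"),
    CHOL = list(role = "sterol", sterol_ref_atom = "C3",
                sterol_axis_atoms = c("C17", "C3"))))
  bilayer_frame(do.call(rbind, coords), do.call(rbind, atoms), box,
                time = 0, topology = topo)
}

test_that("insertion depth is the reference-to-phosphate z difference", {
  f <- make_depth_frame(p_upper = 2.0, sterol_z = 1.3)
  d <- sterol_depth(f, "CHOL")
  expect_equal(d$upper$mean, -0.7, tolerance = 1e-12)
  expect_identical(d$lower$n, 0L)       # reported absent, not an error
  expect_equal(d$pooled$mean, -0.7, tolerance = 1e-12)
})

test_that("depth and tilt are invariant under z-mirroring of the frame", {
  cfg <- synth_config(lattice_nx = 5, lattice_ny = 5,
                      composition = c(DPPC = 0.7, CHIM = 0.3),
                      sterol_depth_nm = -0.55, sterol_tilt_deg = 22,
                      order_noise_sigma = 0.2, n_frames = 4, seed = 12)
  traj <- generate_trajectory(cfg)
  mirrored <- bilayer_trajectory(lapply(traj, function(f) {
    m <- f$coords
    m[, 3] <- f$box[3] - m[, 3]
    bilayer_frame(m, f$atoms, f$box, time = f$time,
                  topology = attr(f, "topology"))
  }))
  d0 <- sterol_depth(traj, "CHIM")
  d1 <- sterol_depth(mirrored, "CHIM")
  expect_equal(d0$pooled$mean, d1$pooled$mean, tolerance = 1e-9)
  t0 <- sterol_tilt(traj, "CHIM")
  t1 <- sterol_tilt(mirrored, "CHIM")
  expect_equal(t0$mean_tilt_deg, t1$mean_tilt_deg, tolerance = 1e-9)
  expect_equal(t0$histogram$density, t1$histogram$density, tolerance = 1e-9)
})

test_that("generator round-trip recovers imposed sterol depth and tilt", {
  cfg <- synth_config(lattice_nx = 6, lattice_ny = 6,
                      composition = c(DPPC = 0.7, CHOL = 0.3),
                      sterol_depth_nm = -0.9, sterol_tilt_deg = 15,
                      seed = 13)
  f <- generate_frame(cfg)
  d <- sterol_depth(f, "CHOL")
  expect_equal(d$pooled$mean, -0.9, tolerance = 0.02)
  tl <- sterol_tilt(f, "CHOL")
  expect_equal(tl$mean_tilt_deg, 15, tolerance = 1)
})

test_that("depth measurements are invariant under rigid z-translation", {
  f <- make_depth_frame()
  g <- bilayer_frame(sweep(f$coords, 2, c(0, 0, 0.6), "+"), f$atoms,
                     f$box + c(0, 0, 1), topology = attr(f, "topology"))
  expect_equal(sterol_depth(f, "CHOL")$upper$mean,
               sterol_depth(g, "CHOL")$upper$mean, tolerance = 1e-12)
})

test_that("upright and flat sterols give 0 and 90 degree tilts", {
  up <- make_depth_frame(sterol_axis = c(0, 0, 1))
  expect_equal(sterol_tilt(up, "CHOL")$mean_tilt_deg, 0, tolerance = 1e-9)
  flat <- make_depth_frame(sterol_axis = c(1, 0, 0))
  expect_equal(sterol_tilt(flat, "CHOL")$mean_tilt_deg, 90, tolerance = 1e-9)
  # misoriented (tailward) axis folds back into [0, 90]
  down <- make_depth_frame(sterol_axis = c(0, 0, -1))
  expect_equal(sterol_tilt(down, "CHOL")$mean_tilt_deg, 0, tolerance = 1e-9)
  degen <- make_depth_frame(sterol_axis = c(0, 0, 0))
  expect_error(sterol_tilt(degen, "CHOL"), "zero-length")
})

test_that("tilt histograms integrate to one", {
  f <- generate_frame(synth_config(lattice_nx = 6, lattice_ny = 6,
                                   composition = c(DPPC = 0.6, CHOL = 0.4),
                                   sterol_tilt_deg = 30, seed = 14))
  tl <- sterol_tilt(f, "CHOL", bin_width_deg = 5)
  expect_equal(sum(tl$histogram$density) * 5, 1, tolerance = 1e-6)
})

test_that("density profiles are normalized number densities", {
  cfg <- synth_config(lattice_nx = 4, lattice_ny = 4,
                      composition = c(DPPC = 0.75, CHOL = 0.25),
                      n_frames = 3, order_noise_sigma = 0.1, seed = 15)
  traj <- generate_trajectory(cfg)
  area <- traj[[1]]$box[1] * traj[[1]]$box[2]
  for (bw in c(0.1, 0.2)) {
    prof <- density_profile(traj, c("P", "C3"), bin_width_nm = bw)
    # integral of density x area recovers the mean atom count per frame
    expect_equal(sum(prof$P) * bw * area, 24, tolerance = 1e-6)
    expect_equal(sum(prof$C3) * bw * area, 8, tolerance = 1e-6)
  }
  # phosphates in a noise-free frame sit at two delta-like planes
  f0 <- generate_frame(synth_config(lattice_nx = 4, lattice_ny = 4,
                                    composition = c(DPPC = 1), seed = 16))
  prof <- density_profile(f0, "P", bin_width_nm = 0.1)
  occupied <- prof$z[prof$P > 0]
  expect_length(occupied, 2)
  expect_equal(sum(prof$P > 0), 2)
})

test_that("uniform random z positions give a flat profile", {
  set.seed(17)
  box <- c(4, 4, 10)
  n <- 4000
  # two phosphate planes to define the midplane, plus uniform test atoms
  coords <- rbind(cbind(1, 1, 8), cbind(1, 3, 2),
                  cbind(runif(n, 0, 4), runif(n, 0, 4), runif(n, 0, 10)))
  atoms <- data.frame(
    residue_id = c(1, 2, seq_len(n) + 2),
    species = c("DPPC", "DPPC", rep("W", n)),
    atom_name = c("P", "P", rep("OW", n)))
  topo <- topology_spec(list(
    DPPC = list(role = "phospholipid",
                chain_atoms = list(c("C1", "C2", "C3", "C4")),
                phosphate_atom = "P")))
  # W is not in the topology on purpose; profile only needs atom names
  f <- bilayer_frame(coords, atoms, box)
  lmtopo <- topology_spec(list(DPPC = topo$DPPC,
                               W = list(role = "sterol",
                                        sterol_ref_atom = "OW",
                                        sterol_axis_atoms = c("OW", "H"))))
  prof <- density_profile(f, "OW", topology = lmtopo, bin_width_nm = 0.5)
  inner <- prof$OW[prof$z > -4.5 & prof$z < 4.5]    # full bins only
  expected <- n / (4 * 4 * 10)
  pois_sd <- sqrt(expected * 0.5 * 16) / (0.5 * 16)
  expect_true(all(abs(inner - expected) < 3 * pois_sd))
})

test_that("profile bin width larger than the box is rejected", {
  f <- make_depth_frame()
  expect_error(density_profile(f, "P", bin_width_nm = 10), "bin width")
  expect_error(density_profile(f, "NOPE"), "not found")
})
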