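# Independent oracles used across the test files. These deliberately avoid
# the package's internal code paths: plain loops, explicit trigonometry.

# Monte-Carlo expectation of the segment order parameter for the generator's
# chain model: each C-C step is the director rotated by N(0, sigma) about a
# random perpendicular axis, and a segment is the sum of two consecutive
# steps; S = E[P2(cos angle-to-director)].
mc_expected_order <- function(sigma, n = 2e5) {
  d <- c(0, 0, 1)
  jitter_step <- function(m) {
    delta <- rnorm(m, 0, sigma); phi <- runif(m, 0, 2 * pi)
    cbind(sin(delta) * cos(phi), sin(delta) * sin(phi), cos(delta))
  }
  seg <- jitter_step(n) + jitter_step(n)
  cosa <- seg[, 3] / sqrt(rowSums(seg^2))
  mean(0.5 * (3 * cosa^2 - 1))
}

# Brute-force per-segment order parameter for one frame: explicit loops over
# lipids, chains and segment pairs; leaflet midplane, tilt and angles all
# recomputed from first principles.
brute_order <- function(frame, species, topology = attr(frame, "topology"),
                        tilt_species = NULL) {
  at <- frame$atoms; xyz <- frame$coords; box <- frame$box
  mi <- function(a, b) {
    d <- b - a
    d - box * round(d / box)
  }
  get_atom <- function(rid, name) {
    xyz[which(at$residue_id == rid & at$atom_name == name), ]
  }
  pl_species <- names(topology)[sapply(topology, function(e)
    e$role == "phospholipid")]
  pz <- c(); prid <- c(); psp <- c()
  for (rid in unique(at$residue_id)) {
    sp <- at$species[match(rid, at$residue_id)]
    if (sp %in% pl_species) {
      pz <- c(pz, get_atom(rid, topology[[sp]]$phosphate_atom)[3])
      prid <- c(prid, rid); psp <- c(psp, sp)
    }
  }
  mid <- mean(pz)
  leaf <- ifelse(pz >= mid, "upper", "lower")
  tilt_vec <- list()
  tsp <- if (is.null(tilt_species)) pl_species else tilt_species
  for (lf in c("upper", "lower")) {
    acc <- c(0, 0, 0)
    inward <- if (lf == "upper") c(0, 0, -1) else c(0, 0, 1)
    for (i in seq_along(prid)) {
      if (leaf[i] != lf || !psp[i] %in% tsp) next
      for (ch in topology[[psp[i]]]$chain_atoms) {
        v <- mi(get_atom(prid[i], ch[1]), get_atom(prid[i], ch[length(ch)]))
        v <- v / sqrt(sum(v^2))
        if (sum(v * inward) < 0) v <- -v
        acc <- acc + v
      }
    }
    tilt_vec[[lf]] <- acc / sqrt(sum(acc^2))
  }
  rids <- prid[psp == species]
  chains <- topology[[species]]$chain_atoms
  n_seg <- max(sapply(chains, length)) - 2
  out <- matrix(NA_real_, length(rids), n_seg)
  for (i in seq_along(rids)) {
    tv <- tilt_vec[[leaf[match(rids[i], prid)]]]
    for (k in seq_len(n_seg)) {
      vals <- c()
      for (ch in chains) {
        if (k > length(ch) - 2) next
        v <- mi(get_atom(rids[i], ch[k]), get_atom(rids[i], ch[k + 2]))
        cosa <- sum(v * tv) / sqrt(sum(v^2))
        vals <- c(vals, 0.5 * (3 * cosa^2 - 1))
      }
      out[i, k] <- mean(vals)
    }
  }
  rownames(out) <- rids
  out
}

# Brute-force neighbor fraction: double loop over lipids with explicit 2D
# minimum-image distances.
brute_neighbor_fraction <- function(frame, center_species, cutoff,
                                    topology = attr(frame, "topology")) {
  lm <- assign_leaflets(frame, topology)
  box <- frame$box
  fracs <- c(); excluded <- 0
  for (i in seq_len(nrow(lm))) {
    if (lm$species[i] != center_species) next
    n_pl <- 0; n_dppc <- 0
    for (j in seq_len(nrow(lm))) {
      if (j == i || lm$leaflet[j] != lm$leaflet[i]) next
      if (lm$role[j] != "phospholipid") next
      dx <- lm$ref_x[j] - lm$ref_x[i]; dx <- dx - box[1] * round(dx / box[1])
      dy <- lm$ref_y[j] - lm$ref_y[i]; dy <- dy - box[2] * round(dy / box[2])
      if (sqrt(dx^2 + dy^2) <= cutoff) {
        n_pl <- n_pl + 1
        if (lm$species[j] == "DPPC") n_dppc <- n_dppc + 1
      }
    }
    if (n_pl == 0) excluded <- excluded + 1
    else fracs <- c(fracs, n_dppc / n_pl)
  }
  list(fraction = mean(fracs), n_excluded = excluded)
}

# Custom frame builder: one single-chain test lipid per supplied direction
# (unit 3-vectors), carbons marching along the direction from z = z0; plus
# pinned reference lipids with vertical chains in both leaflets so that the
# leaflet tilt can be referenced to the z axis via tilt_species = "DPPC".
# All test lipids sit in the upper leaflet.
make_direction_frame <- function(directions, z0 = 6, step = 0.127,
                                 n_pins = 8) {
  n_test <- nrow(directions)
  n_tot <- n_test + n_pins
  nxy <- ceiling(sqrt(n_tot))
  spacing <- 2
  box <- c(nxy * spacing + 4, nxy * spacing + 4, 24)
  coords <- vector("list", n_tot); atoms <- vector("list", n_tot); rid <- 0
  add_lipid <- function(sp, x, y, zp, dir) {
    rid <<- rid + 1
    c1 <- c(x, y, zp - 0.4 * sign(zp - 12))   # chain start just inward of P
    carbons <- t(sapply(0:3, function(i) c1 + i * step * dir))
    coords[[rid]] <<- rbind(c(x, y, zp), carbons)
    atoms[[rid]] <<- data.frame(residue_id = rid, species = sp,
                                atom_name = c("P", "C1", "C2", "C3", "C4"))
  }
  for (i in seq_len(n_tot)) {
    x <- ((i - 1) %% nxy) * spacing + 1
    y <- ((i - 1) %/% nxy) * spacing + 1
    if (i <= n_test) {
      add_lipid("DLiPC", x, y, 18, directions[i, ])
    } else {
      # pins: vertical DPPC chains in both leaflets as the tilt reference
      upper <- i %% 2 == 0
      add_lipid("DPPC", x, y, if (upper) 18 else 6,
                if (upper) c(0, 0, -1) else c(0, 0, 1))
    }
  }
  topo <- topology_spec(list(
    DPPC = list(role = "phospholipid",
                chain_atoms = list(c("C1", "C2", "C3", "C4")),
                phosphate_atom = "P"),
    DLiPC = list(role = "phospholipid",
                 chain_atoms = list(c("C1", "C2", "C3", "C4")),
                 phosphate_atom = "P")))
  bilayer_frame(do.call(rbind, coords), do.call(rbind, atoms), box,
                time = 0, topology = topo)
}

# Random unit vectors, uniform on the sphere.
runif_sphere <- function(n) {
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

# Rigid translation: xy components wrapped back into the box, z left
# unwrapped (a bilayer split across the periodic z boundary is a different
# physical configuration, not a translated one).
wrap_shift <- function(coords, delta, box) {
  out <- sweep(coords, 2, delta, "+")
  out[, 1] <- out[, 1] %% box[1]
  out[, 2] <- out[, 2] %% box[2]
  out
}

# Topology with the synthetic generator's atom naming for extra species.
synth_topology_for_test <- function(n = 16) {
  chains <- list(paste0("C2", seq_len(n)), paste0("C3", seq_len(n)))
  topology_spec(list(
    DPPC = list(role = "phospholipid", chain_atoms = chains,
                phosphate_atom = "P"),
    DLiPC = list(role = "phospholipid", chain_atoms = chains,
                 phosphate_atom = "P")))
}

# Hill curve for generating synthetic isotherms.
hill_curve <- function(c, bmax, k, n) bmax * c^n / (k^n + c^n)
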