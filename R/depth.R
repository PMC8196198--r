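#' Sterol insertion depth
#'
#' Per frame and per leaflet, the insertion depth is the difference between
#' the mean z position of the sterol reference carbon (the carbon bearing the
#' hydroxyl group in cholesterol, or its equivalent in analogs) and the mean
#' phosphate z of the same leaflet's phospholipids. The sign convention is
#' negative toward the bilayer center for both leaflets (lower-leaflet values
#' are z-mirrored before averaging), so a buried sterol has a negative depth.
#' The time average carries a blocking-method standard error
#' ([blocking_se()]); for trajectories shorter than 8 frames the naive
#' standard error is reported and flagged.
#'
#' @param traj a [bilayer_trajectory()] (or single frame).
#' @param species sterol species, e.g. `"CHOL"` or `"CHIM"`.
#' @param topology a [topology_spec()]; defaults to the trajectory's own.
#' @return an object of class `depth_result` with per-leaflet and pooled
#'   depth means, standard errors and per-frame series.
#' @export
sterol_depth <- function(traj, species, topology = NULL) {
  traj <- as_trajectory(traj)
  topology <- resolve_topology(traj, topology)
  if (!species %in% names(topology) || topology[[species]]$role != "sterol")
    stop("`species` must be a sterol in the topology", call. = FALSE)
  series <- list(upper = numeric(0), lower = numeric(0),
                 pooled = numeric(0))
  for (f in traj) {
    leaflets <- assign_leaflets(f, topology)
    vals <- c(upper = NA_real_, lower = NA_real_)
    wts <- c(upper = 0, lower = 0)
    for (leaf in c("upper", "lower")) {
      in_leaf <- leaflets$leaflet == leaf
      pz <- leaflets$ref_z[in_leaf & leaflets$role == "phospholipid"]
      sz <- leaflets$ref_z[in_leaf & leaflets$species == species]
      if (!length(pz))
        stop("degenerate bilayer: no phosphates in the ", leaf, " leaflet",
             call. = FALSE)
      if (!length(sz)) next
      raw <- mean(sz) - mean(pz)
      vals[leaf] <- if (leaf == "upper") raw else -raw
      wts[leaf] <- length(sz)
    }
    series$upper <- c(series$upper, vals[["upper"]])
    series$lower <- c(series$lower, vals[["lower"]])
    present <- !is.na(vals)
    series$pooled <- c(series$pooled, if (any(present))
      sum(vals[present] * wts[present]) / sum(wts[present]) else NA_real_)
  }
  summarize <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(list(mean = NA_real_, se = NA_real_,
                                n = 0L, se_method = "absent"))
    if (length(x) >= 8) {
      b <- blocking_se(x)
      list(mean = mean(x), se = b$se, n = length(x), se_method = "blocking")
    } else {
      list(mean = mean(x),
           se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
           n = length(x), se_method = "naive")
    }
  }
  structure(list(species = species,
                 upper = summarize(series$upper),
                 lower = summarize(series$lower),
                 pooled = summarize(series$pooled),
                 series = series,
                 n_frames = length(traj)),
            class = "depth_result")
}

#' @export
print.depth_result <- function(x, ...) {
  cat(sprintf("Sterol insertion depth (%s), %d frame(s); negative = buried:\n",
              x$species, x$n_frames))
  for (leaf in c("upper", "lower", "pooled")) {
    s <- x[[leaf]]
    if (s$n == 0) cat(sprintf("  %-6s absent\n", leaf))
    else cat(sprintf("  %-6s dz = %+.4f +/- %.4f nm (%s SE)\n", leaf, s$mean,
                     s$se, s$se_method))
  }
  invisible(x)
}

#' Number-density profiles along the bilayer normal
#'
#' Histograms the z positions of named reference-atom classes relative to the
#' per-frame phosphate midplane and normalizes to number density using box
#' area x bin width x frame count, so each profile integrates to the class's
#' mean atom count per frame.
#'
#' @param traj a [bilayer_trajectory()] (or single frame).
#' @param atom_classes character vector of atom classes; either a bare atom
#'   name matched in every species (`"P"`, `"C3"`) or `"SPECIES:ATOM"`
#'   (`"CHOL:C3"`).
#' @param topology a [topology_spec()]; defaults to the trajectory's own.
#' @param bin_width_nm histogram bin width, nm (default 0.1, resolving the
#'   phosphate peaks at typical box heights without starving counts).
#' @return an object of class `density_profile`: a data.frame with column `z`
#'   (bin centers, nm, relative to the phosphate midplane) and one density
#'   column per class (atoms/nm^3).
#' @export
density_profile <- function(traj, atom_classes, topology = NULL,
                            bin_width_nm = 0.1) {
  traj <- as_trajectory(traj)
  topology <- resolve_topology(traj, topology)
  if (bin_width_nm <= 0) stop("bin width must be > 0", call. = FALSE)
  if (bin_width_nm > min(vapply(traj, function(f) f$box[3], 1)))
    stop("bin width exceeds the box height", call. = FALSE)
  select <- function(f, class) {
    if (grepl(":", class, fixed = TRUE)) {
      parts <- strsplit(class, ":", fixed = TRUE)[[1]]
      which(f$atoms$species == parts[1] & f$atoms$atom_name == parts[2])
    } else which(f$atoms$atom_name == class)
  }
  # midplane-relative z per frame and class
  rel <- stats::setNames(vector("list", length(atom_classes)), atom_classes)
  inv_area <- numeric(length(traj))
  for (i in seq_along(traj)) {
    f <- traj[[i]]
    leaflets <- assign_leaflets(f, topology)
    mid <- attr(leaflets, "midplane_z")
    inv_area[i] <- 1 / (f$box[1] * f$box[2])
    for (cl in atom_classes) {
      idx <- select(f, cl)
      if (!length(idx) && i == 1)
        stop("atom class not found in frame: ", cl, call. = FALSE)
      rel[[cl]] <- rbind(rel[[cl]], cbind(f$coords[idx, 3] - mid, i))
    }
  }
  allz <- unlist(lapply(rel, function(m) m[, 1]))
  lo <- floor(min(allz) / bin_width_nm) * bin_width_nm
  hi <- ceiling(max(allz) / bin_width_nm + 1e-9) * bin_width_nm
  breaks <- seq(lo, hi, by = bin_width_nm)
  if (length(breaks) < 2) breaks <- c(lo, lo + bin_width_nm)
  centers <- utils::head(breaks, -1) + bin_width_nm / 2
  out <- data.frame(z = centers)
  for (cl in atom_classes) {
    m <- rel[[cl]]
    b <- findInterval(m[, 1], breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
    dens <- numeric(length(centers))
    acc <- tapply(inv_area[m[, 2]], b, sum)
    dens[as.integer(names(acc))] <- acc / (bin_width_nm * length(traj))
    out[[cl]] <- dens
  }
  structure(out, class = c("density_profile", "data.frame"),
            bin_width_nm = bin_width_nm, n_frames = length(traj))
}

#' @export
plot.density_profile <- function(x, ...) {
  classes <- setdiff(names(x), "z")
  graphics::matplot(x$z, as.matrix(x[classes]), type = "l", lty = 1,
                    xlab = "z - phosphate midplane (nm)",
                    ylab = expression(density ~ (nm^-3)), ...)
  graphics::legend("topright", legend = classes, lty = 1,
                   col = seq_along(classes), bty = "n")
  invisible(x)
}

#' Sterol tilt-angle distribution
#'
#' Per sterol and frame, the tilt is the angle between the sterol ring axis
#' (the vector between the topology's `sterol_axis_atoms`, oriented headward)
#' and the outward leaflet normal, folded into \[0, 90\] degrees. Returns the
#' probability-density histogram, the mean tilt, and a standard error from
#' the blocking method on the per-frame means (naive SE for < 8 frames).
#'
#' @param traj a [bilayer_trajectory()] (or single frame).
#' @param species sterol species.
#' @param topology a [topology_spec()]; defaults to the trajectory's own.
#' @param bin_width_deg histogram bin width, degrees.
#' @return an object of class `tilt_result`.
#' @export
sterol_tilt <- function(traj, species, topology = NULL, bin_width_deg = 2) {
  traj <- as_trajectory(traj)
  topology <- resolve_topology(traj, topology)
  if (!species %in% names(topology) || topology[[species]]$role != "sterol")
    stop("`species` must be a sterol in the topology", call. = FALSE)
  ax <- topology[[species]]$sterol_axis_atoms
  samples <- numeric(0); frame_means <- numeric(0)
  for (f in traj) {
    leaflets <- assign_leaflets(f, topology)
    tail_idx <- chain_index(f, species, ax[1])
    head_idx <- chain_index(f, species, ax[2])
    rids <- as.integer(rownames(tail_idx))
    v <- min_image(f$coords[tail_idx[, 1], , drop = FALSE],
                   f$coords[head_idx[, 1], , drop = FALSE], f$box)
    nv <- sqrt(rowSums(v^2))
    if (any(nv < 1e-9))
      stop("coincident sterol axis atoms give a zero-length axis",
           call. = FALSE)
    leaf <- leaflets$leaflet[match(rids, leaflets$residue_id)]
    outward <- ifelse(leaf == "upper", 1, -1)
    cosa <- pmin(1, pmax(-1, outward * v[, 3] / nv))
    ang <- rad2deg(acos(cosa))
    ang <- ifelse(ang > 90, 180 - ang, ang)
    samples <- c(samples, ang)
    frame_means <- c(frame_means, mean(ang))
  }
  breaks <- seq(0, 90 + bin_width_deg, by = bin_width_deg)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  se <- if (length(frame_means) >= 8) blocking_se(frame_means)$se
        else if (length(frame_means) > 1)
          stats::sd(frame_means) / sqrt(length(frame_means)) else 0
  structure(list(species = species,
                 histogram = data.frame(angle_deg = h$mids,
                                        density = h$density),
                 mean_tilt_deg = mean(samples), se_deg = se,
                 n_samples = length(samples), n_frames = length(traj)),
            class = "tilt_result")
}

#' @export
print.tilt_result <- function(x, ...) {
  cat(sprintf(
    "Sterol tilt (%s): mean %.2f +/- %.2f deg over %d samples, %d frame(s)\n",
    x$species, x$mean_tilt_deg, x$se_deg, x$n_samples, x$n_frames))
  invisible(x)
}

#' @export
plot.tilt_result <- function(x, ...) {
  graphics::plot(x$histogram$angle_deg, x$histogram$density, type = "h",
                 xlab = "tilt (deg)", ylab = "probability density (1/deg)",
                 ...)
  graphics::abline(v = x$mean_tilt_deg, lty = 2)
  invisible(x)
}
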