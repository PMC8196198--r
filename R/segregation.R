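#' Neighbor criterion parameters
#'
#' Neighbors are lipids whose reference atoms (phosphate for phospholipids,
#' reference carbon for sterols) lie within a lateral (xy) minimum-image
#' distance cutoff, by default restricted to the same leaflet. The default
#' 1.0 nm cutoff captures the first coordination shell at typical
#' phospholipid packing.
#'
#' @param cutoff_nm lateral distance cutoff, nm; must be below half the
#'   smaller lateral box edge.
#' @param same_leaflet_only count neighbors within the center's leaflet only.
#' @return an object of class `neighbor_params`.
#' @export
neighbor_params <- function(cutoff_nm = 1.0, same_leaflet_only = TRUE) {
  if (cutoff_nm <= 0) stop("cutoff must be > 0", call. = FALSE)
  structure(list(cutoff_nm = cutoff_nm,
                 same_leaflet_only = isTRUE(same_leaflet_only)),
            class = "neighbor_params")
}

#' Fraction of DPPC neighbors among phospholipid neighbors
#'
#' For each lipid of `center_species`, counts its phospholipid neighbors
#' (sterols never enter the denominator) within the lateral cutoff in the
#' same leaflet and forms the fraction that are DPPC. The frame value is the
#' mean over centers that have at least one phospholipid neighbor; centers
#' with none are excluded and counted in `n_excluded`. Calibration: 0.4 marks
#' random mixing at 40% DPPC among phospholipids, 0.9 complete segregation.
#'
#' @param frame a [bilayer_frame()].
#' @param leaflets a `leaflet_map` from [assign_leaflets()]; recomputed when
#'   `NULL`.
#' @param topology a [topology_spec()]; defaults to the frame's own.
#' @param center_species species around which the neighborhood is evaluated
#'   (`"DPPC"`, `"CHOL"`, `"CHIM"`, ...).
#' @param params a [neighbor_params()].
#' @param target_species the species counted in the numerator (default
#'   `"DPPC"`).
#' @return a list with `fraction` (frame mean), `per_lipid` (data.frame of
#'   per-center counts and fractions), `n_excluded`.
#' @export
neighbor_fraction <- function(frame, leaflets = NULL, topology = NULL,
                              center_species = "DPPC",
                              params = neighbor_params(),
                              target_species = "DPPC") {
  stopifnot(inherits(params, "neighbor_params"))
  topology <- resolve_topology(frame, topology)
  if (is.null(leaflets)) leaflets <- assign_leaflets(frame, topology)
  if (params$cutoff_nm >= min(frame$box[1:2]) / 2)
    stop("cutoff must be below half the lateral box size (minimum image)",
         call. = FALSE)
  if (!center_species %in% leaflets$species)
    stop("center species ", center_species, " absent from frame",
         call. = FALSE)
  res <- list()
  leaves <- if (params$same_leaflet_only) c("upper", "lower") else "all"
  for (leaf in leaves) {
    sub <- if (leaf == "all") leaflets else leaflets[leaflets$leaflet == leaf, ]
    centers <- which(sub$species == center_species)
    if (!length(centers)) next
    is_pl <- sub$role == "phospholipid"
    pl <- which(is_pl)
    if (!length(pl)) next
    d <- lateral_dist(as.matrix(sub[centers, c("ref_x", "ref_y")]),
                      as.matrix(sub[pl, c("ref_x", "ref_y")]), frame$box)
    # a center never counts itself as its own neighbor
    self <- outer(sub$residue_id[centers], sub$residue_id[pl], "==")
    nb <- d <= params$cutoff_nm & !self
    n_pl <- rowSums(nb)
    n_target <- rowSums(nb[, sub$species[pl] == target_species, drop = FALSE])
    res[[leaf]] <- data.frame(residue_id = sub$residue_id[centers],
                              leaflet = if (leaf == "all") sub$leaflet[centers]
                                        else leaf,
                              n_pl_neighbors = n_pl,
                              n_target_neighbors = n_target,
                              fraction = ifelse(n_pl > 0, n_target / n_pl, NA))
  }
  per_lipid <- do.call(rbind, res)
  ok <- !is.na(per_lipid$fraction)
  list(fraction = mean(per_lipid$fraction[ok]),
       per_lipid = per_lipid,
       n_excluded = sum(!ok))
}

#' Segregation time series with tail average and blocking error
#'
#' Computes the per-frame DPPC-neighbor fraction around `center_species`
#' (leaflets reassigned every frame), averages over the last `tail_fraction`
#' of frames, and attaches a blocking-method standard error of that tail
#' mean. Display reference levels follow the calibrations 0.9 (complete
#' segregation) and 0.4 (random mixing at 40% DPPC among phospholipids).
#'
#' @param traj a [bilayer_trajectory()] of length >= 4.
#' @param center_species species around which neighborhoods are evaluated.
#' @param topology a [topology_spec()]; defaults to the trajectory's own.
#' @param params a [neighbor_params()].
#' @param tail_fraction fraction of trailing frames entering the tail mean
#'   (default 0.25).
#' @return an object of class `segregation_series`.
#' @export
segregation_series <- function(traj, center_species = "DPPC",
                               topology = NULL, params = neighbor_params(),
                               tail_fraction = 0.25) {
  traj <- as_trajectory(traj)
  topology <- resolve_topology(traj, topology)
  if (length(traj) < 4)
    stop("segregation series needs >= 4 frames", call. = FALSE)
  if (tail_fraction <= 0 || tail_fraction > 1)
    stop("tail_fraction must be in (0, 1]", call. = FALSE)
  n <- length(traj)
  f_t <- numeric(n); times <- numeric(n); excluded <- integer(n)
  for (i in seq_len(n)) {
    nf <- neighbor_fraction(traj[[i]], topology = topology,
                            center_species = center_species, params = params)
    f_t[i] <- nf$fraction
    excluded[i] <- nf$n_excluded
    times[i] <- traj[[i]]$time
  }
  n_tail <- ceiling(tail_fraction * n)
  tail_idx <- seq(n - n_tail + 1, n)
  tail_vals <- f_t[tail_idx]
  if (n_tail >= 8) {
    b <- blocking_se(tail_vals)
    tail_se <- b$se; se_method <- "blocking"
  } else {
    tail_se <- if (n_tail > 1) stats::sd(tail_vals) / sqrt(n_tail) else 0
    se_method <- "naive"
  }
  structure(list(times = times, f_t = f_t, center_species = center_species,
                 tail_mean = mean(tail_vals), tail_se = tail_se,
                 tail_fraction = tail_fraction, n_tail = n_tail,
                 se_method = se_method, excluded_centers = excluded,
                 ref_segregated = 0.9, ref_random = 0.4,
                 cutoff_nm = params$cutoff_nm),
            class = "segregation_series")
}

#' @export
print.segregation_series <- function(x, ...) {
  cat(sprintf(
    "DPPC-neighbor fraction around %s: %d frames, cutoff %.2f nm\n",
    x$center_species, length(x$f_t), x$cutoff_nm))
  cat(sprintf(
    "  tail mean (last %d frames) = %.4f +/- %.4f (%s SE)\n", x$n_tail,
    x$tail_mean, x$tail_se, x$se_method))
  cat(sprintf("  reference levels: %.1f segregated, %.1f random\n",
              x$ref_segregated, x$ref_random))
  invisible(x)
}

#' @export
plot.segregation_series <- function(x, ...) {
  graphics::plot(x$times, x$f_t, type = "l", ylim = c(0, 1),
                 xlab = "time (ns)",
                 ylab = sprintf("DPPC/PL neighbor fraction around %s",
                                x$center_species), ...)
  graphics::abline(h = c(x$ref_segregated, x$ref_random), lty = 2,
                   col = "grey40")
  graphics::abline(h = x$tail_mean, col = 2)
  invisible(x)
}

#' Blocking-method standard error
#'
#' Flyvbjerg-Petersen blocking: the series is repeatedly pair-averaged; at
#' each level the naive standard error of the blocked series is computed
#' together with its own uncertainty. The reported SE is the plateau value —
#' the first level at which the estimate stops increasing by more than its
#' own uncertainty; if no plateau is reached the maximum over levels is
#' returned and flagged (`plateau_found = FALSE`). For uncorrelated data the
#' result matches the naive standard error; for positively autocorrelated
#' data it converges to the inflated SE implied by the integrated
#' autocorrelation time.
#'
#' @param series numeric vector, length >= 8.
#' @return an object of class `blocking_se`: `se`, `plateau_level`,
#'   `plateau_found`, `naive_se`, and `levels` (a data.frame with the full
#'   block-size curve: level, block size, number of blocks, SE estimate and
#'   its uncertainty).
#' @examples
#' set.seed(1)
#' blocking_se(rnorm(1024))
#' @export
blocking_se <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 8)
    stop("blocking needs a series of length >= 8", call. = FALSE)
  if (anyNA(series)) stop("series contains NA", call. = FALSE)
  x <- series; lev <- 0L; rows <- list()
  while (length(x) >= 4) {
    n <- length(x)
    se <- stats::sd(x) / sqrt(n)
    rows[[lev + 1L]] <- data.frame(level = lev, block_size = 2^lev,
                                   n_blocks = n, se = se,
                                   se_err = se / sqrt(2 * (n - 1)))
    if (n %% 2 == 1) x <- x[-n]
    x <- (x[seq(1, length(x), 2)] + x[seq(2, length(x), 2)]) / 2
    lev <- lev + 1L
  }
  curve <- do.call(rbind, rows)
  plateau <- NA_integer_; found <- FALSE
  for (k in seq_len(nrow(curve) - 1)) {
    if (curve$se[k + 1] <= curve$se[k] + curve$se_err[k]) {
      plateau <- k; found <- TRUE; break
    }
  }
  se <- if (found) max(curve$se[plateau], curve$se[plateau + 1])
        else max(curve$se)
  structure(list(se = se, plateau_level = if (found) plateau else NA_integer_,
                 plateau_found = found, naive_se = curve$se[1],
                 levels = curve),
            class = "blocking_se")
}

#' @export
print.blocking_se <- function(x, ...) {
  cat(sprintf("Blocking SE: %.6g (naive %.6g, plateau %s)\n", x$se,
              x$naive_se,
              if (x$plateau_found) sprintf("at level %d", x$plateau_level)
              else "not reached - max over levels"))
  invisible(x)
}
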