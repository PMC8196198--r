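#' Average leaflet tilt
#'
#' For each leaflet, averages the normalized first-to-last carbon vectors of
#' the selected phospholipid chains (each vector is first oriented to have a
#' positive component along the leaflet's inward normal) and reports the
#' normalized average together with its angle to the bilayer normal (z axis),
#' folded into \[0, 90\] degrees. This average tilt is the reference axis for
#' the chain order parameter.
#'
#' @param frame a [bilayer_frame()].
#' @param leaflets a `leaflet_map` from [assign_leaflets()]; recomputed when
#'   `NULL`.
#' @param topology a [topology_spec()]; defaults to the frame's own.
#' @param species_filter optional character vector restricting the
#'   phospholipid species entering the average.
#' @return a list with entries `upper` and `lower`, each
#'   `list(vector = <unit 3-vector>, angle_deg = <numeric>)`.
#' @export
leaflet_tilt <- function(frame, leaflets = NULL, topology = NULL,
                         species_filter = NULL) {
  topology <- resolve_topology(frame, topology)
  if (is.null(leaflets)) leaflets <- assign_leaflets(frame, topology)
  pls <- species_by_role(topology, "phospholipid")
  if (!is.null(species_filter)) pls <- intersect(pls, species_filter)
  if (!length(pls)) stop("no phospholipid species selected", call. = FALSE)
  out <- list()
  for (leaf in c("upper", "lower")) {
    inward <- if (leaf == "upper") c(0, 0, -1) else c(0, 0, 1)
    vs <- list()
    for (sp in pls) {
      rids <- leaflets$residue_id[leaflets$species == sp &
                                    leaflets$leaflet == leaf]
      if (!length(rids)) next
      for (ch in topology[[sp]]$chain_atoms) {
        idx <- chain_index(frame, sp, ch, rids)
        v <- min_image(frame$coords[idx[, 1], , drop = FALSE],
                       frame$coords[idx[, length(ch)], , drop = FALSE],
                       frame$box)
        v <- normalize_rows(v)
        flip <- (v %*% inward) < 0
        v[flip, ] <- -v[flip, , drop = FALSE]
        vs[[length(vs) + 1]] <- v
      }
    }
    if (!length(vs))
      stop("no phospholipid chains in the ", leaf, " leaflet", call. = FALSE)
    avg <- colMeans(do.call(rbind, vs))
    if (sqrt(sum(avg^2)) < 1e-9)
      stop("degenerate tilt: average chain vector has zero length",
           call. = FALSE)
    avg <- unit(avg)
    out[[leaf]] <- list(vector = avg, angle_deg = rad2deg(acos(min(
      1, abs(avg[3])))))
  }
  out
}

# Atom-index matrix (residue x chain position) for one species' chain.
#' @keywords internal
chain_index <- function(frame, species, chain_atoms, residue_ids = NULL) {
  at <- frame$atoms
  sel <- which(at$species == species & at$atom_name %in% chain_atoms)
  if (!is.null(residue_ids)) sel <- sel[at$residue_id[sel] %in% residue_ids]
  if (!length(sel))
    stop("species ", species, " absent from frame", call. = FALSE)
  rids <- sort(unique(at$residue_id[sel]))
  m <- matrix(NA_integer_, length(rids), length(chain_atoms))
  m[cbind(match(at$residue_id[sel], rids),
          match(at$atom_name[sel], chain_atoms))] <- sel
  if (anyNA(m))
    stop("incomplete chain atoms for species ", species, call. = FALSE)
  rownames(m) <- rids
  m
}

#' Chain order parameter and phase classification
#'
#' Computes the orientational order parameter of the selected phospholipid's
#' acyl chains relative to the same-frame average leaflet tilt. Segment
#' vectors connect every second carbon, i to i+2 (default: all i; set
#' `segment_mode = "stride2"` for the non-overlapping odd subset); alpha is
#' the angle between a segment and its leaflet's average tilt vector, and the
#' per-segment order parameter is the frame average of the second Legendre
#' polynomial (3 cos^2 alpha - 1) / 2 — the universal chain-order convention:
#' 1 for perfect alignment, 0 for isotropic segments, -0.5 perpendicular.
#' Both acyl chains are pooled per lipid; per-lipid values are segment means,
#' and the aggregate is the chosen statistic (default median) across lipids.
#' The bilayer is classified `ordered` when the aggregate strictly exceeds
#' `phase_threshold` (default 0.7), otherwise `disordered`.
#'
#' @param traj a [bilayer_trajectory()] (or single frame).
#' @param species phospholipid species to analyze, e.g. `"DPPC"`.
#' @param topology a [topology_spec()]; defaults to the trajectory's own.
#' @param statistic aggregation across lipids: `"median"` (default) or
#'   `"mean"`; both are always reported in `aggregate_S`.
#' @param phase_threshold ordered/disordered boundary on the aggregate.
#' @param segment_mode `"all"` (segments i to i+2 for every i) or `"stride2"`.
#' @param tilt_species optional species filter for the tilt reference
#'   (default: all phospholipids).
#' @return an object of class `order_result`.
#' @examples
#' traj <- generate_trajectory(synth_config(
#'   composition = c(DPPC = 1), order_noise_sigma = 0.2, n_frames = 3,
#'   seed = 7))
#' compute_order(traj, species = "DPPC")
#' @export
compute_order <- function(traj, species, topology = NULL,
                          statistic = c("median", "mean"),
                          phase_threshold = 0.7,
                          segment_mode = c("all", "stride2"),
                          tilt_species = NULL) {
  statistic <- match.arg(statistic)
  segment_mode <- match.arg(segment_mode)
  traj <- as_trajectory(traj)
  topology <- resolve_topology(traj, topology)
  if (!species %in% names(topology) ||
      topology[[species]]$role != "phospholipid")
    stop("`species` must be a phospholipid in the topology", call. = FALSE)
  chains <- topology[[species]]$chain_atoms
  seg_starts <- lapply(chains, function(ch) {
    n <- length(ch)
    if (n < 3) stop("chain shorter than 3 carbons", call. = FALSE)
    if (segment_mode == "all") seq_len(n - 2) else seq(1, n - 2, by = 2)
  })
  n_seg <- max(vapply(seg_starts, length, 1L))

  first <- traj[[1]]
  if (!species %in% first$atoms$species)
    stop("species ", species, " absent from frame", call. = FALSE)
  rids <- sort(unique(first$atoms$residue_id[first$atoms$species == species]))
  n_lip <- length(rids)
  acc <- matrix(0, n_lip, n_seg)
  cnt <- matrix(0L, n_lip, n_seg)
  tilt_sum <- c(upper = 0, lower = 0)

  for (f in traj) {
    leaflets <- assign_leaflets(f, topology)
    tl <- leaflet_tilt(f, leaflets, topology, species_filter = tilt_species)
    tilt_sum <- tilt_sum + c(tl$upper$angle_deg, tl$lower$angle_deg)
    leaf_of <- stats::setNames(leaflets$leaflet, leaflets$residue_id)
    tilt_mat <- rbind(upper = tl$upper$vector, lower = tl$lower$vector)
    for (ci in seq_along(chains)) {
      idx <- chain_index(f, species, chains[[ci]], rids)
      row_of <- match(as.integer(rownames(idx)), rids)
      tv <- tilt_mat[leaf_of[rownames(idx)], , drop = FALSE]
      for (k in seq_along(seg_starts[[ci]])) {
        s <- seg_starts[[ci]][k]
        v <- min_image(f$coords[idx[, s], , drop = FALSE],
                       f$coords[idx[, s + 2], , drop = FALSE], f$box)
        cosa <- rowSums(v * tv) / sqrt(rowSums(v^2))
        acc[cbind(row_of, k)] <- acc[cbind(row_of, k)] + p2(cosa)
        cnt[cbind(row_of, k)] <- cnt[cbind(row_of, k)] + 1L
      }
    }
  }

  per_segment <- acc / ifelse(cnt > 0, cnt, NA)
  per_lipid <- rowMeans(per_segment, na.rm = TRUE)
  agg <- c(median = stats::median(per_lipid), mean = mean(per_lipid))
  structure(list(
    species = species,
    per_segment_S = structure(per_segment, dimnames = list(rids, NULL)),
    per_lipid_S = stats::setNames(per_lipid, rids),
    aggregate_S = agg,
    statistic = statistic,
    phase = classify_phase(agg[[statistic]], phase_threshold),
    phase_threshold = phase_threshold,
    leaflet_tilt_deg = tilt_sum / length(traj),
    segment_mode = segment_mode,
    n_frames_used = length(traj)),
    class = "order_result")
}

#' Classify bilayer phase from an aggregate order parameter
#'
#' `ordered` when the aggregate order parameter strictly exceeds the
#' threshold, otherwise `disordered` (a value exactly at the threshold is
#' disordered).
#'
#' @param aggregate_S aggregate order parameter, in \[-0.5, 1\].
#' @param threshold phase boundary (default 0.7).
#' @return `"ordered"` or `"disordered"`.
#' @export
classify_phase <- function(aggregate_S, threshold = 0.7) {
  if (!is.finite(aggregate_S) || aggregate_S < -0.5 - 1e-9 ||
      aggregate_S > 1 + 1e-9)
    stop("aggregate_S must lie in [-0.5, 1]", call. = FALSE)
  if (aggregate_S > threshold) "ordered" else "disordered"
}

#' @export
print.order_result <- function(x, ...) {
  cat(sprintf("Chain order parameter: %s over %d lipids, %d frame(s)\n",
              x$species, length(x$per_lipid_S), x$n_frames_used))
  cat(sprintf("  aggregate S: median = %.4f, mean = %.4f (reporting %s)\n",
              x$aggregate_S[["median"]], x$aggregate_S[["mean"]], x$statistic))
  cat(sprintf("  phase: %s (threshold S > %.2f)\n", x$phase, x$phase_threshold))
  cat(sprintf("  leaflet tilt: upper %.2f deg, lower %.2f deg\n",
              x$leaflet_tilt_deg[["upper"]], x$leaflet_tilt_deg[["lower"]]))
  invisible(x)
}

#' @export
plot.order_result <- function(x, ...) {
  s_mean <- colMeans(x$per_segment_S, na.rm = TRUE)
  s_se <- apply(x$per_segment_S, 2, stats::sd, na.rm = TRUE) /
    sqrt(nrow(x$per_segment_S))
  k <- seq_along(s_mean)
  graphics::plot(k, s_mean, type = "b", pch = 16, ylim = c(-0.5, 1),
                 xlab = "segment index", ylab = "S", ...)
  graphics::arrows(k, s_mean - s_se, k, s_mean + s_se, angle = 90, code = 3,
                   length = 0.03)
  graphics::abline(h = x$phase_threshold, lty = 2)
  invisible(x)
}
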