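#' Bilayer frames and trajectories
#'
#' A `bilayer_frame` holds one time point of a planar bilayer: an N x 3
#' coordinate matrix in nm, an orthorhombic box (three edge lengths, nm), and
#' per-atom metadata (`residue_id`, `species`, `atom_name`). The z axis is the
#' bilayer normal. A `bilayer_trajectory` is a list of frames sharing atom
#' order; both may carry a `topology` attribute used as the default topology
#' by the analysis functions.
#'
#' @param coords numeric N x 3 matrix, nm.
#' @param atoms data.frame with columns `residue_id` (integer), `species`
#'   (character residue name), `atom_name` (character).
#' @param box numeric length-3 vector of box edge lengths, nm.
#' @param time frame time in ns, or `NA`.
#' @param topology optional [topology_spec()] attached as the frame's default.
#' @return an object of class `bilayer_frame`.
#' @export
bilayer_frame <- function(coords, atoms, box, time = NA_real_, topology = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) == 0)
    stop("`coords` must be a non-empty N x 3 matrix", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("`box` must be three positive edge lengths (nm)", call. = FALSE)
  need <- c("residue_id", "species", "atom_name")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop("`atoms` needs columns residue_id, species, atom_name", call. = FALSE)
  if (nrow(atoms) != nrow(coords))
    stop("`atoms` and `coords` row counts differ", call. = FALSE)
  structure(
    list(coords = unname(coords),
         atoms = data.frame(residue_id = as.integer(atoms$residue_id),
                            species = as.character(atoms$species),
                            atom_name = as.character(atoms$atom_name)),
         box = as.numeric(box), time = as.numeric(time)),
    class = "bilayer_frame", topology = topology)
}

#' @param frames list of [bilayer_frame()] objects with identical atom tables.
#' @rdname bilayer_frame
#' @export
bilayer_trajectory <- function(frames, topology = NULL) {
  if (length(frames) < 1) stop("a trajectory needs >= 1 frame", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "bilayer_frame")))
    stop("all elements must be bilayer_frame objects", call. = FALSE)
  n <- nrow(frames[[1]]$coords)
  if (!all(vapply(frames, function(f) nrow(f$coords) == n, logical(1))))
    stop("all frames must share the atom count", call. = FALSE)
  topology <- topology %||% attr(frames[[1]], "topology")
  structure(frames, class = "bilayer_trajectory", topology = topology)
}

#' @export
print.bilayer_frame <- function(x, ...) {
  cat(sprintf("Bilayer frame: %d atoms, %d residues, box %.3f x %.3f x %.3f nm",
              nrow(x$coords), length(unique(x$atoms$residue_id)),
              x$box[1], x$box[2], x$box[3]))
  if (is.finite(x$time)) cat(sprintf(", t = %g ns", x$time))
  cat("\n")
  tab <- table(x$atoms$species[!duplicated(x$atoms$residue_id)])
  cat("  composition:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.bilayer_trajectory <- function(x, ...) {
  times <- vapply(x, function(f) f$time, numeric(1))
  cat(sprintf("Bilayer trajectory: %d frames, %d atoms/frame", length(x),
              nrow(x[[1]]$coords)))
  if (all(is.finite(times)))
    cat(sprintf(", t = %g..%g ns", min(times), max(times)))
  cat("\n")
  invisible(x)
}

#' @export
`[.bilayer_trajectory` <- function(x, i) {
  bilayer_trajectory(unclass(x)[i], topology = attr(x, "topology"))
}

# Coerce a single frame to a length-1 trajectory, internal.
#' @keywords internal
as_trajectory <- function(x) {
  if (inherits(x, "bilayer_trajectory")) return(x)
  if (inherits(x, "bilayer_frame"))
    return(bilayer_trajectory(list(x), topology = attr(x, "topology")))
  stop("expected a bilayer_frame or bilayer_trajectory", call. = FALSE)
}

# Resolve the topology for an analysis call, internal.
#' @keywords internal
resolve_topology <- function(x, topology) {
  topo <- topology %||% attr(x, "topology")
  if (is.null(topo))
    stop("no topology: pass `topology` or use frames that carry one",
         call. = FALSE)
  stopifnot(inherits(topo, "topology_spec"))
  missing <- setdiff(unique(if (inherits(x, "bilayer_trajectory"))
    x[[1]]$atoms$species else x$atoms$species), names(topo))
  if (length(missing))
    stop("species missing from topology: ", paste(missing, collapse = ", "),
         call. = FALSE)
  topo
}
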