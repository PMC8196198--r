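#' Assign lipids to bilayer leaflets
#'
#' Splits lipid residues into upper and lower leaflets by the z position of
#' their reference atom relative to the global phosphate midplane: the
#' midplane is the mean phosphate z over all phospholipids, phospholipids are
#' assigned by their phosphate, sterols by their reference carbon. A reference
#' atom exactly on the midplane goes to the upper leaflet (deterministic
#' tie-break). Assignment is per frame, so flip-flop between frames is
#' tolerated. Assignment is invariant under rigid translations of the frame
#' (positions are compared to a midplane computed from the same frame).
#'
#' @param frame a [bilayer_frame()].
#' @param topology a [topology_spec()]; defaults to the frame's own.
#' @return an object of class `leaflet_map`: a data.frame with columns
#'   `residue_id`, `species`, `leaflet` (`"upper"`/`"lower"`), `ref_x`,
#'   `ref_y`, `ref_z` (the reference-atom position, nm), plus attribute
#'   `midplane_z`.
#' @export
assign_leaflets <- function(frame, topology = NULL) {
  stopifnot(inherits(frame, "bilayer_frame"))
  topology <- resolve_topology(frame, topology)
  refs <- reference_atoms(frame, topology)
  is_pl <- refs$role == "phospholipid"
  if (sum(is_pl) < 2)
    stop("leaflet assignment needs at least 2 phospholipids", call. = FALSE)
  midplane <- mean(refs$ref_z[is_pl])
  leaflet <- ifelse(refs$ref_z >= midplane, "upper", "lower")
  if (length(unique(leaflet[is_pl])) < 2)
    stop("degenerate bilayer: all phosphates on one side of the midplane",
         call. = FALSE)
  structure(
    data.frame(residue_id = refs$residue_id, species = refs$species,
               role = refs$role, leaflet = leaflet,
               ref_x = refs$ref_x, ref_y = refs$ref_y, ref_z = refs$ref_z),
    midplane_z = midplane, class = c("leaflet_map", "data.frame"))
}

# One row per lipid residue: its reference atom (phosphate for phospholipids,
# sterol_ref_atom for sterols) and position.
#' @keywords internal
reference_atoms <- function(frame, topology) {
  at <- frame$atoms
  ref_name <- vapply(topology, function(e)
    if (e$role == "phospholipid") e$phosphate_atom else e$sterol_ref_atom,
    character(1))
  role <- vapply(topology, function(e) e$role, character(1))
  keep <- which(at$atom_name == ref_name[at$species])
  if (anyDuplicated(at$residue_id[keep]))
    stop("duplicate reference atoms within a residue", call. = FALSE)
  data.frame(residue_id = at$residue_id[keep],
             species = at$species[keep],
             role = unname(role[at$species[keep]]),
             ref_x = frame$coords[keep, 1],
             ref_y = frame$coords[keep, 2],
             ref_z = frame$coords[keep, 3])
}

#' @export
print.leaflet_map <- function(x, ...) {
  cat(sprintf("Leaflet map: %d lipids, midplane z = %.3f nm\n", nrow(x),
              attr(x, "midplane_z")))
  print(table(x$species, x$leaflet))
  invisible(x)
}
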