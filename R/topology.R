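#' Topology specifications
#'
#' A topology spec maps residue (species) names to their role in the bilayer
#' and to the reference atoms every analysis uses: acyl-chain carbon lists and
#' the phosphate atom for phospholipids; the C3-equivalent reference carbon
#' (the carbon bearing the hydroxyl group in cholesterol, or the corresponding
#' carbon in analogs) and a ring-axis atom pair for sterols.
#'
#' @param species named list; each entry is a list with fields
#'   `role` (`"phospholipid"` or `"sterol"`), and for phospholipids
#'   `chain_atoms` (list of character vectors, one ordered carbon-name list
#'   per acyl chain) and `phosphate_atom`; for sterols `sterol_ref_atom` and
#'   `sterol_axis_atoms` (character vector of two atom names, tail atom first,
#'   head-proximal atom second, so the axis vector points headward).
#' @return an object of class `topology_spec` (a validated named list).
#' @seealso [default_topology()], [read_topology()]
#' @examples
#' topo <- topology_spec(list(
#'   DPPC = list(role = "phospholipid",
#'               chain_atoms = list(paste0("C2", 1:16), paste0("C3", 1:16)),
#'               phosphate_atom = "P"),
#'   CHOL = list(role = "sterol", sterol_ref_atom = "C3",
#'               sterol_axis_atoms = c("C17", "C3"))
#' ))
#' topo
#' @export
topology_spec <- function(species) {
  if (!is.list(species) || is.null(names(species)) || any(names(species) == ""))
    stop("`species` must be a named list of species entries", call. = FALSE)
  for (nm in names(species)) {
    e <- species[[nm]]
    role <- e$role
    if (is.null(role) || !role %in% c("phospholipid", "sterol"))
      stop(sprintf("species %s: role must be 'phospholipid' or 'sterol'", nm),
           call. = FALSE)
    if (role == "phospholipid") {
      if (is.null(e$chain_atoms) || length(e$chain_atoms) < 1)
        stop(sprintf("species %s: phospholipid entry needs chain_atoms", nm),
             call. = FALSE)
      if (!is.list(e$chain_atoms)) e$chain_atoms <- list(e$chain_atoms)
      for (ch in e$chain_atoms)
        if (length(ch) < 4)
          stop(sprintf("species %s: each acyl chain needs >= 4 atoms", nm),
               call. = FALSE)
      if (is.null(e$phosphate_atom))
        stop(sprintf("species %s: phospholipid entry needs phosphate_atom", nm),
             call. = FALSE)
      all_names <- c(unlist(e$chain_atoms), e$phosphate_atom)
    } else {
      if (is.null(e$sterol_ref_atom))
        stop(sprintf("species %s: sterol entry needs sterol_ref_atom", nm),
             call. = FALSE)
      if (is.null(e$sterol_axis_atoms) || length(e$sterol_axis_atoms) != 2 ||
          e$sterol_axis_atoms[1] == e$sterol_axis_atoms[2])
        stop(sprintf("species %s: sterol entry needs two distinct sterol_axis_atoms",
                     nm), call. = FALSE)
      # the reference carbon may itself be an axis endpoint (C3 in sterols)
      all_names <- unique(c(e$sterol_ref_atom, e$sterol_axis_atoms))
    }
    if (anyDuplicated(all_names))
      stop(sprintf("species %s: atom names must be unique within the entry", nm),
           call. = FALSE)
    species[[nm]] <- e
  }
  structure(species, class = "topology_spec")
}

#' Built-in topology for common species
#'
#' CHARMM36-style atom naming: phosphate `P`; palmitoyl/oleoyl/linoleoyl
#' chains `C21...C2n` (sn-2) and `C31...C3n` (sn-1); sterol reference carbon
#' `C3` and ring axis `C17 -> C3` (tail to head).
#'
#' @return a [topology_spec()] covering DPPC, DLiPC, POPS, CHOL and CHIM.
#' @export
default_topology <- function() {
  chains <- function(n2, n3) list(paste0("C2", seq_len(n2)),
                                  paste0("C3", seq_len(n3)))
  sterol <- list(role = "sterol", sterol_ref_atom = "C3",
                 sterol_axis_atoms = c("C17", "C3"))
  topology_spec(list(
    DPPC  = list(role = "phospholipid", chain_atoms = chains(16, 16),
                 phosphate_atom = "P"),
    DLiPC = list(role = "phospholipid", chain_atoms = chains(18, 18),
                 phosphate_atom = "P"),
    POPS  = list(role = "phospholipid", chain_atoms = chains(18, 16),
                 phosphate_atom = "P"),
    CHOL  = sterol,
    CHIM  = sterol
  ))
}

#' Read a topology specification from a YAML file
#'
#' The schema is one mapping per species:
#' ```yaml
#' DPPC:
#'   role: phospholipid
#'   phosphate_atom: P
#'   chain_atoms:
#'     - [C21, C22, ..., C216]
#'     - [C31, C32, ..., C316]
#' CHOL:
#'   role: sterol
#'   sterol_ref_atom: C3
#'   sterol_axis_atoms: [C17, C3]
#' ```
#'
#' @param path YAML file path.
#' @return a validated [topology_spec()].
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path, call. = FALSE)
  topology_spec(yaml::read_yaml(path))
}

#' Write a topology specification to YAML
#'
#' @param topology a [topology_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "topology_spec"))
  yaml::write_yaml(unclass(topology), path)
  invisible(path)
}

#' @export
print.topology_spec <- function(x, ...) {
  cat("Topology spec:", length(x), "species\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    if (e$role == "phospholipid") {
      cat(sprintf("  %-6s phospholipid  %d chain(s) (%s carbons), phosphate '%s'\n",
                  nm, length(e$chain_atoms),
                  paste(vapply(e$chain_atoms, length, 1L), collapse = "+"),
                  e$phosphate_atom))
    } else {
      cat(sprintf("  %-6s sterol        ref '%s', axis %s->%s\n", nm,
                  e$sterol_ref_atom, e$sterol_axis_atoms[1], e$sterol_axis_atoms[2]))
    }
  }
  invisible(x)
}

# species names by role, internal
#' @keywords internal
species_by_role <- function(topology, role) {
  names(topology)[vapply(topology, function(e) e$role == role, logical(1))]
}
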