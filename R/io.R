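#' Coordinate and trajectory I/O
#'
#' Readers and writers for the formats the package understands: GRO
#' (fixed-width, nm; single- or multi-frame), PDB (ATOM records, Angstrom,
#' CRYST1 box; single- or multi-MODEL) and, for reading only, DCD binary
#' trajectories (via bio3d). XTC is not supported: no reader for it exists in
#' the R ecosystem this package builds on; convert XTC to DCD or multi-frame
#' GRO/PDB upstream. All coordinates are stored internally in nm, wrapped into
#' `[0, box)`; only orthorhombic boxes are accepted (planar bilayers with
#' semi-isotropic pressure coupling live in rectangular boxes, and rejecting
#' triclinic cells avoids silent minimum-image errors).
#'
#' @name trajectory-io
NULL

# PDB residue names are at most 4 characters; map the one offender.
.pdb_resname <- c(DLiPC = "DLIP")

#' @keywords internal
species_to_pdb <- function(sp) {
  out <- ifelse(sp %in% names(.pdb_resname), .pdb_resname[sp], sp)
  substr(out, 1, 4)
}

#' @keywords internal
pdb_to_species <- function(res) {
  inv <- stats::setNames(names(.pdb_resname), .pdb_resname)
  ifelse(res %in% names(inv), inv[res], res)
}

#' Write a bilayer frame or trajectory to disk
#'
#' @param frame a [bilayer_frame()].
#' @param path output file path.
#' @param format `"gro"` (nm, 3 decimals) or `"pdb"` (Angstrom, 3 decimals,
#'   CRYST1 box record). Defaults from the file extension.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, format = NULL) {
  stopifnot(inherits(frame, "bilayer_frame"))
  format <- resolve_format(path, format)
  lines <- switch(format,
                  gro = gro_block(frame),
                  pdb = pdb_block(frame, model = NULL))
  if (format == "pdb") lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' @param traj a [bilayer_trajectory()].
#' @rdname write_frame
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  traj <- as_trajectory(traj)
  format <- resolve_format(path, format)
  lines <- switch(format,
    gro = unlist(lapply(traj, gro_block)),
    pdb = c(unlist(lapply(seq_along(traj), function(i)
      pdb_block(traj[[i]], model = i))), "END"))
  writeLines(lines, path)
  invisible(path)
}

#' @keywords internal
resolve_format <- function(path, format) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (!format %in% c("gro", "pdb"))
    stop("unsupported output format: ", format, " (use 'gro' or 'pdb')",
         call. = FALSE)
  format
}

#' @keywords internal
gro_block <- function(frame) {
  n <- nrow(frame$coords)
  title <- sprintf("memblens synthetic/analysis frame%s",
                   if (is.finite(frame$time)) sprintf(", t= %.4f", frame$time)
                   else "")
  at <- frame$atoms
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  at$residue_id %% 100000L, substr(at$species, 1, 5),
                  substr(at$atom_name, 1, 5), seq_len(n) %% 100000L,
                  frame$coords[, 1], frame$coords[, 2], frame$coords[, 3])
  c(title, sprintf("%5d", n), body,
    sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3]))
}

#' @keywords internal
pdb_block <- function(frame, model = NULL) {
  at <- frame$atoms
  xyz <- frame$coords * 10         # nm -> Angstrom
  name4 <- ifelse(nchar(at$atom_name) < 4,
                  sprintf(" %-3s", at$atom_name), substr(at$atom_name, 1, 4))
  body <- sprintf("ATOM  %5d %4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  seq_len(nrow(xyz)) %% 100000L, name4,
                  species_to_pdb(at$species), at$residue_id %% 10000L,
                  xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
  head <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                  frame$box[1] * 10, frame$box[2] * 10, frame$box[3] * 10,
                  90, 90, 90)
  if (is.null(model)) c(head, body)
  else if (model == 1) c(head, sprintf("MODEL     %4d", model), body, "ENDMDL")
  else c(sprintf("MODEL     %4d", model), body, "ENDMDL")
}

#' Read coordinates and an optional trajectory
#'
#' Reads a coordinate file (GRO or PDB) defining the atom order and, if given,
#' a trajectory (multi-frame GRO, multi-MODEL PDB, or DCD) sharing that atom
#' order. Frame times come from `t=` tags in GRO titles when present and are
#' otherwise consecutive integers (ns).
#'
#' @param coord_path coordinate file (.gro or .pdb).
#' @param traj_path optional trajectory file (.gro, .pdb or .dcd).
#' @param topology a [topology_spec()] attached to the result and checked for
#'   coverage of the species found. Default [default_topology()].
#' @return a [bilayer_trajectory()]; length 1 when `traj_path` is `NULL`.
#' @export
read_frames <- function(coord_path, traj_path = NULL,
                        topology = default_topology()) {
  stopifnot(inherits(topology, "topology_spec"))
  first <- read_coord_file(coord_path)
  frames <- first
  if (!is.null(traj_path)) {
    ext <- tolower(tools::file_ext(traj_path))
    if (ext == "xtc")
      stop("XTC trajectories are not supported; convert to DCD or multi-frame ",
           "GRO/PDB", call. = FALSE)
    frames <- if (ext == "dcd")
      read_dcd_frames(traj_path, first[[1]])
    else read_coord_file(traj_path)
    if (nrow(frames[[1]]$atoms) != nrow(first[[1]]$atoms))
      stop("atom count mismatch between coordinate file and trajectory",
           call. = FALSE)
    for (i in seq_along(frames)) frames[[i]]$atoms <- first[[1]]$atoms
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (anyNA(times) || any(diff(times) <= 0))
    for (i in seq_along(frames)) frames[[i]]$time <- i - 1
  found <- unique(frames[[1]]$atoms$species)
  missing <- setdiff(found, names(topology))
  if (length(missing))
    stop("species not in topology: ", paste(missing, collapse = ", "),
         call. = FALSE)
  bilayer_trajectory(frames, topology = topology)
}

#' @keywords internal
read_coord_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gro = read_gro_frames(path),
         pdb = read_pdb_frames(path),
         stop("unsupported coordinate format: .", ext, call. = FALSE))
}

#' @keywords internal
read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i + 1]))) break
    n <- as.integer(trimws(lines[i + 1]))
    title <- lines[i]
    body <- lines[i + 1 + seq_len(n)]
    boxline <- as.numeric(strsplit(trimws(lines[i + 2 + n]), "\\s+")[[1]])
    if (length(boxline) > 3 && any(abs(boxline[-(1:3)]) > 1e-9))
      stop("triclinic box not supported (off-diagonal components present)",
           call. = FALSE)
    coords <- cbind(as.numeric(substr(body, 21, 28)),
                    as.numeric(substr(body, 29, 36)),
                    as.numeric(substr(body, 37, 44)))
    tm <- regmatches(title, regexpr("t=\\s*[0-9eE.+-]+", title))
    tm <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    frames[[length(frames) + 1]] <- bilayer_frame(
      wrap_coords(coords, boxline[1:3]),
      data.frame(residue_id = as.integer(substr(body, 1, 5)),
                 species = trimws(substr(body, 6, 10)),
                 atom_name = trimws(substr(body, 11, 15))),
      boxline[1:3], time = tm)
    i <- i + n + 3
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  frames
}

#' @keywords internal
read_pdb_frames <- function(path) {
  cryst <- grep("^CRYST1", readLines(path, n = 500), value = TRUE)
  if (!length(cryst))
    stop("PDB file lacks a CRYST1 box record: ", path, call. = FALSE)
  box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33))) / 10
  angles <- as.numeric(c(substr(cryst[1], 34, 40), substr(cryst[1], 41, 47),
                         substr(cryst[1], 48, 54)))
  if (any(abs(angles - 90) > 1e-3))
    stop("triclinic box not supported (cell angles differ from 90 degrees)",
         call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- pdb$atom$type == "ATOM"
  atoms <- data.frame(residue_id = as.integer(pdb$atom$resno[sel]),
                      species = pdb_to_species(pdb$atom$resid[sel]),
                      atom_name = pdb$atom$elety[sel])
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(k) {
    m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)[sel, , drop = FALSE] / 10
    bilayer_frame(wrap_coords(m, box), atoms, box, time = NA_real_)
  })
}

#' @keywords internal
read_dcd_frames <- function(path, template_frame) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  lapply(seq_len(nrow(xyz)), function(k) {
    has_cell <- !is.null(cell) && any(abs(as.numeric(cell[k, ])) > 1e-9)
    box <- if (has_cell) as.numeric(cell[k, 1:3]) / 10
           else template_frame$box
    if (has_cell && any(abs(as.numeric(cell[k, 4:6]) - 90) > 1e-3))
      stop("triclinic box not supported in DCD frame ", k, call. = FALSE)
    m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
    bilayer_frame(wrap_coords(m, box), template_frame$atoms, box,
                  time = NA_real_)
  })
}
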