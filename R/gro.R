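#' Read a GRO coordinate file
#'
#' Parses the fixed-column GROMACS GRO layout (resid 1-5, resname 6-10,
#' atom name 11-15, atom number 16-20, then three 8.3f coordinates in nm) and
#' converts coordinates and box to Angstrom. Molecules are grouped by residue
#' number; species labels come from residue names. Velocities, if present, are
#' ignored. Only orthorhombic boxes are supported: a box line with non-zero
#' off-diagonal elements is rejected.
#'
#' @param path Path to a `.gro` file.
#' @param topology Named list of [cg_topology()] objects covering every residue
#'   name in the file.
#' @param time Frame time in ns (GRO files carry no reliable time field;
#'   a `t=` token in the title line is used when present).
#' @return A [cg_frame()].
#' @export
read_gro <- function(path, topology, time = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("GRO format error: file too short (", path, ")", call. = FALSE)
  title <- lines[1]
  n_atoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n_atoms) || n_atoms < 1) {
    stop("GRO format error: bad atom count on line 2", call. = FALSE)
  }
  if (length(lines) < 3 + n_atoms) {
    stop(sprintf(
      "GRO parse error: expected %d atom lines plus a box line, file ends at line %d",
      n_atoms, length(lines)), call. = FALSE)
  }
  atom_lines <- lines[3:(2 + n_atoms)]
  box_line <- trimws(lines[3 + n_atoms])
  if (!nzchar(box_line)) stop("GRO format error: missing box line", call. = FALSE)

  resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
  resname <- trimws(substr(atom_lines, 6, 10))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop(sprintf("GRO parse error: malformed fixed-width atom record at line %d",
                 bad[1] + 2), call. = FALSE)
  }

  box_vals <- suppressWarnings(as.numeric(strsplit(box_line, "[[:space:]]+")[[1]]))
  if (anyNA(box_vals) || length(box_vals) < 3) {
    stop("GRO format error: malformed box line", call. = FALSE)
  }
  if (length(box_vals) > 3 && any(abs(box_vals[-(1:3)]) > 1e-9)) {
    stop("unsupported format: triclinic box (only orthorhombic cells are supported)",
         call. = FALSE)
  }

  # residue numbers wrap at 100000 in GRO; treat changes as molecule boundaries
  new_mol <- c(TRUE, resid[-1] != resid[-n_atoms])
  mol_id <- cumsum(new_mol)
  species <- resname[new_mol]

  if (is.null(time)) {
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(m)) as.numeric(sub("t=\\s*", "", m)) else 0
  }

  cg_frame(
    coords = cbind(x, y, z) * 10,  # nm -> Angstrom
    box = cg_box(box_vals[1:3] * 10),
    mol_id = mol_id, species = species, topology = topology, time = time
  )
}

#' Write a frame to a GRO coordinate file
#'
#' Coordinates and box are converted from the internal Angstrom representation
#' to nm with the standard 8.3f precision. Bead and species names longer than
#' five characters are truncated with a warning.
#'
#' @param frame A [cg_frame()].
#' @param path Output path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, title = NULL) {
  stopifnot(inherits(frame, "cg_frame"))
  n <- nrow(frame$coords)
  resname <- frame$species[frame$mol_id]
  atname <- frame$bead_name
  if (any(nchar(atname) > 5) || any(nchar(resname) > 5)) {
    warning("names longer than 5 characters truncated in GRO output")
    atname <- substr(atname, 1, 5)
    resname <- substr(resname, 1, 5)
  }
  if (is.null(title)) title <- sprintf("aggsurf frame t= %.6f", frame$time)
  nm <- frame$coords / 10
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  frame$mol_id %% 100000L, resname, atname,
                  seq_len(n) %% 100000L, nm[, 1], nm[, 2], nm[, 3])
  box <- sprintf("%10.5f%10.5f%10.5f",
                 frame$box[1] / 10, frame$box[2] / 10, frame$box[3] / 10)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, sprintf("%5d", n), body, box), con)
  invisible(path)
}

#' Write a trajectory to a self-describing JSON container
#'
#' A plain-text fixture format for multi-frame trajectories: frame times, box,
#' flattened coordinates, molecule map and species labels, with the topology
#' (bead names, roles, size classes, masses, sigmas) embedded so the file is
#' self-contained.
#'
#' @param traj A [cg_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  f1 <- traj$frames[[1]]
  topo <- lapply(f1$topology, function(tp) {
    list(name = tp$name, surfactant = tp$surfactant, beads = tp$beads)
  })
  frames <- lapply(traj$frames, function(fr) {
    list(time = fr$time, box = as.numeric(fr$box),
         coords = as.numeric(t(fr$coords)),
         mol_id = fr$mol_id, species = fr$species)
  })
  obj <- list(format = "aggsurf-trajectory", version = 1L,
              units = list(length = "Angstrom", time = "ns"),
              topology = topo, frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory from the JSON container written by [write_trajectory_json()]
#'
#' @param path Path to the JSON trajectory file.
#' @return A [cg_trajectory()].
#' @export
read_trajectory_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "aggsurf-trajectory")) {
    stop("not an aggsurf trajectory container: ", path, call. = FALSE)
  }
  topology <- lapply(obj$topology, function(tp) {
    beads <- lapply(seq_len(nrow(tp$beads)), function(i) {
      b <- tp$beads[i, ]
      bead_spec(b$name, b$size_class, b$role, mass = b$mass, sigma = b$sigma)
    })
    cg_topology(tp$name, beads, surfactant = tp$surfactant)
  })
  names(topology) <- vapply(topology, `[[`, character(1), "name")
  frames <- lapply(seq_len(nrow_or_len(obj$frames)), function(i) {
    fr <- frame_record(obj$frames, i)
    cg_frame(matrix(fr$coords, ncol = 3, byrow = TRUE), cg_box(fr$box),
             fr$mol_id, fr$species, topology, time = fr$time)
  })
  cg_trajectory(frames)
}

# jsonlite simplifies a list of homogeneous records to a data.frame; support both
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
frame_record <- function(x, i) {
  if (is.data.frame(x)) {
    list(time = x$time[i], box = x$box[[i]], coords = x$coords[[i]],
         mol_id = x$mol_id[[i]], species = x$species[[i]])
  } else {
    x[[i]]
  }
}
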