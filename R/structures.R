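#' Orthorhombic periodic box
#'
#' @param lx,ly,lz Box edge lengths in Angstrom; all must be positive. A single
#'   numeric vector of length 3 may be given as `lx`.
#' @return A numeric vector of length 3 with class `"cg_box"`.
#' @export
#' @examples
#' cg_box(100, 100, 150)
cg_box <- function(lx, ly = NULL, lz = NULL) {
  if (is.null(ly) && is.null(lz) && length(lx) == 3) {
    v <- as.numeric(lx)
  } else {
    v <- as.numeric(c(lx, ly, lz))
  }
  if (length(v) != 3 || anyNA(v) || any(v <= 0)) {
    stop("box must be three positive edge lengths (Angstrom)", call. = FALSE)
  }
  structure(v, class = "cg_box")
}

#' @export
print.cg_box <- function(x, ...) {
  cat(sprintf("<orthorhombic box %.2f x %.2f x %.2f Angstrom>\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Declare one coarse-grained bead
#'
#' Mass and sigma default to the bundled size-class constants
#' ([bead_class_table()]) and can be overridden per bead.
#'
#' @param name Bead label (<= 5 characters survive GRO round trips).
#' @param size_class One of `"R"`, `"S"`, `"T"`.
#' @param role One of `"head"`, `"tail"`, `"other"`.
#' @param mass Bead mass in amu; defaults from the size class.
#' @param sigma Lennard-Jones sigma in Angstrom; defaults from the size class.
#' @return A list with class `"bead_spec"`.
#' @export
#' @examples
#' bead_spec("T1", "R", "tail")
bead_spec <- function(name, size_class, role = c("other", "head", "tail"),
                      mass = NULL, sigma = NULL) {
  role <- match.arg(role)
  defaults <- .bead_class_lookup(size_class)
  mass <- if (is.null(mass)) defaults$mass else as.numeric(mass)
  sigma <- if (is.null(sigma)) defaults$sigma else as.numeric(sigma)
  if (mass <= 0) stop("bead mass must be positive", call. = FALSE)
  if (sigma <= 0) stop("bead sigma must be positive", call. = FALSE)
  structure(
    list(name = as.character(name), size_class = size_class, role = role,
         mass = mass, sigma = sigma),
    class = "bead_spec"
  )
}

#' Declare a molecule topology
#'
#' A molecule is an ordered list of beads. Surfactant species must declare at
#' least one head and one tail bead; the tail beads drive aggregate clustering
#' and the head beads define interfaces.
#'
#' @param name Species label (matched against GRO residue names).
#' @param beads List of [bead_spec()] objects, in bead order.
#' @param surfactant Logical; surfactant species are clustered and analyzed,
#'   non-surfactant species (solvent, counterions) are carried but ignored by
#'   the analysis stages.
#' @return A list with class `"cg_topology"`: `name`, `beads` (a data.frame
#'   with one row per bead), `n_beads`, `surfactant`.
#' @export
#' @examples
#' aot <- cg_topology("AOT", list(
#'   bead_spec("HD1", "S", "head"), bead_spec("HD2", "S", "head"),
#'   bead_spec("TL1", "R", "tail"), bead_spec("TL2", "R", "tail"),
#'   bead_spec("TL3", "R", "tail"), bead_spec("TL4", "R", "tail")
#' ))
cg_topology <- function(name, beads, surfactant = TRUE) {
  if (!length(beads)) stop("topology needs at least one bead", call. = FALSE)
  if (!all(vapply(beads, inherits, logical(1), "bead_spec"))) {
    stop("beads must be a list of bead_spec objects", call. = FALSE)
  }
  df <- do.call(rbind, lapply(beads, function(b) {
    data.frame(name = b$name, size_class = b$size_class, role = b$role,
               mass = b$mass, sigma = b$sigma, stringsAsFactors = FALSE)
  }))
  if (surfactant) {
    if (!any(df$role == "tail") || !any(df$role == "head")) {
      stop("surfactant species '", name,
           "' must declare at least one head and one tail bead", call. = FALSE)
    }
  }
  structure(
    list(name = as.character(name), beads = df, n_beads = nrow(df),
         surfactant = isTRUE(surfactant)),
    class = "cg_topology"
  )
}

#' Assemble a simulation frame
#'
#' One time point of a coarse-grained system: bead coordinates, the periodic
#' box, and the per-bead molecule assignment. Bead metadata (role, mass, sigma)
#' is resolved from the species topologies.
#'
#' @param coords Numeric n x 3 matrix of bead coordinates in Angstrom.
#' @param box A [cg_box()].
#' @param mol_id Integer vector (length n): molecule index of each bead.
#'   Beads of one molecule must be contiguous and in topology bead order.
#' @param species Character vector, one species label per molecule.
#' @param topology Named list of [cg_topology()] objects covering every
#'   species label.
#' @param time Frame time in ns.
#' @return A list with class `"cg_frame"`.
#' @export
cg_frame <- function(coords, box, mol_id, species, topology, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix", call. = FALSE)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (!inherits(box, "cg_box")) box <- cg_box(box)
  mol_id <- as.integer(mol_id)
  if (length(mol_id) != nrow(coords)) {
    stop("mol_id must assign every bead to a molecule", call. = FALSE)
  }
  n_mol <- length(species)
  if (!all(sort(unique(mol_id)) == seq_len(n_mol))) {
    stop("mol_id must cover molecules 1..n_mol with no gaps", call. = FALSE)
  }
  if (is.null(names(topology))) {
    names(topology) <- vapply(topology, `[[`, character(1), "name")
  }
  missing_sp <- setdiff(unique(species), names(topology))
  if (length(missing_sp)) {
    stop("no topology declared for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  # per-bead metadata resolved once, in frame order
  counts <- tabulate(mol_id, nbins = n_mol)
  expected <- vapply(species, function(s) topology[[s]]$n_beads, numeric(1))
  if (!all(counts == expected)) {
    bad <- which(counts != expected)[1]
    stop(sprintf(
      "molecule %d (%s) has %d beads but its topology declares %d",
      bad, species[bad], counts[bad], expected[bad]), call. = FALSE)
  }
  ord <- order(mol_id)
  if (any(diff(mol_id) < 0)) {
    coords <- coords[ord, , drop = FALSE]
    mol_id <- mol_id[ord]
  }
  meta <- do.call(rbind, lapply(seq_len(n_mol), function(m) topology[[species[m]]]$beads))
  structure(
    list(time = as.numeric(time), box = box, coords = coords,
         mol_id = mol_id, species = as.character(species),
         topology = topology,
         bead_name = meta$name, bead_role = meta$role,
         bead_mass = meta$mass, bead_sigma = meta$sigma),
    class = "cg_frame"
  )
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf("<cg_frame t=%.3f ns: %d beads, %d molecules, box %.1f x %.1f x %.1f A>\n",
              x$time, nrow(x$coords), length(x$species),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Indices of surfactant molecules in a frame
#' @param frame A [cg_frame()].
#' @return Integer vector of molecule indices whose species is a surfactant.
#' @export
surfactant_molecules <- function(frame) {
  is_s <- vapply(frame$topology, `[[`, logical(1), "surfactant")
  which(is_s[frame$species])
}

#' Bundle frames into a trajectory
#'
#' @param frames List of [cg_frame()] objects with strictly increasing times.
#' @return A list with class `"cg_trajectory"`.
#' @export
cg_trajectory <- function(frames) {
  if (!length(frames)) stop("trajectory needs at least one frame", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "cg_frame"))) {
    stop("frames must be cg_frame objects", call. = FALSE)
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, times = times), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory: %d frames, %.3f..%.3f ns>\n",
              length(x$frames), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.cg_trajectory <- function(x) length(x$frames)
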