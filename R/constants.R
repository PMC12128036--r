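#' Bead size-class constants
#'
#' Default mass and Lennard-Jones sigma for the three coarse-grained bead size
#' classes used by Martini-style models: regular (R, 4 heavy atoms), small
#' (S, 3) and tiny (T, 2). `sigma` is the interparticle distance at which the
#' Lennard-Jones potential crosses zero, in Angstrom; masses are in amu and
#' depend only on the size class, not on the atoms a bead represents.
#'
#' The table is exported so that users can inspect the defaults; per-bead
#' values can always be overridden when declaring a topology with
#' [bead_spec()].
#'
#' @return A data.frame with columns `size_class`, `mass` (amu) and
#'   `sigma` (Angstrom).
#' @export
#' @examples
#' bead_class_table()
bead_class_table <- function() {
  data.frame(
    size_class = c("R", "S", "T"),
    mass = c(72, 54, 36),
    sigma = c(4.70, 4.10, 3.40),
    stringsAsFactors = FALSE
  )
}

.bead_class_lookup <- function(size_class) {
  tab <- bead_class_table()
  i <- match(size_class, tab$size_class)
  if (anyNA(i)) {
    stop("unknown bead size class: ",
         paste(unique(size_class[is.na(i)]), collapse = ", "),
         " (expected one of R, S, T)", call. = FALSE)
  }
  tab[i, , drop = FALSE]
}
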