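# Core molecule container. Atom indexing is 1-based everywhere the user sees
# it (SDF convention); coordinates are Cartesian angstroms.

.ATOMIC_NUMBERS <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Br = 35L, I = 53L
)

#' Construct a molecule
#'
#' A `molecule` holds an ordered atom list (element symbols), Cartesian
#' coordinates in angstroms, and an undirected bond list. Bond orders are not
#' stored: none of the leverage/autocorrelation machinery uses them. The
#' descriptors expect explicit hydrogens; a molecule with more than one heavy
#' atom and no hydrogen triggers a warning (not an error).
#'
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric matrix with one row per atom and columns x, y, z
#'   (angstroms).
#' @param bonds two-column integer matrix of bonded atom-index pairs
#'   (unordered; stored with first index < second). `NULL` means no bonds yet
#'   (e.g. freshly read XYZ input, see [perceive_bonds()]).
#' @param name free-text molecule name.
#' @param check_h if `TRUE` (default), warn when explicit hydrogens are
#'   missing from a polyatomic heavy-atom structure.
#' @return an object of class `molecule` with fields `elements`, `coords`,
#'   `bonds`, `name`, `explicit_h`.
#' @examples
#' m <- molecule(c("O", "H", "H"),
#'               matrix(c(0, 0, 0, 0.96, 0, 0, -0.24, 0.93, 0),
#'                      ncol = 3, byrow = TRUE),
#'               bonds = rbind(c(1, 2), c(1, 3)), name = "water")
#' n_atoms(m)
#' @export
molecule <- function(elements, coords, bonds = NULL, name = "", check_h = TRUE) {
  elements <- as.character(elements)
  a <- length(elements)
  if (a == 0L) stop("empty structure: no atoms")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != a || ncol(coords) != 3L)
    stop("coords must be a ", a, " x 3 matrix")
  if (!all(is.finite(coords)))
    stop("non-finite coordinate value at atom ",
         which(!apply(is.finite(coords), 1L, all))[1L])
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (is.null(bonds)) {
    bonds <- matrix(integer(0), ncol = 2L)
  } else {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2L)
    if (nrow(bonds)) {
      if (any(bonds < 1L | bonds > a))
        stop("bond references atom index outside 1..", a)
      if (any(bonds[, 1L] == bonds[, 2L]))
        stop("bond connects an atom to itself")
      bonds <- t(apply(bonds, 1L, sort))
      bonds <- unique(bonds)
      bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
    }
  }
  colnames(bonds) <- c("i", "j")
  nh <- sum(elements == "H")
  heavy <- a - nh
  explicit_h <- nh > 0L || a == 1L
  if (check_h && heavy > 1L && nh == 0L)
    warning("molecule '", name, "' has ", heavy,
            " heavy atoms and no hydrogens; HATS descriptors assume ",
            "explicit-hydrogen structures", call. = FALSE)
  structure(
    list(elements = elements, coords = coords, bonds = bonds,
         name = name, explicit_h = explicit_h),
    class = "molecule")
}

#' Number of atoms in a molecule
#' @param mol a [molecule()].
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Atomic numbers of a molecule's atoms
#' @param mol a [molecule()].
#' @return integer vector of atomic numbers.
#' @export
atomic_numbers <- function(mol) {
  z <- .ATOMIC_NUMBERS[mol$elements]
  if (anyNA(z))
    stop("unknown element symbol: ",
         paste(unique(mol$elements[is.na(z)]), collapse = ", "))
  unname(z)
}

#' Molecular formula in Hill order
#' @param mol a [molecule()].
#' @return character scalar, e.g. `"C20H42"`.
#' @export
molecular_formula <- function(mol) {
  tab <- table(mol$elements)
  syms <- names(tab)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s)
    paste0(s, if (tab[[s]] > 1L) tab[[s]] else ""), ""), collapse = "")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", if (nzchar(x$name)) x$name else "(unnamed)",
      ": ", molecular_formula(x), ", ", n_atoms(x), " atoms, ",
      nrow(x$bonds), " bonds",
      if (!x$explicit_h) " [no explicit H]", "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.molecule <- function(x, ...) {
  data.frame(atom = seq_len(n_atoms(x)), element = x$elements,
             x = x$coords[, 1L], y = x$coords[, 2L], z = x$coords[, 3L])
}
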