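# Distance-based bond perception for inputs without a bond block (XYZ).

# Single-bond covalent radii in angstroms, Cordero et al. (2008),
# Dalton Trans. 2832-2838 (C is the sp3 value).
.COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
  N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
  Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Br = 1.20, I = 1.39
)

#' Perceive bonds from interatomic distances
#'
#' Creates a bond between atoms i and j whenever their Euclidean distance is
#' at most `scale` times the sum of their single-bond covalent radii
#' (Cordero 2008 values). An atom is never bonded to itself. Any existing
#' bond list is replaced.
#'
#' @param mol a [molecule()] with coordinates.
#' @param scale positive multiplier on the covalent-radius sum; the default
#'   1.15 is the common heuristic tolerance for slightly stretched bonds.
#' @return `mol` with the perceived bond list.
#' @examples
#' # ideal methane: C-H 1.09 A bonds perceived, H..H 1.78 A not
#' m <- make_n_alkane(1)
#' nrow(perceive_bonds(m)$bonds)  # 4
#' @export
perceive_bonds <- function(mol, scale = 1.15) {
  stopifnot(is.numeric(scale), scale > 0)
  r <- .COVALENT_RADII[mol$elements]
  if (anyNA(r))
    stop("no covalent radius for element: ",
         paste(unique(mol$elements[is.na(r)]), collapse = ", "))
  a <- n_atoms(mol)
  if (a == 1L) {
    mol$bonds <- matrix(integer(0), ncol = 2L,
                        dimnames = list(NULL, c("i", "j")))
    return(mol)
  }
  d <- as.matrix(stats::dist(mol$coords))
  cutoff <- outer(r, r, "+") * scale
  hit <- d <= cutoff & upper.tri(d)
  idx <- which(hit, arr.ind = TRUE)
  mol$bonds <- matrix(as.integer(idx[order(idx[, 1L], idx[, 2L]), ,
                                     drop = FALSE]),
                      ncol = 2L, dimnames = list(NULL, c("i", "j")))
  mol
}
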