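# Molecular influence matrix (MIM) and atomic leverages.
#
# The MIM is the orthogonal projector H = M (M'M)^-1 M' onto the column
# space of the centered coordinate matrix M. Its diagonal h_ii (leverages)
# measures how far atom i sits from the molecular geometric center; the
# leverages sum to the rank D of M (3 for a general 3D structure, 2 for a
# planar one, 1 for a collinear one).

#' Center Cartesian coordinates on the geometric center
#'
#' Subtracts the unweighted mean atom position (the geometric center — all
#' atoms count equally, no mass weighting) from every coordinate, producing
#' the molecular matrix M whose columns have zero mean. This centering is
#' what makes all downstream descriptors invariant to translation.
#'
#' @param mol a [molecule()], or an A x 3 coordinate matrix.
#' @return A x 3 numeric matrix with zero column means.
#' @export
center_coordinates <- function(mol) {
  coords <- if (inherits(mol, "molecule")) mol$coords else as.matrix(mol)
  sweep(coords, 2L, colMeans(coords), "-")
}

#' Molecular influence matrix and leverages
#'
#' Builds the projector onto the column space of the centered molecular
#' matrix via singular value decomposition: H = U_r U_r' where U_r spans the
#' singular directions above tolerance. The SVD route handles exactly planar
#' (rank 2) and collinear (rank 1) molecules, where the textbook explicit
#' inverse of M'M does not exist, with all leverage identities intact. A
#' degenerate all-zero M (single atom, or all atoms coincident) gives rank 0
#' and a zero matrix — documented behaviour, not an error.
#'
#' @param M centered A x 3 matrix from [center_coordinates()], or a
#'   [molecule()] (centered internally).
#' @param tol relative rank tolerance: singular values below `tol` times the
#'   largest are treated as zero.
#' @return an object of class `mim`: list with `H` (A x A symmetric
#'   idempotent matrix), `leverages` (its diagonal, each in \[0, 1\]),
#'   `rank_D` (rank of M), `mean_leverage` (= D / A).
#' @examples
#' mm <- molecular_influence_matrix(make_fullerene_c60())
#' range(mm$leverages)   # all 0.05 by icosahedral symmetry
#' mm$rank_D             # 3
#' @export
molecular_influence_matrix <- function(M, tol = 1e-8) {
  M <- center_coordinates(M)
  a <- nrow(M)
  s <- svd(M, nu = min(a, 3L), nv = 0L)
  r <- if (max(s$d) > 0) sum(s$d > tol * max(s$d)) else 0L
  if (r > 0L) {
    U <- s$u[, seq_len(r), drop = FALSE]
    H <- tcrossprod(U)
  } else {
    H <- matrix(0, a, a)
  }
  lev <- diag(H)
  # clamp roundoff just outside [0, 1]
  lev <- pmin(pmax(lev, 0), 1)
  structure(list(H = H, leverages = lev, rank_D = as.integer(r),
                 mean_leverage = r / a),
            class = "mim")
}

#' @export
print.mim <- function(x, ...) {
  cat("<mim> ", length(x$leverages), " atoms, rank D = ", x$rank_D,
      ", mean leverage ", format(x$mean_leverage, digits = 4), "\n", sep = "")
  cat("leverage range: [", format(min(x$leverages), digits = 4), ", ",
      format(max(x$leverages), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Per-atom leverage table
#'
#' @param mol a [molecule()].
#' @param ... passed to [molecular_influence_matrix()].
#' @return data.frame with columns `atom`, `element`, `leverage`, suitable
#'   for CSV export or for [write_leverage_pdb()].
#' @export
leverage_table <- function(mol, ...) {
  mm <- molecular_influence_matrix(mol, ...)
  data.frame(atom = seq_len(n_atoms(mol)), element = mol$elements,
             leverage = mm$leverages)
}
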