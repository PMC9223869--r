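# Substructure-based interpretation: split a HATS value into intra- and
# inter-fragment contributions, cut molecules into substructures, and compare
# fragment contributions across weighting schemes.

#' Decompose a HATS value into fragment contributions
#'
#' Routes every pair contribution at one lag to the unordered fragment cell
#' (frag(i), frag(j)): diagonal cells collect intra-fragment pairs, an
#' off-diagonal cell the inter-fragment pairs spanning two fragments. The
#' cells partition the summands exactly, so they sum to the descriptor value.
#' Lag-0 self terms always land on the diagonal.
#'
#' @param hats a `hats` object from [hats_profile()].
#' @param partition a [fragment_partition()] covering every atom.
#' @param scheme,lag which descriptor to decompose (must be present in
#'   `hats`); defaults: first scheme, lag 5.
#' @return an object of class `fragment_decomposition`: list with `labels`,
#'   `matrix` (symmetric fragment x fragment contribution matrix), `total`
#'   (the descriptor value), `scheme`, `lag`, and `pair_detail` (the pair
#'   list annotated with `fragment_i`, `fragment_j`).
#' @examples
#' mol <- make_halide_probe("Br")
#' part <- fragment_partition(
#'   ifelse(mol$elements == "Br", "R4", "core"), mol)
#' fragment_decompose(hats_profile(mol, "m", 5), part)
#' @export
fragment_decompose <- function(hats, partition,
                               scheme = hats$schemes[1L], lag = 5L) {
  stopifnot(inherits(hats, "hats"), inherits(partition, "fragment_partition"))
  if (length(partition) != n_atoms(hats$molecule))
    stop("partition covers ", length(partition), " atoms, molecule has ",
         n_atoms(hats$molecule))
  if (!scheme %in% hats$schemes)
    stop("scheme '", scheme, "' not present in this hats object")
  if (!lag %in% hats$lags)
    stop("lag ", lag, " not present in this hats object")
  pairs <- hats$pairs[[scheme]][[as.character(lag)]]
  labs <- attr(partition, "labels")
  mat <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  fi <- unclass(partition)[pairs$i]
  fj <- unclass(partition)[pairs$j]
  # unordered cell: (min label, max label)
  lo <- pmin(fi, fj)
  hi <- pmax(fi, fj)
  if (nrow(pairs)) {
    agg <- tapply(pairs$value, list(lo, hi), sum)
    for (arow in rownames(agg)) for (acol in colnames(agg)) {
      v <- agg[arow, acol]
      if (!is.na(v)) {
        mat[arow, acol] <- mat[arow, acol] + v
        if (arow != acol) mat[acol, arow] <- mat[arow, acol]
      }
    }
  }
  detail <- pairs
  detail$fragment_i <- fi
  detail$fragment_j <- fj
  structure(list(labels = labs, matrix = mat,
                 total = hats$values[scheme, as.character(lag)],
                 scheme = scheme, lag = as.integer(lag),
                 pair_detail = detail),
            class = "fragment_decomposition")
}

#' @export
print.fragment_decomposition <- function(x, digits = 4, ...) {
  cat("<fragment_decomposition> HATS", x$lag, x$scheme, " = ",
      round(x$total, digits), "\n", sep = "")
  cat("fragment cells (diagonal = intra, off-diagonal = inter):\n")
  print(round(x$matrix, digits))
  invisible(x)
}

#' Long-format fragment contribution table
#' @param x a `fragment_decomposition`.
#' @param ... unused.
#' @return data.frame (fragment_a, fragment_b, contribution) over cells
#'   a <= b.
#' @export
as.data.frame.fragment_decomposition <- function(x, ...) {
  labs <- x$labels
  idx <- which(upper.tri(x$matrix, diag = TRUE), arr.ind = TRUE)
  data.frame(scheme = x$scheme, lag = x$lag,
             fragment_a = labs[idx[, 1L]], fragment_b = labs[idx[, 2L]],
             contribution = x$matrix[idx])
}

#' Cut a molecule down to a substructure
#'
#' Keeps the selected atoms with their original coordinates — no hydrogen
#' capping, no re-optimization, no re-centering here (centering is always
#' recomputed inside the influence-matrix step), preserving the initial
#' spatial arrangement of the remaining atom pairs. Leverages and descriptors
#' of the substructure must then be recomputed from scratch: they are not
#' slices of the parent's values, which is exactly what makes cutting
#' informative about size effects.
#'
#' @param mol a [molecule()].
#' @param keep integer vector of 1-based atom indices to keep.
#' @return list with `molecule` (the cut structure, bonds induced on the kept
#'   atoms) and `index_map` (integer vector: `index_map[new]` = old index).
#' @export
substructure_cut <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  if (!length(keep)) stop("keep set is empty")
  a <- n_atoms(mol)
  if (any(keep < 1L | keep > a))
    stop("keep references atom index outside 1..", a)
  new_of_old <- integer(a)
  new_of_old[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[b[, 1L] %in% keep & b[, 2L] %in% keep, , drop = FALSE]
  bonds <- if (nrow(b)) cbind(new_of_old[b[, 1L]], new_of_old[b[, 2L]])
           else NULL
  cut <- molecule(mol$elements[keep], mol$coords[keep, , drop = FALSE],
                  bonds, name = paste0(mol$name, "-cut"), check_h = FALSE)
  list(molecule = cut, index_map = keep)
}

#' Fragment contributions across weighting schemes
#'
#' Runs the fragment decomposition at one lag under several weighting
#' schemes and aligns the cells for comparison — e.g. to see how a
#' heavy-atom-sensitive scheme (mass, volume) inflates the cells containing
#' a halogen relative to the unweighted descriptor.
#'
#' @param mol a [molecule()] with bonds.
#' @param partition a [fragment_partition()].
#' @param lag integer lag, default 5.
#' @param schemes weighting scheme ids, default all six.
#' @return data.frame with columns `scheme`, `lag`, `fragment_a`,
#'   `fragment_b`, `contribution`; attribute `totals` holds the per-scheme
#'   descriptor values (each equal to its rows' sum).
#' @export
weighting_sensitivity <- function(mol, partition, lag = 5L,
                                  schemes = c("u", "m", "e", "p", "v", "i")) {
  h <- hats_profile(mol, schemes = schemes, lags = lag)
  out <- do.call(rbind, lapply(schemes, function(s)
    as.data.frame(fragment_decompose(h, partition, scheme = s, lag = lag))))
  attr(out, "totals") <- stats::setNames(h$values[, as.character(lag)],
                                         schemes)
  out
}
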