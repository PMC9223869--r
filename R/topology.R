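# Topological (graph) distances on the molecular graph and lag selection.
# The lag machinery is purely graph-theoretic: a "distance" is the number of
# bonds on the shortest path, never a Euclidean length.

#' All-pairs topological distances
#'
#' Computes the shortest-path bond count between every pair of atoms
#' (breadth-first search on the unweighted molecular graph). Disconnected
#' pairs (multi-fragment input such as salts) get `Inf` and never match any
#' finite lag.
#'
#' @param mol a [molecule()] with bonds.
#' @return an object of class `topology`: list with `dist` (A x A matrix of
#'   distances, `Inf` for disconnected pairs) and `n_pairs_at` (named integer
#'   vector counting unordered pairs at each finite distance k >= 1).
#' @examples
#' topo <- topological_distances(make_n_alkane(20))
#' topo$n_pairs_at[["5"]]  # 153 atomic pairs five bonds apart
#' @export
topological_distances <- function(mol) {
  a <- n_atoms(mol)
  if (nrow(mol$bonds) == 0L && a > 1L)
    stop("molecule has no bonds; run perceive_bonds() first")
  g <- igraph::make_empty_graph(n = a, directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, t(mol$bonds))
  d <- igraph::distances(g, algorithm = "unweighted")
  dimnames(d) <- NULL
  ut <- d[upper.tri(d)]
  finite <- ut[is.finite(ut)]
  counts <- if (length(finite)) table(as.integer(finite)) else integer(0)
  n_pairs_at <- stats::setNames(as.integer(counts), names(counts))
  structure(list(dist = d, n_pairs_at = n_pairs_at),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  a <- nrow(x$dist)
  fin <- x$dist[upper.tri(x$dist)]
  cat("<topology> ", a, " atoms, diameter ",
      if (any(is.finite(fin))) max(fin[is.finite(fin)]) else 0,
      if (any(!is.finite(fin))) " (disconnected)", "\n", sep = "")
  if (length(x$n_pairs_at)) {
    cat("pairs per lag:\n")
    print(x$n_pairs_at)
  }
  invisible(x)
}

#' Select atomic pairs at a given lag (Dirac delta)
#'
#' Returns exactly the unordered atom pairs whose topological distance equals
#' the lag `k` — the pair set the Dirac-delta function selects in the HATS
#' autocorrelation sum.
#'
#' @param topo a `topology` from [topological_distances()].
#' @param k positive integer lag.
#' @return two-column integer matrix of pairs (i < j), sorted by (i, j);
#'   zero rows when no pair sits at that lag (k beyond the graph diameter).
#' @export
dirac_select <- function(topo, k) {
  stopifnot(inherits(topo, "topology"), length(k) == 1L, k >= 1)
  hit <- which(topo$dist == k & upper.tri(topo$dist), arr.ind = TRUE)
  out <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
  matrix(as.integer(out), ncol = 2L, dimnames = list(NULL, c("i", "j")))
}
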