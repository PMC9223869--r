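# Conformer shape-similarity analysis. Conformers of one molecule share the
# bond topology, so the lag-k pair set is identical across them; only the
# leverages (geometry) differ. The per-pair contributions therefore form a
# fingerprint vector on a common pair-key index, and Euclidean distances
# between fingerprints feed average-linkage (UPGMA) clustering.

#' Pair-contribution fingerprints for a set of conformers
#'
#' @param conformers list of [molecule()]s sharing element sequence and bond
#'   topology (checked; the first differing bond is reported).
#' @param lag integer lag, default 5.
#' @param scheme weighting scheme id, default `"m"`.
#' @param normalize if `TRUE`, scale each fingerprint to unit sum (shape
#'   only); default `FALSE` — raw contributions, so each row sums to that
#'   conformer's HATS(lag, scheme) value.
#' @return an object of class `pair_fingerprints`: numeric matrix with one
#'   row per conformer and one column per canonical pair key `"i-j"`;
#'   attributes `lag`, `scheme`, `values` (per-conformer descriptor values).
#' @export
pair_fingerprints <- function(conformers, lag = 5L, scheme = "m",
                              normalize = FALSE) {
  stopifnot(is.list(conformers), length(conformers) >= 1L)
  ref <- conformers[[1L]]
  for (c in seq_along(conformers)[-1L]) {
    m <- conformers[[c]]
    if (!identical(m$elements, ref$elements))
      stop("conformer ", c, " element sequence differs from conformer 1")
    if (!identical(unname(m$bonds), unname(ref$bonds))) {
      diff1 <- setdiff(apply(m$bonds, 1L, paste, collapse = "-"),
                       apply(ref$bonds, 1L, paste, collapse = "-"))
      diff2 <- setdiff(apply(ref$bonds, 1L, paste, collapse = "-"),
                       apply(m$bonds, 1L, paste, collapse = "-"))
      stop("conformer ", c, " bond topology differs from conformer 1 ",
           "(first differing bond: ", c(diff1, diff2)[1L], ")")
    }
  }
  topo <- topological_distances(ref)
  sel <- dirac_select(topo, lag)
  keys <- paste0(sel[, 1L], "-", sel[, 2L])
  w <- weight_vector(scheme, ref)
  fp <- t(vapply(conformers, function(m) {
    lev <- molecular_influence_matrix(m)$leverages
    wh <- w * lev
    wh[sel[, 1L]] * wh[sel[, 2L]]
  }, numeric(nrow(sel))))
  dimnames(fp) <- list(
    vapply(seq_along(conformers), function(c) {
      nm <- conformers[[c]]$name
      if (nzchar(nm)) nm else paste0("conf", c)
    }, ""),
    keys)
  values <- rowSums(fp)
  if (normalize) {
    nz <- values > 0
    fp[nz, ] <- fp[nz, , drop = FALSE] / values[nz]
  }
  structure(fp, lag = as.integer(lag), scheme = scheme, values = values,
            class = c("pair_fingerprints", "matrix"))
}

#' UPGMA (average-linkage) clustering of fingerprints or distances
#'
#' Agglomerates with the unweighted pair-group method with arithmetic mean
#' on Euclidean distances, yielding an ultrametric dendrogram whose
#' cophenetic distances can be compared with the originals.
#'
#' @param x a `pair_fingerprints` matrix (Euclidean distances are computed),
#'   a [stats::dist], or a square distance matrix.
#' @return an object of class `upgma`: list with `hclust` (a
#'   [stats::hclust] object, method "average"), `dist` (the input
#'   distances), `cophenetic` (the dendrogram-implied [stats::dist]), and
#'   `labels`.
#' @export
upgma <- function(x) {
  d <- if (inherits(x, "dist")) x
       else if (inherits(x, "pair_fingerprints") || is.matrix(x)) {
         if (is.matrix(x) && nrow(x) == ncol(x) &&
             !inherits(x, "pair_fingerprints") &&
             isTRUE(all.equal(unname(x), unname(t(x)))))
           stats::as.dist(x)
         else stats::dist(x)  # Euclidean on fingerprint rows
       } else stop("x must be fingerprints, a dist, or a distance matrix")
  if (anyNA(d)) stop("distances contain NA/NaN")
  if (attr(d, "Size") < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, dist = d, cophenetic = stats::cophenetic(hc),
                 labels = hc$labels),
            class = "upgma")
}

#' @export
print.upgma <- function(x, ...) {
  cat("<upgma> ", attr(x$dist, "Size"), " leaves, merge heights [",
      format(min(x$hclust$height), digits = 4), ", ",
      format(max(x$hclust$height), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.upgma <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic (dendrogram-implied) distances — the standard check of how
#' faithfully a hierarchical clustering preserves the distance structure
#' (1 for exactly ultrametric input).
#'
#' @param dend a `upgma` object.
#' @param dist optional original distances (defaults to those stored in
#'   `dend`).
#' @return real in \[-1, 1\].
#' @export
cophenetic_correlation <- function(dend, dist = dend$dist) {
  v1 <- as.vector(dist)
  v2 <- as.vector(dend$cophenetic)
  if (length(v1) != length(v2)) stop("distance sets differ in size")
  if (length(v1) < 2L)
    stop("cophenetic correlation undefined for fewer than 3 items")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("cophenetic correlation undefined: zero-variance distances")
  stats::cor(v1, v2)
}

#' Flat shape clusters with per-cluster contribution profiles
#'
#' Cuts the UPGMA tree into flat clusters and aggregates each cluster's mean
#' pair-contribution fingerprint; with a fragment partition the profile is
#' further aggregated into fragment cells for interpretation (which
#' substituent arrangements distinguish the shapes).
#'
#' @param fingerprints a `pair_fingerprints` matrix.
#' @param n_clusters number of flat clusters (exclusive with `height`).
#' @param height cut height (exclusive with `n_clusters`).
#' @param partition optional [fragment_partition()] of the shared topology.
#' @return an object of class `shape_report`: list with `assignments`
#'   (named integer vector), `tree` (the `upgma` object), `ccc`, `profiles`
#'   (cluster x pair-key mean-contribution matrix), and `fragment_profiles`
#'   (cluster x fragment-cell matrix, when a partition is given).
#' @export
shape_report <- function(fingerprints, n_clusters = NULL, height = NULL,
                         partition = NULL) {
  stopifnot(inherits(fingerprints, "pair_fingerprints"))
  tree <- upgma(fingerprints)
  if (is.null(n_clusters) == is.null(height))
    stop("give exactly one of n_clusters or height")
  if (!is.null(n_clusters)) {
    if (n_clusters < 1L || n_clusters > nrow(fingerprints))
      stop("n_clusters must be in 1..", nrow(fingerprints))
    cl <- stats::cutree(tree$hclust, k = n_clusters)
  } else {
    cl <- stats::cutree(tree$hclust, h = height)
  }
  profiles <- do.call(rbind, lapply(sort(unique(cl)), function(g)
    colMeans(fingerprints[cl == g, , drop = FALSE])))
  rownames(profiles) <- paste0("cluster", sort(unique(cl)))
  fragment_profiles <- NULL
  if (!is.null(partition)) {
    keys <- do.call(rbind, strsplit(colnames(fingerprints), "-", fixed = TRUE))
    fi <- unclass(partition)[as.integer(keys[, 1L])]
    fj <- unclass(partition)[as.integer(keys[, 2L])]
    cell <- paste(pmin(fi, fj), pmax(fi, fj), sep = ":")
    fragment_profiles <- t(apply(profiles, 1L, function(row)
      tapply(row, cell, sum)))
  }
  ccc <- if (nrow(fingerprints) >= 3L) cophenetic_correlation(tree) else NA_real_
  structure(list(assignments = cl, tree = tree, ccc = ccc,
                 profiles = profiles, fragment_profiles = fragment_profiles),
            class = "shape_report")
}

#' @export
print.shape_report <- function(x, ...) {
  cat("<shape_report> ", length(x$assignments), " conformers in ",
      length(unique(x$assignments)), " cluster(s); CCC = ",
      format(x$ccc, digits = 4), "\n", sep = "")
  print(x$assignments)
  invisible(x)
}

#' Export a UPGMA dendrogram as a newick string
#'
#' @param dend a `upgma` object.
#' @param path optional file to write to.
#' @return the newick string (invisibly when `path` is given).
#' @export
as_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "upgma"))
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
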