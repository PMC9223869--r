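# HATS leverage-weighted autocorrelation descriptors.
#
# HATS0(w) = sum_i (w_i h_ii)^2
# HATSk(w) = sum_{i<j} (w_i h_ii) (w_j h_jj) [d_ij = k],   k = 1, 2, ...
#
# where h_ii are the molecular-influence-matrix leverages, w the
# carbon-scaled atomic weights, and d_ij the topological distance. Every
# summand is kept as a pair-contribution record so the descriptor value can
# be traced back to individual atom pairs.

.pair_frame <- function(i, j, value, lag) {
  df <- data.frame(i = as.integer(i), j = as.integer(j),
                   value = as.numeric(value),
                   lag = rep(as.integer(lag), length(i)))
  df[order(-df$value, df$i, df$j), , drop = FALSE]
}

#' HATS0: the squared self-term sum
#'
#' @param weights per-atom weights (see [weight_vector()]).
#' @param leverages per-atom leverages (see [molecular_influence_matrix()]).
#' @return list with `value` = sum of (w_i h_ii)^2 and `pairs`, a data frame
#'   of the A self terms (i = j, lag 0) sorted by descending contribution.
#' @export
hats0 <- function(weights, leverages) {
  if (length(weights) != length(leverages))
    stop("weights (", length(weights), ") and leverages (",
         length(leverages), ") differ in length")
  v <- (weights * leverages)^2
  idx <- seq_along(v)
  list(value = sum(v), pairs = .pair_frame(idx, idx, v, 0L))
}

#' HATSk: leverage-weighted autocorrelation at lag k
#'
#' Sums (w_i h_ii)(w_j h_jj) over the unordered atom pairs whose topological
#' distance equals `k`, returning both the descriptor value and the full
#' per-pair contribution list (sorted by descending contribution, ties by
#' ascending (i, j) for reproducible coverage counts).
#'
#' @param weights,leverages per-atom vectors of equal length.
#' @param topo a `topology` from [topological_distances()].
#' @param k positive integer lag.
#' @return list with `value` and `pairs` (columns i, j, value, lag); an
#'   empty pair set (lag beyond the diameter) gives value 0.
#' @export
hatsk <- function(weights, leverages, topo, k) {
  if (length(weights) != length(leverages))
    stop("weights and leverages differ in length")
  if (length(weights) != nrow(topo$dist))
    stop("weight/leverage length does not match the topology")
  sel <- dirac_select(topo, k)
  wh <- weights * leverages
  v <- wh[sel[, 1L]] * wh[sel[, 2L]]
  list(value = sum(v), pairs = .pair_frame(sel[, 1L], sel[, 2L], v, k))
}

#' Full HATS profile of a molecule
#'
#' Computes HATS(k, w) for every requested lag and weighting scheme, with
#' complete pair bookkeeping. This is the main entry point of the package.
#'
#' @param mol a [molecule()] with bonds and 3D coordinates.
#' @param schemes character vector of weighting scheme ids
#'   (subset of u, m, v, e, p, i); default `"m"` (atomic mass).
#' @param lags integer lags; default 0:8 (lag 0 is the squared self-term
#'   descriptor HATS0, lags beyond the graph diameter give 0).
#' @param tol rank tolerance passed to [molecular_influence_matrix()].
#' @return an object of class `hats`: list with `name`, `schemes`, `lags`,
#'   `values` (scheme x lag matrix), `pairs` (nested list
#'   `pairs[[scheme]][[as.character(lag)]]` of contribution data frames),
#'   `leverages`, `topology`, `molecule`.
#' @examples
#' h <- hats_profile(make_fullerene_c60(), schemes = "m", lags = 5)
#' coef(h)  # HATS5m = 0.75
#' @export
hats_profile <- function(mol, schemes = "m", lags = 0:8, tol = 1e-8) {
  stopifnot(inherits(mol, "molecule"))
  schemes <- as.character(schemes)
  bad <- setdiff(schemes, names(.WEIGHT_SCHEMES))
  if (length(bad)) stop("unknown weighting scheme(s): ",
                        paste(bad, collapse = ", "))
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 0L)) stop("lags must be >= 0")
  topo <- topological_distances(mol)
  mm <- molecular_influence_matrix(mol, tol = tol)
  values <- matrix(NA_real_, length(schemes), length(lags),
                   dimnames = list(schemes, lags))
  pairs <- stats::setNames(vector("list", length(schemes)), schemes)
  for (s in schemes) {
    w <- weight_vector(s, mol)
    pairs[[s]] <- stats::setNames(vector("list", length(lags)),
                                  as.character(lags))
    for (k in lags) {
      res <- if (k == 0L) hats0(w, mm$leverages)
             else hatsk(w, mm$leverages, topo, k)
      values[s, as.character(k)] <- res$value
      pairs[[s]][[as.character(k)]] <- res$pairs
    }
  }
  structure(list(name = mol$name, schemes = schemes, lags = lags,
                 values = values, pairs = pairs,
                 leverages = mm$leverages, rank_D = mm$rank_D,
                 topology = topo, molecule = mol),
            class = "hats")
}

#' @export
print.hats <- function(x, digits = 4, ...) {
  cat("<hats> ", if (nzchar(x$name)) x$name else "(unnamed)", ": ",
      molecular_formula(x$molecule), ", rank D = ", x$rank_D, "\n", sep = "")
  cat("HATS(k, w) values:\n")
  print(round(x$values, digits))
  invisible(x)
}

#' @export
coef.hats <- function(object, ...) object$values

#' @export
summary.hats <- function(object, fraction = 0.8, ...) {
  rows <- do.call(rbind, lapply(object$schemes, function(s)
    do.call(rbind, lapply(object$lags, function(k) {
      p <- object$pairs[[s]][[as.character(k)]]
      cov <- top_pairs_coverage(p, fraction)
      data.frame(scheme = s, lag = k,
                 value = object$values[s, as.character(k)],
                 n_pairs = nrow(p), n_top = cov$count,
                 covered = cov$covered_fraction)
    }))))
  structure(list(name = object$name, fraction = fraction, table = rows),
            class = "summary.hats")
}

#' @export
print.summary.hats <- function(x, ...) {
  cat("HATS profile", if (nzchar(x$name)) paste0(" of ", x$name), ":\n",
      sep = "")
  cat("(n_top = pairs needed to cover ", x$fraction * 100,
      "% of the value)\n", sep = "")
  tab <- x$table
  tab$value <- round(tab$value, 4)
  tab$covered <- round(tab$covered, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.hats <- function(x, ...) {
  vals <- t(x$values)
  graphics::barplot(t(vals), beside = TRUE, names.arg = rownames(vals),
                    xlab = "lag k", ylab = "HATS(k, w)",
                    legend.text = x$schemes,
                    main = if (nzchar(x$name)) x$name else "HATS profile",
                    ...)
  invisible(x)
}

#' @export
as.data.frame.hats <- function(x, ...) {
  do.call(rbind, lapply(x$schemes, function(s)
    do.call(rbind, lapply(x$lags, function(k) {
      p <- x$pairs[[s]][[as.character(k)]]
      if (!nrow(p)) return(NULL)
      cbind(molecule = x$name, scheme = s, p)
    }))))
}

#' Smallest set of pairs covering a fraction of the descriptor value
#'
#' Identifies the dominant atomic pairs: the shortest prefix of the
#' descending-sorted contribution list whose sum reaches `fraction` of the
#' descriptor value. With equal ties the (i, j)-ascending order makes the
#' count deterministic.
#'
#' @param pairs a pair-contribution data frame (from [hatsk()] or a `hats`
#'   object's `pairs` entry).
#' @param fraction target coverage in (0, 1], default 0.8.
#' @return list with `pairs` (the covering subset), `count`, and
#'   `covered_fraction` (achieved coverage; 0 for an all-zero pair set).
#' @export
top_pairs_coverage <- function(pairs, fraction = 0.8) {
  stopifnot(fraction > 0, fraction <= 1)
  total <- sum(pairs$value)
  if (!nrow(pairs) || total <= 0)
    return(list(pairs = pairs[0L, , drop = FALSE], count = 0L,
                covered_fraction = 0))
  cum <- cumsum(pairs$value)
  n <- which(cum >= fraction * total - 1e-12 * total)[1L]
  list(pairs = pairs[seq_len(n), , drop = FALSE], count = n,
       covered_fraction = cum[n] / total)
}
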