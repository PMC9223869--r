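# Independent oracles, deliberately naive: brute-force implementations that
# share no code path with the package internals.

# Floyd-Warshall all-pairs shortest paths on the bond graph
fw_distances <- function(mol) {
  a <- n_atoms(mol)
  d <- matrix(Inf, a, a)
  diag(d) <- 0
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1L]; j <- mol$bonds[r, 2L]
      d[i, j] <- d[j, i] <- 1
    }
  }
  for (k in seq_len(a)) for (i in seq_len(a)) for (j in seq_len(a))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# leverages through the literal textbook inverse H = M (M'M)^-1 M'
# (valid for full-rank 3D structures only)
leverages_textbook <- function(mol) {
  M <- sweep(mol$coords, 2L, colMeans(mol$coords), "-")
  H <- M %*% solve(t(M) %*% M) %*% t(M)
  diag(H)
}

# naive HATS: explicit double loop over every atom pair with the Dirac delta
hats_naive <- function(mol, scheme, k, leverages = NULL) {
  w <- weight_vector(scheme, mol)
  h <- if (is.null(leverages)) leverages_textbook(mol) else leverages
  if (k == 0L) return(sum((w * h)^2))
  d <- fw_distances(mol)
  a <- n_atoms(mol)
  total <- 0
  for (i in seq_len(a - 1L)) for (j in (i + 1L):a)
    if (is.finite(d[i, j]) && d[i, j] == k)
      total <- total + (w[i] * h[i]) * (w[j] * h[j])
  total
}

# naive UPGMA: track cluster member lists, merge the closest pair at the
# average of all inter-member original distances
upgma_naive_heights <- function(dmat) {
  dmat <- as.matrix(dmat)
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (p in seq_len(length(clusters) - 1L))
      for (q in (p + 1L):length(clusters)) {
        avg <- mean(dmat[clusters[[p]], clusters[[q]]])
        if (avg < bestd) { bestd <- avg; best <- c(p, q) }
      }
    heights <- c(heights, bestd)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# random connected molecule: random tree plus optional extra edges, random
# coordinates, elements drawn from the supported table
random_molecule <- function(n, extra_edge_prob = 0.15,
                            elements = c("C", "H", "N", "O", "S", "Cl", "Br")) {
  el <- sample(elements, n, replace = TRUE)
  bonds <- if (n >= 2L)
    cbind(vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L), 2:n)
  else NULL
  if (n >= 3L) {
    for (i in 1:(n - 2L)) if (stats::runif(1) < extra_edge_prob) {
      j <- sample(setdiff(seq_len(n), i), 1L)
      bonds <- rbind(bonds, sort(c(i, j)))
    }
  }
  molecule(el, matrix(stats::runif(3L * n, -5, 5), ncol = 3L), bonds,
           name = paste0("rnd", n), check_h = FALSE)
}

# random rigid transform (proper rotation + translation)
rigid_transform <- function(coords) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  sweep(coords %*% q, 2L, stats::runif(3L, -10, 10), "+")
}
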