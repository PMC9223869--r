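# Programmatic reference structures. Everything the tests and the
# reproduction script need is generated here from ideal geometric
# parameters; nothing is downloaded or read from disk.

.TET <- acos(-1 / 3)          # tetrahedral angle, 109.471 deg
.CC_SP3 <- 1.54               # sp3 C-C bond, angstrom
.CH <- 1.09                   # C-H bond, angstrom

.unit <- function(v) v / sqrt(sum(v^2))

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# place atom D bonded to C with |CD| = r, angle(B,C,D) = ang and
# torsion(A,B,C,D) = tor (the standard internal-coordinate construction)
.place_atom <- function(A, B, C, r, ang, tor) {
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- c(-r * cos(ang), r * sin(ang) * cos(tor), r * sin(ang) * sin(tor))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

# complete an sp3 carbon to 4 substituents: given unit directions to the
# existing neighbors, return unit directions for the missing hydrogens
.sp3_h_directions <- function(nb_dirs, ref = NULL) {
  deg <- if (is.null(nb_dirs)) 0L else nrow(nb_dirs)
  if (deg == 0L) {
    return(rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
             sqrt(3))
  }
  if (deg == 1L) {
    b <- nb_dirs[1L, ]
    if (is.null(ref)) ref <- c(0, 0, 1)
    e1 <- ref - sum(ref * b) * b
    if (sum(e1^2) < 1e-12) e1 <- c(0, 1, 0) - b[2L] * b
    e1 <- .unit(e1)
    e2 <- .cross3(b, e1)
    phi <- c(60, 180, 300) * pi / 180  # staggered w.r.t. the reference
    return(t(vapply(phi, function(p)
      cos(.TET) * b + sin(.TET) * (cos(p) * e1 + sin(p) * e2),
      numeric(3L))))
  }
  if (deg == 2L) {
    b1 <- nb_dirs[1L, ]; b2 <- nb_dirs[2L, ]
    d <- -.unit(b1 + b2)
    p <- .unit(.cross3(b1, b2))
    half <- .TET / 2
    return(rbind(cos(half) * d + sin(half) * p,
                 cos(half) * d - sin(half) * p))
  }
  if (deg == 3L) {
    return(matrix(-.unit(colSums(nb_dirs)), 1L))
  }
  matrix(numeric(0), 0L, 3L)
}

# carbon skeleton -> full alkane: append hydrogens completing every carbon
# to 4 bonds
.hydrogenate_sp3 <- function(ccoords, cbonds, n_carbons) {
  adj <- lapply(seq_len(n_carbons), function(i) {
    b <- cbonds[cbonds[, 1L] == i | cbonds[, 2L] == i, , drop = FALSE]
    setdiff(as.vector(b), i)
  })
  coords <- ccoords
  bonds <- cbonds
  elements <- rep("C", n_carbons)
  for (i in seq_len(n_carbons)) {
    nbs <- adj[[i]]
    dirs <- if (length(nbs))
      t(vapply(nbs, function(j) .unit(coords[j, ] - ccoords[i, ]),
               numeric(3L)))
    else NULL
    ref <- NULL
    if (length(nbs) == 1L) {
      # torsion reference: a neighbor of the neighbor already placed
      nn <- setdiff(which(vapply(seq_len(nrow(coords)), function(q)
        any((bonds[, 1L] == nbs & bonds[, 2L] == q) |
            (bonds[, 2L] == nbs & bonds[, 1L] == q)), NA)), i)
      if (length(nn)) ref <- .unit(coords[nn[1L], ] - coords[nbs, ])
    }
    hd <- .sp3_h_directions(dirs, ref)
    if (nrow(hd)) {
      for (r in seq_len(nrow(hd))) {
        coords <- rbind(coords, ccoords[i, ] + .CH * hd[r, ])
        elements <- c(elements, "H")
        bonds <- rbind(bonds, c(i, nrow(coords)))
      }
    }
  }
  list(elements = elements, coords = coords, bonds = bonds)
}

# carbon backbone of an unbranched chain with given C-C-C dihedrals
# (length n-3; 180 = anti, +-60 = gauche)
.chain_backbone <- function(n, dihedrals) {
  stopifnot(n >= 1L)
  co <- matrix(0, n, 3L)
  if (n >= 2L) co[2L, ] <- c(.CC_SP3, 0, 0)
  if (n >= 3L)
    co[3L, ] <- co[2L, ] + .CC_SP3 * c(-cos(.TET), sin(.TET), 0)
  if (n >= 4L) {
    for (i in 4:n)
      co[i, ] <- .place_atom(co[i - 3L, ], co[i - 2L, ], co[i - 1L, ],
                             .CC_SP3, .TET, dihedrals[i - 3L] * pi / 180)
  }
  co
}

#' Generate an unbranched alkane CnH2n+2
#'
#' Ideal sp3 geometry: C-C 1.54 A, C-H 1.09 A, tetrahedral angles. The
#' default `all_anti` conformation is the fully extended zigzag. `n = 1`
#' gives methane with the carbon exactly at the hydrogen centroid.
#'
#' @param n_carbons chain length (>= 1).
#' @param conformation `"all_anti"`, or a numeric vector of `n_carbons - 3`
#'   backbone dihedrals in degrees (180 = anti, +-60 = gauche).
#' @return a [molecule()] (atoms: carbons 1..n in chain order, then
#'   hydrogens grouped by carbon).
#' @export
make_n_alkane <- function(n_carbons, conformation = "all_anti") {
  n <- as.integer(n_carbons)
  if (is.na(n) || n < 1L) stop("n_carbons must be >= 1")
  dih <- if (identical(conformation, "all_anti")) rep(180, max(0L, n - 3L))
         else as.numeric(conformation)
  if (n >= 4L && length(dih) != n - 3L)
    stop("need ", n - 3L, " dihedrals for a C", n, " chain")
  co <- .chain_backbone(n, dih)
  cbonds <- if (n >= 2L) cbind(seq_len(n - 1L), 2:n)
            else matrix(integer(0), 0L, 2L)
  parts <- .hydrogenate_sp3(co, cbonds, n)
  molecule(parts$elements, parts$coords, parts$bonds,
           name = if (n == 1L) "methane" else paste0("n-C", n, "H", 2L * n + 2L))
}

#' Generate buckminsterfullerene C60
#'
#' The 60 carbons sit at the vertices of a truncated icosahedron (canonical
#' golden-ratio vertex coordinates: cyclic permutations of (0, +-1, +-3phi),
#' (+-1, +-(2+phi), +-2phi), (+-phi, +-2, +-(2phi+1))), uniformly scaled to
#' a 1.44 A bond length. 90 bonds, every atom degree 3, 12 pentagonal and
#' 20 hexagonal faces. The icosahedral symmetry forces all 60 leverages to
#' be equal (3/60 = 0.05).
#'
#' @return a [molecule()] named `"C60"`.
#' @export
make_fullerene_c60 <- function() {
  phi <- (1 + sqrt(5)) / 2
  signed <- function(v) {
    nz <- which(v != 0)
    sg <- as.matrix(expand.grid(rep(list(c(1, -1)), length(nz))))
    out <- matrix(rep(v, nrow(sg)), ncol = 3L, byrow = TRUE)
    out[, nz] <- sweep(sg, 2L, v[nz], "*")
    out
  }
  base <- rbind(signed(c(0, 1, 3 * phi)),
                signed(c(1, 2 + phi, 2 * phi)),
                signed(c(phi, 2, 2 * phi + 1)))
  verts <- rbind(base,
                 base[, c(2L, 3L, 1L)],
                 base[, c(3L, 1L, 2L)])
  verts <- verts * (1.44 / 2)  # canonical edge length is 2
  mol <- molecule(rep("C", 60L), verts, bonds = NULL, name = "C60",
                  check_h = FALSE)
  perceive_bonds(mol)
}

#' Generate hexa-peri-hexabenzocoronene C42H18
#'
#' A strictly planar (z = 0) graphene-like sheet: 42 sp2 carbons on an ideal
#' honeycomb lattice (C-C 1.42 A) forming 13 fused hexagons with D6h
#' symmetry, and 18 peripheral hydrogens (C-H 1.09 A) on the degree-2 rim
#' carbons along the external bisector.
#'
#' @return a [molecule()] named `"C42H18"`.
#' @export
make_hexabenzocoronene <- function() {
  a <- 1.42
  s3 <- sqrt(3)
  A1 <- s3 * a * c(1, 0)
  A2 <- s3 * a * c(0.5, s3 / 2)
  centers <- rbind(c(0, 0),
                   A1, -A1, A2, -A2, A1 - A2, A2 - A1,
                   A1 + A2, -(A1 + A2),
                   2 * A1 - A2, A2 - 2 * A1,
                   2 * A2 - A1, A1 - 2 * A2)
  hex <- t(vapply((30 + 60 * 0:5) * pi / 180,
                  function(t) a * c(cos(t), sin(t)), numeric(2L)))
  verts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c)
    sweep(hex, 2L, centers[c, ], "+")))
  verts <- verts[!duplicated(round(verts, 6L)), , drop = FALSE]
  co <- cbind(verts, 0)
  mol <- molecule(rep("C", nrow(co)), co, bonds = NULL, name = "C42H18",
                  check_h = FALSE)
  mol <- perceive_bonds(mol)
  deg <- tabulate(as.vector(mol$bonds), nbins = n_atoms(mol))
  rim <- which(deg == 2L)
  hco <- t(vapply(rim, function(i) {
    b <- mol$bonds[mol$bonds[, 1L] == i | mol$bonds[, 2L] == i, ,
                   drop = FALSE]
    nbs <- setdiff(as.vector(b), i)
    d1 <- .unit(co[nbs[1L], ] - co[i, ])
    d2 <- .unit(co[nbs[2L], ] - co[i, ])
    co[i, ] - .CH * .unit(d1 + d2)
  }, numeric(3L)))
  elements <- c(mol$elements, rep("H", length(rim)))
  coords <- rbind(co, hco)
  bonds <- rbind(mol$bonds,
                 cbind(rim, n_atoms(mol) + seq_along(rim)))
  molecule(elements, coords, bonds, name = "C42H18")
}

# ideal planar ring scaffold shared by the benzene-family fixtures
.ring6 <- function() {
  t(vapply((60 * 0:5) * pi / 180,
           function(t) 1.40 * c(cos(t), sin(t), 0), numeric(3L)))
}

#' Generate benzene C6H6
#'
#' Ideal D6h hexagon: C-C 1.40 A, C-H 1.09 A, planar.
#' @return a [molecule()] (atoms 1-6 carbon, 7-12 hydrogen).
#' @export
make_benzene <- function() {
  ring <- .ring6()
  h <- ring * (1.40 + 1.09) / 1.40
  molecule(c(rep("C", 6L), rep("H", 6L)), rbind(ring, h),
           bonds = rbind(cbind(1:6, c(2:6, 1L)), cbind(1:6, 7:12)),
           name = "benzene")
}

#' Generate chlorobenzene C6H5Cl
#'
#' Benzene geometry with the hydrogen on C1 replaced by chlorine
#' (C-Cl 1.74 A, in plane). 12 atoms, 12 bonds, planar.
#' @return a [molecule()] (atom 7 is Cl).
#' @export
make_chlorobenzene <- function() {
  ring <- .ring6()
  cl <- ring[1L, ] * (1.40 + 1.74) / 1.40
  h <- ring[2:6, ] * (1.40 + 1.09) / 1.40
  molecule(c(rep("C", 6L), "Cl", rep("H", 5L)), rbind(ring, cl, h),
           bonds = rbind(cbind(1:6, c(2:6, 1L)), c(1L, 7L),
                         cbind(2:6, 8:12)),
           name = "chlorobenzene")
}

#' Generate the fixed-geometry para-halide probe
#'
#' A planar styrene-like scaffold — a benzene ring with a vinyl
#' (CH=CH2) arm on C1 and the substituent X para on C4 — designed so the
#' substituent always sits at topological distance 5 from the terminal
#' vinyl carbon. The X position is identical for every choice of X
#' (placed at 1.74 A, the C-Cl length), so the halogen series varies only
#' the atomic weight, never the geometry or the leverage pattern: HATS5m
#' then responds purely to the weighting scheme.
#'
#' @param halogen one of `"H"`, `"F"`, `"Cl"`, `"Br"`.
#' @return a [molecule()]; the substituent X is the last atom.
#' @export
make_halide_probe <- function(halogen = c("Cl", "H", "F", "Br")) {
  halogen <- match.arg(halogen)
  ring <- .ring6()                      # C1 at (1.40, 0, 0)
  c7 <- ring[1L, ] + c(1.45, 0, 0)
  c8 <- c7 + 1.34 * c(0.5, sin(pi / 3), 0)
  h7 <- c7 + 1.09 * c(0.5, -sin(pi / 3), 0)
  h8a <- c8 + 1.09 * c(-0.5, sin(pi / 3), 0)
  h8b <- c8 + 1.09 * c(1, 0, 0)
  ringh <- ring[c(2L, 3L, 5L, 6L), ] * (1.40 + 1.09) / 1.40
  x <- ring[4L, ] * (1.40 + 1.74) / 1.40  # same position for every X
  elements <- c(rep("C", 6L), "C", "C", "H", "H", "H",
                rep("H", 4L), halogen)
  coords <- rbind(ring, c7, c8, h7, h8a, h8b, ringh, x)
  bonds <- rbind(cbind(1:6, c(2:6, 1L)),   # ring
                 c(1L, 7L), c(7L, 8L),      # vinyl arm
                 c(7L, 9L), c(8L, 10L), c(8L, 11L),
                 cbind(c(2L, 3L, 5L, 6L), 12:15),
                 c(4L, 16L))
  molecule(elements, coords, bonds,
           name = paste0("para-", halogen, "-styrene-probe"))
}

#' Generate a synthetic conformer ensemble of one alkane chain
#'
#' Builds conformers of a single unbranched alkane (fixed topology and atom
#' numbering) in three planted shape classes by setting backbone dihedrals:
#' all-anti (`linear`, extended), one central gauche kink (`L`), and two
#' gauche kinks (`U`, hairpin-like). Small seeded Gaussian coordinate jitter
#' (sd `jitter` A) makes replicates within a class distinct while keeping
#' the classes well separated — a controllable stand-in for a force-field
#' conformer ensemble.
#'
#' @param n_linear,n_u,n_l conformers per shape class.
#' @param seed optional integer seed for the jitter (`set.seed`).
#' @param n_carbons chain length, default 10.
#' @param jitter coordinate jitter standard deviation in A, default 0.02.
#' @return list of [molecule()]s named `linear1..`, `U1..`, `L1..`, all with
#'   identical element sequence and bond list.
#' @export
make_synthetic_conformers <- function(n_linear = 9, n_u = 6, n_l = 5,
                                      seed = NULL, n_carbons = 10,
                                      jitter = 0.02) {
  stopifnot(n_linear >= 0, n_u >= 0, n_l >= 0)
  if (!is.null(seed)) set.seed(seed)
  nd <- n_carbons - 3L
  mid <- max(1L, nd %/% 2L)
  dihedrals <- list(
    linear = rep(180, nd),
    U = {d <- rep(180, nd); d[max(1L, mid - 2L)] <- 60; d[min(nd, mid + 2L)] <- 60; d},
    L = {d <- rep(180, nd); d[mid] <- 60; d})
  counts <- c(linear = n_linear, U = n_u, L = n_l)
  out <- list()
  for (cls in names(counts)) {
    for (r in seq_len(counts[[cls]])) {
      m <- make_n_alkane(n_carbons, conformation = dihedrals[[cls]])
      m$coords <- m$coords +
        matrix(stats::rnorm(3L * n_atoms(m), sd = jitter), ncol = 3L)
      m$name <- paste0(cls, r)
      out[[m$name]] <- m
    }
  }
  out
}
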