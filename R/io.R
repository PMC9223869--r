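# Structure file I/O: SDF/MOL V2000 and XYZ in, SDF and leverage-annotated
# PDB out, plus the fragment-partition file reader.

#' Read a molecular structure file
#'
#' Reads SDF/MOL (V2000) or XYZ. SDF/MOL input carries a bond block which is
#' used as-is; XYZ input has no bonds until [perceive_bonds()] is applied.
#' Atom order is preserved exactly as in the file (1-based).
#'
#' @param path path to the structure file.
#' @param format one of `"auto"` (by extension), `"sdf"`, `"mol"`, `"xyz"`.
#' @return a [molecule()], or a list of molecules for a multi-record SDF.
#' @export
read_structure <- function(path, format = c("auto", "sdf", "mol", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "mol", xyz = "xyz",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  if (format == "xyz") return(.read_xyz(path))
  .read_sdf(path)
}

.read_sdf <- function(path) {
  set <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("failed to parse SDF/MOL file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  mols <- lapply(seq_along(ChemmineR::cid(set)), function(r) {
    sdf <- set[[r]]
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(ab) || nrow(ab) == 0L)
      stop("empty structure (zero atoms) in record ", r, " of ", path)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- ab[, 1:3, drop = FALSE]
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.null(bb) || nrow(bb) == 0L) NULL else
      cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
    nm <- ChemmineR::sdfid(sdf)
    molecule(elements, coords, bonds,
             name = if (length(nm) && !is.na(nm)) nm else "")
  })
  if (length(mols) == 1L) mols[[1L]] else mols
}

# XYZ dialect: line 1 atom count, line 2 comment, then "element x y z".
.read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path)
  a <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(a)) stop("XYZ parse error at line 1 of ", path,
                     ": expected atom count, got '", lines[1L], "'")
  if (a < 1L) stop("empty structure (zero atoms) in ", path)
  if (length(lines) < a + 2L)
    stop("XYZ file ", path, " truncated: expected ", a,
         " atom lines, found ", max(0L, length(lines) - 2L))
  elements <- character(a)
  coords <- matrix(NA_real_, a, 3L)
  for (i in seq_len(a)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L)
      stop("XYZ parse error at line ", ln, " of ", path,
           ": expected 'element x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("XYZ parse error at line ", ln, " of ", path,
           ": non-numeric coordinate")
    elements[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  molecule(elements, coords, bonds = NULL,
           name = trimws(lines[2L]), check_h = FALSE)
}

#' Write a molecule (or list of molecules) as SDF V2000
#'
#' Coordinates are written at the standard 4-decimal V2000 precision, so a
#' read/write round trip preserves them to that precision. All bonds are
#' written as single bonds (orders are not tracked).
#'
#' @param mol a [molecule()] or list of molecules (multi-record SDF).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path) {
  mols <- if (inherits(mol, "molecule")) list(mol) else mol
  out <- unlist(lapply(mols, .format_molfile))
  writeLines(out, path)
  invisible(path)
}

.format_molfile <- function(mol) {
  a <- n_atoms(mol)
  b <- nrow(mol$bonds)
  c(mol$name,
    "  hgetaway",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", a, b),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            mol$coords[, 1L], mol$coords[, 2L], mol$coords[, 3L],
            mol$elements),
    if (b) sprintf("%3d%3d  1  0  0  0  0", mol$bonds[, 1L], mol$bonds[, 2L]),
    "M  END",
    "$$$$")
}

#' Write atomic leverages into the B-factor column of a PDB file
#'
#' Encodes per-atom leverage values (multiplied by 100, two decimals) in the
#' B-factor column of a standard PDB file, so any molecular viewer can
#' color the structure by leverage.
#'
#' @param mol a [molecule()].
#' @param leverages numeric vector of per-atom leverages, length `n_atoms(mol)`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_leverage_pdb <- function(mol, leverages, path) {
  a <- n_atoms(mol)
  if (length(leverages) != a)
    stop("leverages has length ", length(leverages), ", expected ", a)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(mol$coords)),
    type = rep("HETATM", a),
    resno = rep(1L, a),
    resid = rep("MOL", a),
    elety = paste0(mol$elements, seq_len(a)),
    elesy = mol$elements,
    b = round(leverages * 100, 2))
  invisible(path)
}

#' Read a fragment partition file
#'
#' A fragment partition assigns every atom of a molecule to exactly one
#' labelled fragment (e.g. a common core and substituents R1..R4). Accepted
#' formats: a JSON object mapping atom index to label, or a two-column
#' CSV (atom index, label; a header line is detected and skipped). The
#' partition must be total: unlisted atoms are an error, never silently
#' defaulted.
#'
#' @param path path to a `.json` or `.csv` partition file.
#' @param mol the target [molecule()].
#' @return a [fragment_partition()].
#' @export
read_fragment_partition <- function(path, mol) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- jsonlite::read_json(path)
    idx <- suppressWarnings(as.integer(names(obj)))
    lab <- vapply(obj, as.character, "")
  } else {
    df <- utils::read.csv(path, header = FALSE, strip.white = TRUE,
                          colClasses = "character")
    if (ncol(df) != 2L)
      stop("fragment CSV must have exactly two columns (atom index, label)")
    if (nrow(df) && is.na(suppressWarnings(as.integer(df[1L, 1L]))))
      df <- df[-1L, , drop = FALSE]  # header line
    idx <- suppressWarnings(as.integer(df[[1L]]))
    lab <- df[[2L]]
  }
  if (anyNA(idx)) stop("non-integer atom index in fragment partition file")
  .build_partition(idx, lab, mol)
}

#' Construct a fragment partition programmatically
#'
#' @param labels character vector of fragment labels, one per atom, in atom
#'   order.
#' @param mol the target [molecule()] (checked for length agreement).
#' @return an object of class `fragment_partition`: a character vector of
#'   per-atom labels with a `labels` attribute listing the distinct fragments.
#' @export
fragment_partition <- function(labels, mol) {
  .build_partition(seq_along(labels), as.character(labels), mol)
}

.build_partition <- function(idx, lab, mol) {
  a <- n_atoms(mol)
  if (any(idx < 1L | idx > a))
    stop("fragment partition references atom index outside 1..", a, ": ",
         paste(idx[idx < 1L | idx > a], collapse = ", "))
  if (anyDuplicated(idx))
    stop("duplicate atom index in fragment partition: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  missing <- setdiff(seq_len(a), idx)
  if (length(missing))
    stop("fragment partition does not cover atom(s): ",
         paste(missing, collapse = ", "))
  out <- character(a)
  out[idx] <- lab
  structure(out, labels = sort(unique(lab)), class = "fragment_partition")
}

#' @export
print.fragment_partition <- function(x, ...) {
  tab <- table(unclass(x))
  cat("<fragment_partition> ", length(x), " atoms in ", length(tab),
      " fragment(s): ",
      paste0(names(tab), " (", tab, ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}
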