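# Carbon-scaled atomic weighting schemes.
#
# Every scheme divides a raw physicochemical property by the carbon value,
# so w(C) = 1 exactly — the convention of the Dragon/Todeschini descriptor
# system. Scheme "u" is the unweighted case (w = 1 for every element).

.WEIGHT_SCHEMES <- c(u = "unweighted", m = "atomic mass",
                     v = "van der Waals volume", e = "electronegativity",
                     p = "polarizability", i = "ionization potential")

.weights_env <- new.env(parent = emptyenv())

.property_table <- function() {
  if (is.null(.weights_env$tab)) {
    path <- system.file("extdata", "atomic_properties.csv",
                        package = "hgetaway", mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
    rownames(tab) <- tab$element
    .weights_env$tab <- tab
  }
  .weights_env$tab
}

#' An atomic weighting scheme
#'
#' @param id one of `"u"` (unweighted), `"m"` (atomic mass), `"v"` (van der
#'   Waals volume), `"e"` (Sanderson electronegativity), `"p"`
#'   (polarizability), `"i"` (first ionization potential).
#' @return an object of class `weight_scheme` with the carbon-scaled
#'   element -> weight table.
#' @examples
#' atomic_weight(weight_scheme("m"), "Br")  # 79.904 / 12.011
#' @export
weight_scheme <- function(id = c("u", "m", "v", "e", "p", "i")) {
  id <- match.arg(id)
  tab <- .property_table()
  raw <- switch(id,
    u = stats::setNames(rep(1, nrow(tab)), tab$element),
    m = stats::setNames(tab$mass, tab$element),
    v = stats::setNames((4 / 3) * pi * tab$vdw_radius^3, tab$element),
    e = stats::setNames(tab$electronegativity, tab$element),
    p = stats::setNames(tab$polarizability, tab$element),
    i = stats::setNames(tab$ionization, tab$element))
  structure(list(id = id, name = .WEIGHT_SCHEMES[[id]],
                 table = raw / raw[["C"]], carbon_value = raw[["C"]]),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme> ", x$id, " (", x$name, "), ",
      length(x$table), " elements, w(C) = 1\n", sep = "")
  invisible(x)
}

#' Carbon-scaled weight of one element
#'
#' @param scheme a [weight_scheme()] or its id string.
#' @param element element symbol.
#' @return positive real: raw property value divided by the carbon value.
#' @export
atomic_weight <- function(scheme, element) {
  if (is.character(scheme)) scheme <- weight_scheme(scheme)
  w <- scheme$table[element]
  if (anyNA(w))
    stop("element '", paste(element[is.na(w)], collapse = ", "),
         "' not supported by weighting scheme '", scheme$id, "'")
  unname(w)
}

#' Per-atom weight vector for a molecule
#'
#' @param scheme a [weight_scheme()] or id string.
#' @param mol a [molecule()].
#' @return numeric vector of length `n_atoms(mol)` in atom order.
#' @export
weight_vector <- function(scheme, mol) {
  atomic_weight(scheme, mol$elements)
}
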