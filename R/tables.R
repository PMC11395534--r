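# Atomic property tables. Single source of truth is the commented CSV files
# under inst/extdata; they are read once per session into .pkg_cache.

.pkg_cache <- new.env(parent = emptyenv())

.supported_elements <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

#' Atomic property table
#'
#' Per-element constants used throughout the descriptor stack: conventional
#' IUPAC standard atomic weights, Sanderson electronegativities, static atomic
#' polarizabilities (A^3), the principal quantum number of the valence shell
#' and the valence-electron count. Supported elements:
#' H, C, N, O, F, P, S, Cl, Br, I.
#'
#' @return A data.frame with one row per supported element.
#' @export
atomic_property_table <- function() {
  if (is.null(.pkg_cache$atomic)) {
    path <- system.file("extdata", "atomic_properties.csv", package = "pyrimqsar")
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    rownames(tab) <- tab$element
    .pkg_cache$atomic <- tab
  }
  .pkg_cache$atomic
}

#' PEOE sigma-charge parameter table
#'
#' Polynomial electronegativity coefficients chi(q) = a + b q + c q^2 per atom
#' type (element plus sigma hybridisation where it matters), as published for
#' the partial equalization of orbital electronegativities charge model.
#'
#' @return A data.frame with columns `type`, `a`, `b`, `c`.
#' @export
peoe_parameter_table <- function() {
  if (is.null(.pkg_cache$peoe)) {
    path <- system.file("extdata", "peoe_parameters.csv", package = "pyrimqsar")
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    rownames(tab) <- tab$type
    .pkg_cache$peoe <- tab
  }
  .pkg_cache$peoe
}

.atomic_lookup <- function(elements, column) {
  tab <- atomic_property_table()
  bad <- setdiff(unique(elements), tab$element)
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  tab[elements, column]
}
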