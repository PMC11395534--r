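# Molecular distance-edge descriptors between typed nitrogen atoms.

#' Classify nitrogen atoms by heavy-atom substitution
#'
#' Type 1 = primary (one heavy neighbour), 2 = secondary (-NH- and
#' pyridine-type ring N; two heavy neighbours), 3 = tertiary (-N<; three
#' heavy neighbours).
#'
#' @param mol A `molecule`.
#' @return Integer vector of types, one per nitrogen atom (in atom order).
#' @export
nitrogen_types <- function(mol) {
  idx <- which(mol$atoms$element == "N")
  types <- mol$atoms$heavy_degree[idx]
  if (any(types < 1L | types > 3L)) {
    stop("nitrogen with heavy degree outside 1..3; not a neutral amine/azine")
  }
  stats::setNames(as.integer(types), idx)
}

#' Molecular distance-edge descriptor between typed nitrogens (MDEN-st)
#'
#' \deqn{MDEN_{st} = n_{st} / (\prod d_{ij})^{1/n_{st}}}
#' where the product runs over the topological distances of all unordered
#' pairs of an s-type and a t-type nitrogen (self-pairs excluded for s = t)
#' and \eqn{n_{st}} is the number of such pairs. Equivalent to the classical
#' \eqn{\lambda_{st} = n_{st} / \bar d_{st}^2} with
#' \eqn{\bar d_{st} = (\prod d_{ij})^{1/(2 n_{st})}}. Zero when no pair
#' exists.
#'
#' @param mol A `molecule`.
#' @param s,t Nitrogen types in 1..3 with `s <= t`.
#' @return Non-negative numeric descriptor value.
#' @examples
#' mden(parse_smiles("CNCCN(C)C"), 2, 3)  # one pair at distance 3 -> 1/3
#' @export
mden <- function(mol, s, t) {
  stopifnot(s %in% 1:3, t %in% 1:3, s <= t)
  types <- nitrogen_types(mol)
  idx <- as.integer(names(types))
  si <- idx[types == s]
  ti <- idx[types == t]
  if (!length(si) || !length(ti)) return(0)
  d <- distance_matrix(mol)
  pairs <- if (s == t) {
    if (length(si) < 2L) return(0)
    utils::combn(si, 2L, simplify = FALSE)
  } else {
    unlist(lapply(si, function(a) lapply(ti, function(b) c(a, b))),
           recursive = FALSE)
  }
  dists <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  n <- length(dists)
  gm <- exp(mean(log(dists)))
  n / gm
}
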