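# Per-atom weighting properties for the autocorrelation descriptors.
#
# Each weighting returns an `atom_weighting`: scheme code, per-atom values
# aligned with the molecule's atom table, and their arithmetic mean. Scheme
# codes follow the descriptor naming convention: s = intrinsic state,
# c = partial charge, e = Sanderson electronegativity, p = polarizability.

.new_weighting <- function(scheme, values) {
  structure(list(scheme = scheme, values = values, mean = mean(values)),
            class = "atom_weighting")
}

#' @export
print.atom_weighting <- function(x, ...) {
  cat("<atom_weighting> scheme '", x$scheme, "', ", length(x$values),
      " atoms, mean ", format(x$mean, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Kier-Hall intrinsic state
#'
#' The intrinsic state of atom i is
#' \deqn{I_i = ((2/L_i)^2 \delta^v_i + 1) / \delta_i}
#' with L the principal quantum number of the valence shell, \eqn{\delta^v}
#' the valence electron count minus attached hydrogens, and \eqn{\delta} the
#' number of sigma bonds to heavy atoms. It weights heteroatoms with low
#' sigma-bond counts and high pi/lone-pair electron counts heavily.
#'
#' Explicit hydrogen vertices (produced by [expand_hydrogens()]) receive the
#' value of the same formula evaluated for H (L = 1, \eqn{\delta^v} = 1,
#' \eqn{\delta} = 1), i.e. 5, unless overridden via `h_value`.
#'
#' @param mol A `molecule`.
#' @param h_value Value assigned to explicit hydrogen vertices.
#' @return An `atom_weighting` with scheme `"s"`.
#' @examples
#' intrinsic_state(parse_smiles("CCC"))$values  # 2.0 1.5 2.0
#' @export
intrinsic_state <- function(mol, h_value = 5) {
  at <- mol$atoms
  tab <- atomic_property_table()
  n <- nrow(at)
  h_neighbours <- .h_neighbour_counts(mol)
  vals <- numeric(n)
  for (k in seq_len(n)) {
    if (at$element[k] == "H") { vals[k] <- h_value; next }
    L <- tab[at$element[k], "pqn"]
    zv <- tab[at$element[k], "valence_electrons"]
    h_att <- at$implicit_h[k] + h_neighbours[k]
    delta <- at$heavy_degree[k]
    if (delta == 0L) {
      stop("intrinsic state undefined for isolated atom (index ", k, ")")
    }
    vals[k] <- ((2 / L)^2 * (zv - h_att) + 1) / delta
  }
  .new_weighting("s", vals)
}

.h_neighbour_counts <- function(mol) {
  cnt <- integer(nrow(mol$atoms))
  is_h <- mol$atoms$element == "H"
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    if (is_h[j]) cnt[i] <- cnt[i] + 1L
    if (is_h[i]) cnt[j] <- cnt[j] + 1L
  }
  cnt
}

#' Sanderson electronegativity weighting
#'
#' Per-element lookup of Sanderson electronegativities, optionally scaled
#' relative to carbon (the convention of classical 2D-descriptor software).
#'
#' @param mol A `molecule`.
#' @param scale_to_carbon Divide all values by the carbon value?
#' @return An `atom_weighting` with scheme `"e"`.
#' @export
sanderson_en <- function(mol, scale_to_carbon = FALSE) {
  if (nrow(mol$atoms) == 0L) stop("empty molecule")
  vals <- .atomic_lookup(mol$atoms$element, "sanderson_en")
  if (scale_to_carbon) vals <- vals / .atomic_lookup("C", "sanderson_en")
  .new_weighting("e", vals)
}

#' Atomic polarizability weighting
#'
#' Per-element static atomic polarizabilities in cubic Angstrom, optionally
#' scaled relative to carbon. Polarizability tracks atom size: I > Br > Cl > F.
#'
#' @inheritParams sanderson_en
#' @return An `atom_weighting` with scheme `"p"`.
#' @export
polarizability <- function(mol, scale_to_carbon = FALSE) {
  if (nrow(mol$atoms) == 0L) stop("empty molecule")
  vals <- .atomic_lookup(mol$atoms$element, "polarizability")
  if (scale_to_carbon) vals <- vals / .atomic_lookup("C", "polarizability")
  .new_weighting("p", vals)
}

#' PEOE (Gasteiger-Marsili) partial charges
#'
#' Iterative partial equalization of orbital electronegativities with the
#' polynomial electronegativity \eqn{\chi = a + b q + c q^2} per atom type and
#' damping factor \eqn{(1/2)^n} at iteration n. Hydrogens take part in the
#' equalization explicitly: molecules without explicit H vertices are expanded
#' internally, and the resulting H charges are either folded onto their heavy
#' neighbour (`fold_h_charges = TRUE`, the default for heavy-atom graphs) or
#' discarded with an error. Total charge is conserved to machine precision.
#'
#' @param mol A `molecule`; may contain explicit H vertices.
#' @param iterations Number of damped iterations (default 6, the convention of
#'   the original descriptor software).
#' @param fold_h_charges When `mol` has no explicit H vertices, add each
#'   implicit hydrogen's charge onto its heavy atom.
#' @return An `atom_weighting` with scheme `"c"`, one value per atom of `mol`.
#' @export
partial_charges <- function(mol, iterations = 6, fold_h_charges = TRUE) {
  has_explicit_h <- any(mol$atoms$element == "H")
  work <- if (has_explicit_h) mol else expand_hydrogens(mol)
  q <- .peoe_iterate(work, iterations)
  if (has_explicit_h) {
    return(.new_weighting("c", q))
  }
  nheavy <- nrow(mol$atoms)
  if (fold_h_charges) {
    for (b in seq_len(nrow(work$bonds))) {
      i <- work$bonds$i[b]; j <- work$bonds$j[b]
      if (j > nheavy) q[i] <- q[i] + q[j]
      if (i > nheavy) q[j] <- q[j] + q[i]
    }
  }
  .new_weighting("c", q[seq_len(nheavy)])
}

# One PEOE run over a molecule whose hydrogens are explicit vertices.
.peoe_iterate <- function(mol, iterations) {
  params <- peoe_parameter_table()
  types <- .peoe_atom_types(mol)
  missing <- setdiff(unique(types), rownames(params))
  if (length(missing)) {
    stop("no PEOE parameters for atom type(s): ",
         paste(missing, collapse = ", "))
  }
  a <- params[types, "a"]; b <- params[types, "b"]; cc <- params[types, "c"]
  chi_plus <- a + b + cc
  chi_plus[types == "H"] <- 20.02   # published special value for hydrogen
  n <- nrow(mol$atoms)
  q <- numeric(n)
  bi <- mol$bonds$i; bj <- mol$bonds$j
  for (it in seq_len(iterations)) {
    chi <- a + b * q + cc * q^2
    damp <- 0.5^it
    dq <- numeric(n)
    for (k in seq_along(bi)) {
      i <- bi[k]; j <- bj[k]
      if (chi[i] == chi[j]) next
      if (chi[i] < chi[j]) {
        t <- (chi[j] - chi[i]) / chi_plus[i] * damp
        dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
      } else {
        t <- (chi[i] - chi[j]) / chi_plus[j] * damp
        dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
      }
    }
    q <- q + dq
  }
  q
}

# Sigma-framework atom types for the PEOE parameter lookup. Hybridisation is
# inferred from the atom's own bonds (sp for a triple bond or two doubles,
# sp2 for aromatic atoms or one double bond, sp3 otherwise), except that
# nitrogen and oxygen bearing only single bonds are promoted to sp2 when a
# neighbour is aromatic or multiply bonded: the lone pair conjugates into the
# pi system (anisole-type O, amide N), which raises the effective
# electronegativity. This matches the type assignment of the widely used
# PEOE implementations.
.peoe_atom_types <- function(mol) {
  n <- nrow(mol$atoms)
  n_double <- integer(n); n_triple <- integer(n)
  adj <- vector("list", n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    o <- mol$bonds$order[b]
    if (o == "2") {
      n_double[i] <- n_double[i] + 1L
      n_double[j] <- n_double[j] + 1L
    } else if (o == "3") {
      n_triple[i] <- n_triple[i] + 1L
      n_triple[j] <- n_triple[j] + 1L
    }
  }
  conjugated_neighbour <- function(k) {
    nb <- adj[[k]]
    length(nb) > 0 && any(mol$atoms$aromatic[nb] | n_double[nb] > 0L |
                          n_triple[nb] > 0L)
  }
  vapply(seq_len(n), function(k) {
    el <- mol$atoms$element[k]
    if (el %in% c("H", "F", "Cl", "Br", "I")) return(el)
    hyb <- if (n_triple[k] > 0L || n_double[k] >= 2L) "sp"
    else if (mol$atoms$aromatic[k] || n_double[k] == 1L) "sp2"
    else if (el %in% c("N", "O") && conjugated_neighbour(k)) "sp2"
    else "sp3"
    if (el == "S") return("S.sp3")
    if (el == "P") return("P.sp3")       # unparameterized; caught by caller
    paste0(el, ".", hyb)
  }, character(1))
}

#' Expand implicit hydrogens to explicit vertices
#'
#' Returns a copy of the molecule in which every implicit hydrogen becomes an
#' explicit H vertex bonded to its heavy atom by a single bond. Heavy atoms
#' keep their positions (indices 1..n_heavy); hydrogens are appended.
#'
#' @param mol A `molecule`.
#' @return A `molecule` with explicit hydrogen vertices and `implicit_h = 0`.
#' @export
expand_hydrogens <- function(mol) {
  nheavy <- nrow(mol$atoms)
  hcounts <- mol$atoms$implicit_h
  nh <- sum(hcounts)
  if (nh == 0L) return(mol)
  h_atoms <- data.frame(element = rep("H", nh), aromatic = FALSE,
                        implicit_h = 0L, charge = 0L, heavy_degree = 1L,
                        stringsAsFactors = FALSE)
  parents <- rep(seq_len(nheavy), hcounts)
  h_bonds <- data.frame(i = parents, j = nheavy + seq_len(nh), order = "1",
                        stringsAsFactors = FALSE)
  mol$atoms$implicit_h <- 0L
  mol$atoms <- rbind(mol$atoms, h_atoms)
  mol$bonds <- rbind(mol$bonds, h_bonds)
  mol
}
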