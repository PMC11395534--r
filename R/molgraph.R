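# Heavy-atom molecular graphs parsed from SMILES.
#
# The graph holds heavy atoms only; hydrogens are implicit counts on atoms.
# Aromaticity is taken from lowercase SMILES notation, plus detection of
# six-membered Kekule rings with alternating single/double bonds (C/N only),
# which are normalised to the aromatic representation. Stereo descriptors and
# formal charges are parsed and discarded: the modelled chemical space is
# neutral and all descriptors are 2D-topological.

#' Parse a SMILES string into a molecular graph
#'
#' Builds a heavy-atom molecular graph with implicit hydrogen counts assigned
#' from standard neutral valences (C 4; N 3; O 2; S 2/4/6; P 3/5; halogens 1).
#' Bracket atoms respect their explicit hydrogen count (e.g. `[nH]`).
#' Aromatic rings may be written in lowercase or Kekule form; alternating
#' six-membered C/N Kekule rings are normalised to aromatic.
#'
#' @param smiles A SMILES string. Supported elements:
#'   H, C, N, O, F, P, S, Cl, Br, I (aromatic subset: c, n, o, s, p).
#' @param name Optional molecule label.
#' @return An object of class `molecule`: a list with `atoms` (data.frame with
#'   columns `element`, `aromatic`, `implicit_h`, `charge`, `heavy_degree`),
#'   `bonds` (data.frame with columns `i`, `j`, `order` where order is
#'   `1`, `2`, `3` or `ar`), `name` and `smiles`.
#' @examples
#' pyridine <- parse_smiles("c1ccncc1")
#' n_atoms(pyridine)
#' @export
parse_smiles <- function(smiles, name = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("smiles must be a single non-empty string")
  }
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  element <- character(0)
  aromatic <- logical(0)
  implicit_h <- integer(0)   # NA means "assign from valence rules"
  charge <- integer(0)
  bond_i <- integer(0)
  bond_j <- integer(0)
  bond_o <- character(0)

  prev <- NA_integer_          # atom awaiting the next bond
  pending <- NULL              # explicit bond symbol for next atom/ring bond
  stack <- integer(0)          # branch stack
  rings <- list()              # ring-closure digit -> list(atom, bond)

  add_atom <- function(el, arom, h, chg) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    implicit_h[length(implicit_h) + 1L] <<- h
    charge[length(charge) + 1L] <<- chg
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- if (is.null(pending)) {
        if (arom && aromatic[prev]) "ar" else "1"
      } else pending
      add_bond(prev, idx, ord)
    }
    pending <<- NULL
    prev <<- idx
    idx
  }
  add_bond <- function(i, j, ord) {
    if (i == j) stop("parse error: self-bond in SMILES '", smiles, "'")
    bond_i[length(bond_i) + 1L] <<- i
    bond_j[length(bond_j) + 1L] <<- j
    bond_o[length(bond_o) + 1L] <<- ord
  }
  ring_event <- function(digit) {
    key <- as.character(digit)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending)
    } else {
      open <- rings[[key]]
      ord <- pending
      if (is.null(ord)) ord <- open$bond
      if (is.null(ord)) {
        ord <- if (aromatic[open$atom] && aromatic[prev]) "ar" else "1"
      }
      add_bond(open$atom, prev, ord)
      rings[[key]] <<- NULL
    }
    pending <<- NULL
  }

  two_letter <- c(Cl = "Cl", Br = "Br")
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    nxt <- if (i < n) chars[i + 1L] else ""
    if (ch == "[") {
      close <- i + match("]", chars[(i + 1L):n])
      if (is.na(close)) stop("parse error: unclosed bracket in '", smiles, "'")
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      at <- .parse_bracket_atom(body, smiles)
      add_atom(at$element, at$aromatic, at$h, at$charge)
      i <- close + 1L
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      el <- if (paste0(ch, nxt) %in% names(two_letter)) paste0(ch, nxt) else ch
      if (el %in% c("B")) stop("unsupported element: B")
      if (!el %in% .supported_elements) stop("unsupported element: ", el)
      add_atom(el, FALSE, NA_integer_, 0L)
      i <- i + nchar(el)
    } else if (ch %in% c("c", "n", "o", "s", "p")) {
      add_atom(toupper(ch), TRUE, NA_integer_, 0L)
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- "1"; i <- i + 1L
    } else if (ch == "=") {
      pending <- "2"; i <- i + 1L
    } else if (ch == "#") {
      pending <- "3"; i <- i + 1L
    } else if (ch == ":") {
      pending <- "ar"; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("parse error: branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("parse error: unmatched ')' in '", smiles, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      ring_event(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("parse error: truncated %nn ring closure")
      ring_event(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NULL; i <- i + 1L
    } else {
      stop("parse error: unexpected character '", ch, "' in '", smiles, "'")
    }
  }
  if (length(stack)) stop("parse error: unmatched '(' in '", smiles, "'")
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings)) {
    stop("parse error: unclosed ring bond(s) ", paste(open_rings, collapse = ","))
  }
  if (!length(element)) stop("parse error: no atoms in '", smiles, "'")

  mol <- structure(
    list(
      atoms = data.frame(element = element, aromatic = aromatic,
                         implicit_h = implicit_h, charge = charge,
                         heavy_degree = 0L, stringsAsFactors = FALSE),
      bonds = data.frame(i = bond_i, j = bond_j, order = bond_o,
                         stringsAsFactors = FALSE),
      name = if (is.null(name)) smiles else name,
      smiles = smiles
    ),
    class = "molecule"
  )
  mol <- .normalize_kekule_aromatics(mol)
  mol <- .assign_implicit_h(mol)
  mol$atoms$heavy_degree <- .heavy_degrees(mol)
  mol
}

.parse_bracket_atom <- function(body, smiles) {
  # [isotope? element chirality? Hcount? charge? :class?]
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9+-]*)?(:[0-9]+)?$",
    body))[[1]]
  if (!length(m)) stop("parse error: bad bracket atom [", body, "] in '", smiles, "'")
  sym <- m[3]
  arom <- sym %in% c("c", "n", "o", "s", "p")
  el <- if (arom) toupper(sym) else sym
  if (!el %in% .supported_elements) stop("unsupported element: ", el)
  h <- 0L
  if (nzchar(m[5])) {
    h <- if (m[5] == "H") 1L else as.integer(sub("^H", "", m[5]))
  }
  chg <- 0L
  if (nzchar(m[6])) {
    cs <- m[6]
    if (cs %in% c("+", "-")) chg <- if (cs == "+") 1L else -1L
    else if (grepl("^[+-][0-9]+$", cs)) chg <- as.integer(cs)
    else chg <- sum(ifelse(strsplit(cs, "")[[1]] == "+", 1L, -1L))
  }
  list(element = el, aromatic = arom, h = h, charge = chg)
}

.bond_order_numeric <- function(order) {
  v <- c(`1` = 1, `2` = 2, `3` = 3, ar = 1)
  unname(v[order])
}

.heavy_degrees <- function(mol) {
  deg <- integer(nrow(mol$atoms))
  heavy <- mol$atoms$element != "H"
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    if (heavy[j]) deg[i] <- deg[i] + 1L
    if (heavy[i]) deg[j] <- deg[j] + 1L
  }
  deg
}

# Explicit valence: sum of bond orders, aromatic bonds counting 1 each.
.explicit_valence <- function(mol) {
  val <- numeric(nrow(mol$atoms))
  for (b in seq_len(nrow(mol$bonds))) {
    o <- .bond_order_numeric(mol$bonds$order[b])
    val[mol$bonds$i[b]] <- val[mol$bonds$i[b]] + o
    val[mol$bonds$j[b]] <- val[mol$bonds$j[b]] + o
  }
  val
}

.assign_implicit_h <- function(mol) {
  val <- .explicit_valence(mol)
  at <- mol$atoms
  for (k in seq_len(nrow(at))) {
    if (!is.na(at$implicit_h[k])) next     # bracket atom: explicit count
    el <- at$element[k]
    v <- val[k]
    h <- if (at$aromatic[k]) {
      # lowercase organic-subset atom: carbon completes to 3 sigma+pi slots,
      # heteroatoms carry no implicit H unless written [nH]
      if (el == "C") max(0, 3 - v) else 0
    } else {
      target <- switch(el,
        C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1, H = 0,
        S = { s <- c(2, 4, 6); s[s >= v][1] },
        P = { s <- c(3, 5); s[s >= v][1] })
      if (is.na(target)) target <- v
      max(0, target - v)
    }
    at$implicit_h[k] <- as.integer(h)
  }
  mol$atoms <- at
  mol
}

# Normalise alternating six-membered C/N Kekule rings to the aromatic form.
.normalize_kekule_aromatics <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb < 6L) return(mol)
  na <- nrow(mol$atoms)
  adj <- vector("list", na)
  for (b in seq_len(nb)) {
    adj[[mol$bonds$i[b]]] <- c(adj[[mol$bonds$i[b]]], b)
    adj[[mol$bonds$j[b]]] <- c(adj[[mol$bonds$j[b]]], b)
  }
  other <- function(b, a) if (mol$bonds$i[b] == a) mol$bonds$j[b] else mol$bonds$i[b]
  seen <- character(0)
  to_ar <- integer(0)
  # DFS for simple 6-cycles
  walk <- function(start, at, path_atoms, path_bonds) {
    if (length(path_atoms) == 6L) {
      for (b in adj[[at]]) {
        if (other(b, at) == start) {
          key <- paste(sort(path_atoms), collapse = "-")
          if (!key %in% seen) {
            seen <<- c(seen, key)
            cyc <- c(path_bonds, b)
            ords <- .bond_order_numeric(mol$bonds$order[cyc])
            els <- mol$atoms$element[path_atoms]
            if (all(els %in% c("C", "N")) &&
                all(ords %in% c(1, 2)) &&
                all(abs(diff(c(ords, ords[1]))) == 1)) {
              to_ar <<- union(to_ar, cyc)
            }
          }
        }
      }
      return(invisible())
    }
    for (b in adj[[at]]) {
      nxt <- other(b, at)
      if (nxt %in% path_atoms) next
      if (nxt < start) next                 # canonical: cycle rooted at min atom
      walk(start, nxt, c(path_atoms, nxt), c(path_bonds, b))
    }
  }
  for (a in seq_len(na)) walk(a, a, a, integer(0))
  if (length(to_ar)) {
    mol$bonds$order[to_ar] <- "ar"
    ar_atoms <- unique(c(mol$bonds$i[to_ar], mol$bonds$j[to_ar]))
    mol$atoms$aromatic[ar_atoms] <- TRUE
  }
  mol
}

#' Number of heavy atoms
#' @param mol A `molecule`.
#' @return Integer count of non-hydrogen atoms.
#' @export
n_atoms <- function(mol) sum(mol$atoms$element != "H")

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$name, "\n", sep = "")
  cat("  SMILES: ", x$smiles, "\n", sep = "")
  cat("  ", n_atoms(x), " heavy atoms, ", nrow(x$bonds), " bonds, formula ",
      molecular_formula(x), ", MW ", sprintf("%.2f", molecular_weight(x)),
      "\n", sep = "")
  invisible(x)
}

#' Topological distance matrix
#'
#' All-pairs shortest-path distances in bond counts over the molecular graph.
#'
#' @param mol A `molecule`.
#' @return A symmetric integer matrix `d` with `d[i, i] = 0`.
#' @export
distance_matrix <- function(mol) {
  na <- nrow(mol$atoms)
  if (na == 1L) return(matrix(0L, 1, 1))
  g <- igraph::make_empty_graph(n = na, directed = FALSE)
  g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  d <- igraph::distances(g)
  if (any(is.infinite(d))) {
    stop("disconnected molecular graph: distance matrix undefined")
  }
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Molecular formula in Hill order
#' @param mol A `molecule`.
#' @return Character scalar, e.g. `"C7H7Cl3N2"`.
#' @export
molecular_formula <- function(mol) {
  counts <- .element_counts(mol)
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

.element_counts <- function(mol) {
  els <- mol$atoms$element
  h <- sum(mol$atoms$implicit_h) + sum(els == "H")
  counts <- table(els[els != "H"])
  out <- as.list(counts)
  out <- lapply(out, as.integer)
  if (h > 0L) out$H <- as.integer(h)
  out
}

#' Molecular weight
#'
#' Sum of standard atomic weights over all atoms including implicit hydrogens.
#'
#' @param mol A `molecule`.
#' @param digits Decimal places for rounding; `NULL` for the raw sum.
#' @return Mass in g/mol, rounded to `digits` (default 2) decimals.
#' @examples
#' molecular_weight(parse_smiles("C"))  # 16.04
#' @export
molecular_weight <- function(mol, digits = 2) {
  counts <- .element_counts(mol)
  w <- .atomic_lookup(names(counts), "weight")
  mw <- sum(w * unlist(counts))
  if (is.null(digits)) mw else round(mw, digits)
}

#' Mass percentage of an element
#'
#' @param mol A `molecule`.
#' @param element Element symbol; must be in the supported set.
#' @param digits Decimal places (default 2, matching elemental-analysis
#'   reporting convention); `NULL` for the raw value.
#' @return `100 * mass(element)/molecular weight`; 0 when the element is absent.
#' @export
elemental_percent <- function(mol, element, digits = 2) {
  if (!element %in% .supported_elements) {
    stop("unsupported element: ", element)
  }
  counts <- .element_counts(mol)
  k <- counts[[element]]
  if (is.null(k)) return(0)
  pct <- 100 * k * .atomic_lookup(element, "weight") /
    molecular_weight(mol, digits = NULL)
  if (is.null(digits)) pct else round(pct, digits)
}

#' Write a molecule back to SMILES
#'
#' Produces a valid, fully explicit (bracket-atom) SMILES for round-tripping.
#' The output is not canonical; it is a faithful serialisation of the graph.
#'
#' @param mol A `molecule`.
#' @return A SMILES string that reparses to an isomorphic graph.
#' @export
write_smiles <- function(mol) {
  na <- nrow(mol$atoms)
  nb <- nrow(mol$bonds)
  adj <- vector("list", na)
  for (b in seq_len(nb)) {
    adj[[mol$bonds$i[b]]] <- c(adj[[mol$bonds$i[b]]], b)
    adj[[mol$bonds$j[b]]] <- c(adj[[mol$bonds$j[b]]], b)
  }
  other <- function(b, a) if (mol$bonds$i[b] == a) mol$bonds$j[b] else mol$bonds$i[b]

  # pass 1: DFS spanning forest; classify tree vs ring-closure (back) edges
  visited <- logical(na)
  used <- logical(nb)
  tree_children <- vector("list", na)   # tree bonds, in emission order
  ring_bonds <- vector("list", na)      # back bonds incident, in digit order
  digit_of <- integer(nb)
  ndigits <- 0L
  roots <- integer(0)
  dfs1 <- function(a) {
    visited[a] <<- TRUE
    for (b in adj[[a]]) {
      if (used[b]) next
      nxt <- other(b, a)
      if (!visited[nxt]) {
        used[b] <<- TRUE
        tree_children[[a]] <<- c(tree_children[[a]], b)
        dfs1(nxt)
      } else {
        used[b] <<- TRUE
        ndigits <<- ndigits + 1L
        digit_of[b] <<- ndigits
        ring_bonds[[nxt]] <<- c(ring_bonds[[nxt]], b)
        ring_bonds[[a]] <<- c(ring_bonds[[a]], b)
      }
    }
  }
  for (root in seq_len(na)) {
    if (!visited[root]) { roots <- c(roots, root); dfs1(root) }
  }

  bond_sym <- function(b) switch(mol$bonds$order[b], `1` = "-", `2` = "=",
                                 `3` = "#", ar = "")
  atom_token <- function(a) {
    sym <- if (mol$atoms$aromatic[a]) tolower(mol$atoms$element[a]) else
      mol$atoms$element[a]
    h <- mol$atoms$implicit_h[a]
    paste0("[", sym, if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
           "]")
  }
  digit_token <- function(b) {
    d <- digit_of[b]
    if (d < 10L) as.character(d) else paste0("%", sprintf("%02d", d))
  }

  # pass 2: emit
  emit <- function(a, via_bond) {
    out <- if (is.null(via_bond)) "" else bond_sym(via_bond)
    out <- paste0(out, atom_token(a))
    for (b in ring_bonds[[a]]) {
      out <- paste0(out, bond_sym(b), digit_token(b))
    }
    ch <- tree_children[[a]]
    for (k in seq_along(ch)) {
      sub <- emit(other(ch[k], a), ch[k])
      if (k < length(ch)) sub <- paste0("(", sub, ")")
      out <- paste0(out, sub)
    }
    out
  }
  paste(vapply(roots, function(r) emit(r, NULL), character(1)), collapse = ".")
}
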