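# Shared fixtures and small oracles used across the test files.

fixture_smiles <- c(
  benzene = "c1ccccc1",
  pyridine = "c1ccncc1",
  propane = "CCC",
  toluene = "Cc1ccccc1",
  uracil = "O=c1cc[nH]c(=O)[nH]1",
  pyrimidine = "c1cncnc1",
  anisole = "COc1ccccc1",
  fluoromethane = "CF",
  diamine = "CNCCN(C)C",
  halothane_ish = "ClCCCBr"
)

fixture_molecules <- function() lapply(names(fixture_smiles), function(nm) {
  parse_smiles(fixture_smiles[[nm]], name = nm)
})

# Brute-force all-pairs shortest paths (Floyd-Warshall) oracle.
floyd_warshall <- function(mol) {
  n <- nrow(mol$atoms)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (b in seq_len(nrow(mol$bonds))) {
    d[mol$bonds$i[b], mol$bonds$j[b]] <- 1
    d[mol$bonds$j[b], mol$bonds$i[b]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Apply a random permutation to a molecule's atom order (relabelling the
# graph); descriptors must be invariant under this.
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  out <- mol
  out$atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$bonds$i <- inv[mol$bonds$i]
  out$bonds$j <- inv[mol$bonds$j]
  out
}

# Graph isomorphism including atom attributes, via igraph VF2 with colours.
molecules_isomorphic <- function(a, b) {
  if (nrow(a$atoms) != nrow(b$atoms) || nrow(a$bonds) != nrow(b$bonds)) {
    return(FALSE)
  }
  colour <- function(mol) {
    key <- paste(mol$atoms$element, mol$atoms$aromatic, mol$atoms$implicit_h)
    as.integer(factor(key, levels = sort(unique(c(
      paste(a$atoms$element, a$atoms$aromatic, a$atoms$implicit_h),
      paste(b$atoms$element, b$atoms$aromatic, b$atoms$implicit_h))))))
  }
  ecolour <- function(mol) {
    as.integer(factor(mol$bonds$order, levels = c("1", "2", "3", "ar")))
  }
  ga <- igraph::graph_from_edgelist(cbind(a$bonds$i, a$bonds$j),
                                    directed = FALSE)
  gb <- igraph::graph_from_edgelist(cbind(b$bonds$i, b$bonds$j),
                                    directed = FALSE)
  ga <- igraph::add_vertices(ga, max(0, nrow(a$atoms) - igraph::vcount(ga)))
  gb <- igraph::add_vertices(gb, max(0, nrow(b$atoms) - igraph::vcount(gb)))
  igraph::is_isomorphic_to(ga, gb, method = "vf2",
                           vertex.color1 = colour(a),
                           vertex.color2 = colour(b),
                           edge.color1 = ecolour(a), edge.color2 = ecolour(b))
}

# Brute-force centered autocorrelation oracle over the distance matrix.
atsc_bruteforce <- function(d, w, k, ordered = FALSE) {
  wc <- w - mean(w)
  n <- length(w)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] == k) s <- s + wc[i] * wc[j]
  }
  if (ordered) 2 * s else s
}
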