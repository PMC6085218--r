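# Independent graph oracles built on igraph; the package itself never calls
# igraph, so these are genuinely separate routes for cross-checking.

mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$nodes), directed = FALSE)
  if (nrow(mol$bonds)) g <- igraph::add_edges(g, t(mol$bonds))
  g
}

node_signature <- function(mol) {
  paste(mol$nodes$name,
        ifelse(is.na(mol$nodes$backbone_label), "", mol$nodes$backbone_label),
        mol$nodes$start, mol$nodes$end, sep = "\r")
}

# graph isomorphism respecting names, backbone labels and tags (VF2)
molecules_isomorphic <- function(a, b) {
  if (nrow(a$nodes) != nrow(b$nodes) || nrow(a$bonds) != nrow(b$bonds) ||
      a$parts != b$parts) return(FALSE)
  sa <- node_signature(a); sb <- node_signature(b)
  lev <- sort(unique(c(sa, sb)))
  igraph::isomorphic(mol_igraph(a), mol_igraph(b), method = "vf2",
                     vertex.color1 = as.integer(factor(sa, lev)),
                     vertex.color2 = as.integer(factor(sb, lev)))
}

# brute-force longest path length (in particles) of a tree: on a tree the
# unique path between two nodes realizes their distance, so the longest
# simple path is the maximum pairwise distance + 1
tree_longest_path_len <- function(mol) {
  d <- igraph::distances(mol_igraph(mol))
  max(d[is.finite(d)]) + 1
}

# check bond-offset closure of a record table against first principles
offsets_closed <- function(tab) {
  n <- nrow(tab)
  for (i in seq_len(n)) {
    for (d in tab$bond_offsets[[i]]) {
      j <- i + d
      if (j < 1L || j > n) return(FALSE)
      if (!(-d %in% tab$bond_offsets[[j]])) return(FALSE)
    }
  }
  TRUE
}

expect_valid_spices <- function(s) {
  rep <- validate_spices(s)
  expect_true(rep$valid, info = paste("expected valid:", s))
}
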