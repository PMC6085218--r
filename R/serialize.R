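#' Serialize a molecule back to SPICES notation
#'
#' Emits a syntactically valid SPICES string for a molecule graph. The writer
#' walks a depth-first spanning tree of each part from its first particle
#' (children in ascending node-index order), writing non-tree bonds as
#' ring-closure label pairs and earlier siblings as branches. Backbone labels
#' and START/END tags are preserved. The notation is not canonically unique,
#' and no canonicalization is attempted: re-parsing the output yields a graph
#' isomorphic to the input (same names, labels, tags and part count), not
#' necessarily the identical string the molecule was parsed from.
#'
#' @param mol a `spices_molecule` satisfying all structural invariants
#'   (violations raise an error naming the invariant).
#' @return A single character string.
#' @examples
#' serialize_spices(parse_spices("A-B[1]-C-D[1]"))
#' @export
serialize_spices <- function(mol) {
  validate_molecule(mol)
  adj <- adjacency_list(mol)
  nd <- mol$nodes
  n <- nrow(nd)
  out_parts <- character(mol$parts)

  for (p in seq_len(mol$parts)) {
    idx <- which(nd$part == p)
    root <- idx[1L]
    # spanning tree by recursive DFS, ascending neighbor order
    parent <- rep(NA_integer_, n)
    visited <- logical(n)
    children <- vector("list", n)
    ring_edges <- list()      # non-tree edges, in discovery order
    ring_seen <- new.env(parent = emptyenv())
    dfs <- function(v) {
      visited[v] <<- TRUE
      for (w in adj[[v]]) {
        if (!visited[w]) {
          parent[w] <<- v
          children[[v]] <<- c(children[[v]], w)
          dfs(w)
        } else if (is.na(parent[v]) || w != parent[v]) {
          key <- paste(min(v, w), max(v, w))
          if (is.null(ring_seen[[key]])) {
            ring_seen[[key]] <- TRUE
            ring_edges[[length(ring_edges) + 1L]] <<- c(v, w)
          }
        }
      }
    }
    dfs(root)
    # per-part ring labels 1, 2, ... in discovery order
    ring_at <- vector("list", n)
    if (length(ring_edges)) {
      for (k in seq_along(ring_edges)) {
        e <- ring_edges[[k]]
        ring_at[[e[1L]]] <- c(ring_at[[e[1L]]], k)
        ring_at[[e[2L]]] <- c(ring_at[[e[2L]]], k)
      }
    }
    node_token <- function(v) {
      s <- nd$name[v]
      if (!is.na(nd$backbone_label[v]))
        s <- paste0(s, "'", nd$backbone_label[v], "'")
      if (nd$start[v]) s <- paste0(s, "[START]")
      if (nd$end[v])   s <- paste0(s, "[END]")
      if (length(ring_at[[v]]))
        s <- paste0(s, paste0("[", sort(ring_at[[v]]), "]", collapse = ""))
      s
    }
    emit <- function(v) {
      s <- node_token(v)
      ch <- children[[v]]
      if (length(ch)) {
        for (k in seq_along(ch)) {
          sub <- emit(ch[k])
          s <- if (k < length(ch)) paste0(s, "(-", sub, ")")
               else paste0(s, "-", sub)
        }
      }
      s
    }
    out_parts[p] <- emit(root)
  }
  paste(out_parts, collapse = ".")
}
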