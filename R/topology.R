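#' Particle frequencies
#'
#' Counts every particle occurrence in a molecule by name. The counts always
#' sum to the total particle count.
#'
#' @param mol a `spices_molecule`.
#' @return A named integer vector (names sorted alphabetically).
#' @examples
#' particle_frequencies(parse_spices("Et-Et-MeAc"))
#' @export
particle_frequencies <- function(mol) {
  stopifnot(inherits(mol, "spices_molecule"))
  tab <- table(mol$nodes$name)
  stats::setNames(as.integer(tab), names(tab))
}

#' Neighbor shells of every particle
#'
#' For each particle, lists the particles at graph (bond-count) distance
#' exactly 1, 2, ..., `depth`. Shell 1 is the bond adjacency; shells are
#' disjoint by construction.
#'
#' @param mol a `spices_molecule`.
#' @param depth maximum shell, a positive integer.
#' @return A list with one element per particle (notation order); each element
#'   is a list of `depth` sorted integer vectors of 1-based node indices
#'   (possibly empty).
#' @examples
#' next_neighbors(parse_spices("A-B-C"), depth = 2)
#' @export
next_neighbors <- function(mol, depth = 1L) {
  stopifnot(inherits(mol, "spices_molecule"))
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("'depth' must be a positive integer")
  adj <- adjacency_list(mol)
  n <- length(adj)
  lapply(seq_len(n), function(v) {
    dist <- rep(NA_integer_, n)
    dist[v] <- 0L
    queue <- integer(n); queue[1L] <- v; head <- 1L; tail <- 1L
    while (head <= tail) {
      u <- queue[head]; head <- head + 1L
      if (dist[u] >= depth) next
      for (w in adj[[u]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[u] + 1L
          tail <- tail + 1L; queue[tail] <- w
        }
      }
    }
    lapply(seq_len(depth), function(k) which(dist == k))
  })
}

#' Split a molecule into its independent parts
#'
#' Returns one single-part molecule per independent part (connected
#' component), preserving relative node order. Node indices are renumbered
#' consecutively within each part.
#'
#' @param mol a `spices_molecule`.
#' @return A list of `spices_molecule` objects, one per part.
#' @examples
#' length(connected_parts(parse_spices("A-B.C-D-E")))  # 2
#' @export
connected_parts <- function(mol) {
  stopifnot(inherits(mol, "spices_molecule"))
  nd <- mol$nodes
  lapply(seq_len(mol$parts), function(p) {
    idx <- which(nd$part == p)
    remap <- integer(nrow(nd)); remap[idx] <- seq_along(idx)
    sub_nodes <- nd[idx, , drop = FALSE]
    sub_nodes$part <- 1L
    rownames(sub_nodes) <- NULL
    keep <- nd$part[mol$bonds[, 1L]] == p
    sub_bonds <- mol$bonds[keep, , drop = FALSE]
    if (nrow(sub_bonds)) {
      sub_bonds <- cbind(remap[sub_bonds[, 1L]], remap[sub_bonds[, 2L]])
    }
    new_spices_molecule(sub_nodes, sub_bonds, 1L, source_text = NULL)
  })
}

#' @keywords internal
new_chain_path <- function(nodes, oriented) {
  structure(list(nodes = as.integer(nodes), oriented = isTRUE(oriented)),
            class = "chain_path")
}

#' @export
print.chain_path <- function(x, ...) {
  cat(sprintf("<chain_path: %d particles%s>\n  %s\n", length(x$nodes),
              if (x$oriented) ", oriented (START -> END)" else "",
              paste(x$nodes, collapse = " - ")))
  invisible(x)
}

# recursive DFS from `root`; returns depth and parent along the DFS tree,
# neighbors explored in ascending index order (fixed tie-breaking)
#' @keywords internal
dfs_tree <- function(adj, root) {
  n <- length(adj)
  depth <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  visit <- function(v, d, p) {
    depth[v] <<- d
    parent[v] <<- p
    for (w in adj[[v]]) if (is.na(depth[w])) visit(w, d + 1L, v)
  }
  visit(root, 0L, NA_integer_)
  list(depth = depth, parent = parent)
}

#' Longest chain by the double depth-first-search sweep
#'
#' Determines a long linear particle chain with two DFS passes: starting from
#' the first particle of the notation, pass 1 finds the maximum-distant
#' particle A (distance measured along the DFS tree); pass 2, started from A,
#' finds the maximum-distant particle B and returns the A-to-B path of its
#' DFS tree. For acyclic molecules this is a true longest path; for cyclic
#' molecules the double sweep may return a non-maximal chain, which is
#' accepted behavior (the resulting tube geometries are still valid start
#' configurations for soft-potential simulations). Ties in distance are
#' broken toward the lowest node index, and the returned path is oriented to
#' start at its lower-indexed endpoint, so repeated calls are deterministic.
#'
#' @param mol a single-part (connected) `spices_molecule`.
#' @return A `chain_path` with `oriented = FALSE`.
#' @examples
#' longest_chain(parse_spices("A-B-C-D"))$nodes       # 1 2 3 4
#' length(longest_chain(parse_spices("A(-B)(-C)-D"))$nodes)  # 3
#' @export
longest_chain <- function(mol) {
  stopifnot(inherits(mol, "spices_molecule"))
  if (mol$parts != 1L)
    stop("molecule must be a single connected part; see connected_parts()")
  adj <- adjacency_list(mol)
  pass1 <- dfs_tree(adj, 1L)
  if (anyNA(pass1$depth))
    stop("molecule is not connected")
  a <- which.max(ifelse(is.na(pass1$depth), -1L, pass1$depth))
  pass2 <- dfs_tree(adj, a)
  b <- which.max(ifelse(is.na(pass2$depth), -1L, pass2$depth))
  path <- integer(0)
  v <- b
  while (!is.na(v)) {
    path <- c(v, path)
    v <- pass2$parent[v]
  }
  # without tags either orientation is valid; fix the one starting at the
  # lower-indexed endpoint so repeated calls and platforms agree
  if (path[1L] > path[length(path)]) path <- rev(path)
  new_chain_path(path, oriented = FALSE)
}

#' Longest oriented chain between the START and END tags
#'
#' Finds the longest simple path from the `[START]`-tagged particle to the
#' `[END]`-tagged particle by exhaustive depth-first enumeration of simple
#' paths (neighbors in ascending index order; among equally long paths the
#' first found is kept). The enumeration is capped at `max_states` visited
#' search states; past the cap the best complete START-to-END path found so
#' far is returned (the search runs on until a first complete path exists),
#' which concedes optimality only on large cyclic molecules.
#'
#' @param mol a single-part `spices_molecule` with exactly one START and one
#'   END tag.
#' @param max_states state budget for the exhaustive search (default 10^4).
#' @return A `chain_path` with `oriented = TRUE`; its first node carries
#'   START and its last carries END.
#' @examples
#' longest_chain_oriented(parse_spices("A[START]-B-C[END]"))$nodes  # 1 2 3
#' @export
longest_chain_oriented <- function(mol, max_states = 1e4) {
  stopifnot(inherits(mol, "spices_molecule"))
  if (mol$parts != 1L)
    stop("molecule must be a single connected part; see connected_parts()")
  s <- which(mol$nodes$start)
  e <- which(mol$nodes$end)
  if (length(s) != 1L || length(e) != 1L)
    stop("oriented chain requires exactly one [START] and one [END] tag")
  adj <- adjacency_list(mol)
  n <- length(adj)
  onpath <- logical(n)
  path <- integer(n)
  plen <- 0L
  best <- NULL
  blen <- -1L
  states <- 0L
  rec <- function(v) {
    states <<- states + 1L
    plen <<- plen + 1L
    path[plen] <<- v
    onpath[v] <<- TRUE
    if (v == e) {
      if (plen > blen) { best <<- path[seq_len(plen)]; blen <<- plen }
    } else if (states < max_states || is.null(best)) {
      for (w in adj[[v]]) if (!onpath[w]) rec(w)
    }
    onpath[v] <<- FALSE
    plen <<- plen - 1L
  }
  rec(s)
  if (is.null(best))
    stop("no path between the START and END particles (molecule not connected)")
  new_chain_path(best, oriented = TRUE)
}
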