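#' Specify a start-to-end line for a 3D tube
#'
#' A line specification gives the spatial anchor of one linear molecule tube:
#' the 3D position the first main-chain particle is pinned to, the position
#' the chain grows toward, and the requested bond length between consecutive
#' main-chain particles. All quantities are in box-length units.
#'
#' @param start,end numeric length-3 points; must differ.
#' @param bond_length positive spacing between consecutive main-chain
#'   particles (default 1).
#' @return A `line_spec` object.
#' @export
line_spec <- function(start, end, bond_length = 1) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 3L || length(end) != 3L || anyNA(start) || anyNA(end))
    stop("'start' and 'end' must be numeric 3D points")
  if (all(start == end))
    stop("degenerate line: start and end coincide (no direction exists)")
  bond_length <- as.numeric(bond_length)
  if (length(bond_length) != 1L || is.na(bond_length) || bond_length <= 0)
    stop("'bond_length' must be a positive number")
  structure(list(start = start, end = end, bond_length = bond_length),
            class = "line_spec")
}

#' @export
print.line_spec <- function(x, ...) {
  cat(sprintf("<line_spec: (%g, %g, %g) -> (%g, %g, %g), bond length %g>\n",
              x$start[1], x$start[2], x$start[3],
              x$end[1], x$end[2], x$end[3], x$bond_length))
  invisible(x)
}

# nearest main-chain host (by bond-count distance) for every node, ties
# broken toward the lower main-chain position index. Multi-source BFS with
# sources queued in chain order gives exactly that tie-break.
#' @keywords internal
nearest_chain_host <- function(adj, chain_nodes) {
  n <- length(adj)
  host <- rep(NA_integer_, n)   # main-chain position index (1..m) per node
  queue <- integer(n)
  head <- 1L; tail <- 0L
  for (k in seq_along(chain_nodes)) {
    v <- chain_nodes[k]
    host[v] <- k
    tail <- tail + 1L; queue[tail] <- v
  }
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    for (w in adj[[u]]) {
      if (is.na(host[w])) {
        host[w] <- host[u]
        tail <- tail + 1L; queue[tail] <- w
      }
    }
  }
  host
}

#' Map a molecule onto a straight line as a 3D tube
#'
#' Converts a single-part molecule topology into a linear 3D tube: the main
#' chain — the oriented longest chain when the part carries a START/END tag
#' pair, otherwise the double-DFS longest chain — is lined up along the
#' start-to-end line, and every side-chain particle is collapsed onto the
#' exact position of its nearest main-chain particle (nearest by bond-count
#' distance; ties toward the lower chain position). Coinciding particles are
#' intentional: mesoscopic simulations use soft potentials, so particles may
#' occupy the same exact spatial position.
#'
#' The first main-chain particle always sits exactly at `line$start`. With
#' `m` main-chain particles and line length `L`, the realized spacing is
#' `bond_length` when `(m-1) * bond_length <= L` (the tube then ends at or
#' short of `line$end`), and the tube is squeezed to a uniform `L / (m-1)`
#' otherwise. A single-particle molecule is placed at `line$start` with an
#' effective bond length of 0.
#'
#' @param mol a single-part `spices_molecule`.
#' @param line a [line_spec()].
#' @return A `tube_mapping`: list with `positions` (numeric n x 3 matrix, one
#'   row per particle in notation order), `main_chain` (a `chain_path`),
#'   `effective_bond_length` (realized spacing) and `hosts` (main-chain
#'   position index each particle collapses to).
#' @examples
#' mol <- parse_spices("A-B-C")
#' map_molecule_to_line(mol, line_spec(c(0, 0, 0), c(10, 0, 0)))$positions
#' @export
map_molecule_to_line <- function(mol, line) {
  stopifnot(inherits(mol, "spices_molecule"), inherits(line, "line_spec"))
  if (mol$parts != 1L)
    stop("molecule must be a single connected part; see connected_parts()")
  has_pair <- any(mol$nodes$start) && any(mol$nodes$end)
  chain <- if (has_pair) longest_chain_oriented(mol) else longest_chain(mol)
  tube_mapping_for_chain(mol, chain, line)
}

#' @keywords internal
tube_mapping_for_chain <- function(mol, chain, line, adj = adjacency_list(mol)) {
  m <- length(chain$nodes)
  d <- line$end - line$start
  L <- sqrt(sum(d * d))
  unit <- d / L
  spacing <- if (m == 1L) 0 else min(line$bond_length, L / (m - 1))
  hosts <- nearest_chain_host(adj, chain$nodes)
  if (anyNA(hosts)) stop("molecule is not connected")
  n <- nrow(mol$nodes)
  t_along <- (hosts - 1L) * spacing
  positions <- cbind(line$start[1L] + t_along * unit[1L],
                     line$start[2L] + t_along * unit[2L],
                     line$start[3L] + t_along * unit[3L])
  colnames(positions) <- c("x", "y", "z")
  structure(list(positions = positions, main_chain = chain,
                 effective_bond_length = spacing, hosts = hosts),
            class = "tube_mapping")
}

#' @export
print.tube_mapping <- function(x, ...) {
  cat(sprintf(
    "<tube_mapping: %d particles, %d on the main chain, spacing %g>\n",
    nrow(x$positions), length(x$main_chain$nodes), x$effective_bond_length))
  invisible(x)
}

#' Particle positions and bond-offset records for one molecule
#'
#' Turns a molecule plus its tube mapping into the per-particle records a
#' simulation kernel consumes: one record per particle in notation order with
#' its name, x/y/z position, the signed record-index offsets to every bonded
#' partner, and a force index (0 unless supplied). Offsets are mutually
#' consistent: if record `i` lists offset `d`, record `i + d` lists `-d`.
#'
#' @param mol a `spices_molecule`.
#' @param mapping a `tube_mapping` covering every particle of `mol`.
#' @param force_index optional integer vector (one non-negative entry per
#'   particle); default all 0.
#' @return A `box_record_table`: a data frame with columns `name`, `x`, `y`,
#'   `z`, `bond_offsets` (list column of sorted integer vectors) and
#'   `force_index`.
#' @examples
#' mol <- parse_spices("A-B")
#' mp <- map_molecule_to_line(mol, line_spec(c(0, 0, 0), c(5, 0, 0)))
#' particle_positions_and_connections(mol, mp)
#' @export
particle_positions_and_connections <- function(mol, mapping, force_index = NULL) {
  stopifnot(inherits(mol, "spices_molecule"), inherits(mapping, "tube_mapping"))
  n <- nrow(mol$nodes)
  if (nrow(mapping$positions) != n)
    stop("mapping does not cover every particle of the molecule")
  if (is.null(force_index)) {
    force_index <- integer(n)
  } else {
    force_index <- as.integer(force_index)
    if (length(force_index) != n || anyNA(force_index) || any(force_index < 0))
      stop("'force_index' must be one non-negative integer per particle")
  }
  new_box_record_table(name = mol$nodes$name,
                       xyz = mapping$positions,
                       bond_offsets = bond_offsets_list(mol$bonds, n),
                       force_index = force_index)
}

# list of sorted signed offsets per record index
#' @keywords internal
bond_offsets_list <- function(bonds, n) {
  off <- vector("list", n)
  for (v in seq_len(n)) off[[v]] <- integer(0)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[[r, 1L]]; j <- bonds[[r, 2L]]
      off[[i]] <- c(off[[i]], j - i)
      off[[j]] <- c(off[[j]], i - j)
    }
    off <- lapply(off, sort)
  }
  off
}
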