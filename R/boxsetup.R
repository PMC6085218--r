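#' Define a simulation box
#'
#' @param lengths three positive box extents (box-length units). The box
#'   corner sits at the origin; coordinates run over `[0, extent]` per axis.
#' @return A `simulation_box`.
#' @export
simulation_box <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3L || anyNA(lengths) || any(lengths <= 0))
    stop("'lengths' must be three positive extents")
  structure(list(lengths = lengths), class = "simulation_box")
}

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf("<simulation_box: %g x %g x %g>\n",
              x$lengths[1L], x$lengths[2L], x$lengths[3L]))
  invisible(x)
}

# One root seed, one independent substream per line, derived by counter
# offset so a line's geometry does not depend on how many lines precede it.
#' @keywords internal
derive_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 69069 + as.double(counter) * 30011
  as.integer(s %% 2147483647)
}

#' Randomly placed tube lines in a box
#'
#' Draws `n` line specifications with uniformly random start points inside the
#' box and uniformly random orientations (directions uniform on the sphere).
#' For each line the orientation is resampled (up to 1000 attempts) until the
#' end point also lies inside the box. Deterministic under `seed`: each line
#' uses its own substream derived from the root seed by counter offset.
#'
#' @param box a [simulation_box()].
#' @param n number of lines (>= 1).
#' @param tube_length line length; must not exceed the smallest box extent.
#' @param bond_length requested main-chain spacing stored on each line
#'   (default 1).
#' @param seed integer root seed.
#' @return A list of `n` [line_spec()] objects.
#' @export
random_lines <- function(box, n, tube_length, bond_length = 1, seed = 1L) {
  stopifnot(inherits(box, "simulation_box"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  if (tube_length <= 0) stop("'tube_length' must be positive")
  if (tube_length > min(box$lengths))
    stop("geometry error: tube_length exceeds the smallest box extent")
  ext <- box$lengths
  lines <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    start <- stats::runif(3) * ext
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      d <- stats::rnorm(3)
      nrm <- sqrt(sum(d * d))
      if (nrm < 1e-12) next
      end <- start + tube_length * d / nrm
      if (all(end >= 0 & end <= ext)) { ok <- TRUE; break }
    }
    if (!ok)
      stop(sprintf("geometry error: no in-box orientation found for line %d after 1000 attempts", i))
    lines[[i]] <- line_spec(start, end, bond_length)
  }
  lines
}

#' Bilayer-oriented tube lines in a box
#'
#' Draws `n` line specifications arranged as a bilayer around a midplane
#' perpendicular to `normal_axis`: `n/2` lines per leaflet, every line
#' parallel to the normal axis, running from the midplane-distal side toward
#' the midplane. The two leaflets are mirror images, so START-tagged head
#' particles (pinned to line starts) face away from the midplane on both
#' sides. Lateral positions are uniform under `seed`.
#'
#' @param box a [simulation_box()].
#' @param n even number of lines.
#' @param normal_axis 1, 2, 3 or "x", "y", "z": the bilayer normal.
#' @param midplane coordinate of the bilayer midplane along the normal axis.
#' @param tube_length leaflet thickness (line length); at most half the box
#'   extent along the normal axis, and `midplane +/- tube_length` must stay
#'   inside the box.
#' @param bond_length requested main-chain spacing stored on each line
#'   (default 1).
#' @param seed integer root seed.
#' @return A list of `n` [line_spec()] objects; the first `n/2` form the
#'   upper leaflet (starts at `midplane + tube_length`), the rest the lower.
#' @export
bilayer_lines <- function(box, n, normal_axis, midplane, tube_length,
                          bond_length = 1, seed = 1L) {
  stopifnot(inherits(box, "simulation_box"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L || n %% 2L != 0L)
    stop("geometry error: 'n' must be an even count >= 2")
  axis <- if (is.character(normal_axis)) match(tolower(normal_axis), c("x", "y", "z"))
          else as.integer(normal_axis)
  if (is.na(axis) || !(axis %in% 1:3)) stop("'normal_axis' must be 1..3 or x/y/z")
  ext <- box$lengths
  if (tube_length <= 0) stop("'tube_length' must be positive")
  if (tube_length > ext[axis] / 2)
    stop("geometry error: tube_length exceeds half the box extent along the normal axis")
  if (midplane - tube_length < 0 || midplane + tube_length > ext[axis])
    stop("geometry error: leaflet extends outside the box")
  lateral <- setdiff(1:3, axis)
  lines <- vector("list", n)
  half <- n %/% 2L
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    lat <- stats::runif(2) * ext[lateral]
    start <- end <- numeric(3)
    start[lateral] <- lat
    end[lateral] <- lat
    if (i <= half) {          # upper leaflet: start distal, run down to midplane
      start[axis] <- midplane + tube_length
      end[axis] <- midplane
    } else {                  # lower leaflet: mirror image
      start[axis] <- midplane - tube_length
      end[axis] <- midplane
    }
    lines[[i]] <- line_spec(start, end, bond_length)
  }
  lines
}

#' Project a molecule population into the simulation box
#'
#' Maps one molecule topology onto every supplied line and concatenates the
#' per-molecule record blocks in line order. Bond offsets are intra-block only
#' (molecules are independent bonded blocks; no inter-molecular bonds are
#' emitted). Force indices are assigned through the backbone-label
#' indirection: a particle whose backbone label appears in `force_map` gets
#' the mapped index, unlabeled particles get 0. In strict mode (the default) a
#' label present in the molecule but absent from a non-empty `force_map` is an
#' error; with `strict = FALSE` it falls back to 0.
#'
#' The molecule's main chain, collapse hosts and offset pattern are computed
#' once and reused across lines, so populations of tens of thousands of
#' molecules project in seconds.
#'
#' @param mol a single-part `spices_molecule`.
#' @param lines list of [line_spec()] objects (e.g. from [random_lines()] or
#'   [bilayer_lines()]).
#' @param force_map optional named integer vector mapping backbone labels to
#'   force indices.
#' @param strict error on a molecule label missing from a non-empty
#'   `force_map` (default `TRUE`).
#' @return A `box_record_table` with `n_particles(mol) * length(lines)`
#'   records.
#' @examples
#' mol <- parse_spices(fixture_dmpc())
#' box <- simulation_box(c(20, 20, 20))
#' tab <- project_population(mol, random_lines(box, 10, tube_length = 8, seed = 7))
#' nrow(tab)  # 160
#' @export
project_population <- function(mol, lines, force_map = NULL, strict = TRUE) {
  stopifnot(inherits(mol, "spices_molecule"))
  if (mol$parts != 1L)
    stop("molecule must be a single connected part; see connected_parts()")
  if (!length(lines)) return(empty_record_table())
  if (!all(vapply(lines, inherits, logical(1L), "line_spec")))
    stop("'lines' must be a list of line_spec objects")

  # per-particle force indices from the backbone-label indirection
  n <- nrow(mol$nodes)
  force_index <- integer(n)
  labels <- mol$nodes$backbone_label
  if (!is.null(force_map) && length(force_map)) {
    if (is.null(names(force_map)) || any(!nzchar(names(force_map))))
      stop("'force_map' must be a named vector (backbone label -> force index)")
    labeled <- which(!is.na(labels))
    miss <- setdiff(labels[labeled], names(force_map))
    if (length(miss) && strict)
      stop(sprintf("backbone label(s) missing from force_map: %s",
                   paste(sort(miss), collapse = ", ")))
    hit <- labeled[labels[labeled] %in% names(force_map)]
    force_index[hit] <- as.integer(force_map[labels[hit]])
    if (anyNA(force_index) || any(force_index < 0))
      stop("'force_map' values must be non-negative integers")
  }

  # topology template, shared by every line
  adj <- adjacency_list(mol)
  has_pair <- any(mol$nodes$start) && any(mol$nodes$end)
  chain <- if (has_pair) longest_chain_oriented(mol) else longest_chain(mol)
  m <- length(chain$nodes)
  hosts <- nearest_chain_host(adj, chain$nodes)
  if (anyNA(hosts)) stop("molecule is not connected")
  cc <- hosts - 1L                       # chain coordinate per particle
  offsets <- bond_offsets_list(mol$bonds, n)

  nl <- length(lines)
  starts <- t(vapply(lines, function(l) l$start, numeric(3L)))
  ends   <- t(vapply(lines, function(l) l$end, numeric(3L)))
  bls    <- vapply(lines, function(l) l$bond_length, numeric(1L))
  d <- ends - starts
  L <- sqrt(rowSums(d * d))
  spacing <- if (m == 1L) rep(0, nl) else pmin(bls, L / (m - 1))
  su <- d * (spacing / L)                # spacing * unit direction, per line

  # coords[particle, line] per axis, flattened line-major into record blocks
  xyz <- matrix(NA_real_, n * nl, 3L)
  for (a in 1:3)
    xyz[, a] <- as.vector(outer(cc, su[, a]) +
                          matrix(starts[, a], nrow = n, ncol = nl, byrow = TRUE))
  new_box_record_table(name = rep(mol$nodes$name, times = nl),
                       xyz = xyz,
                       bond_offsets = rep(offsets, times = nl),
                       force_index = rep(force_index, times = nl))
}
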