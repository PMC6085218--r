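#' DMPC phospholipid fixture
#'
#' The reference fragmentation of the DMPC phospholipid into 16 particles: a
#' START-tagged choline head (`TriMeNP`), the phosphate/glycerol particle
#' (`DMPN`), a side branch of one ester (`MeAc`) followed by six chained
#' ethylene (`Et`) particles, and a main chain continuing with the second
#' ester and six `Et` particles, the last of which carries the END tag. The
#' topology is a tree (15 bonds); the oriented main chain has 9 particles and
#' mapping the molecule onto a line collapses the whole side tail onto the
#' second main-chain position.
#'
#' @return A SPICES string.
#' @examples
#' n_particles(parse_spices(fixture_dmpc()))  # 16
#' @export
fixture_dmpc <- function() {
  "TriMeNP[START]-DMPN(-MeAc-6Et)-MeAc-5Et-Et[END]"
}

#' Fused-ring sterol-like fixture with backbone labels
#'
#' A synthetic structural analog of a sterol fragmentation: 17 particles, each
#' carrying a backbone label `'1'` to `'17'`, with two ring closures giving
#' two independent cycles (a fused-ring core) plus a short tail. It exercises
#' backbone labels and cyclic topology together; it is an analog for testing,
#' not a verbatim fragmentation of cholesterol.
#'
#' @return A SPICES string.
#' @examples
#' sum(!is.na(parse_spices(fixture_cholesterol_like())$nodes$backbone_label))  # 17
#' @export
fixture_cholesterol_like <- function() {
  paste0("MeOH'1'-Me'2'-Me'3'[1]-Me'4'-Me'5'-Me'6'[2]-Me'7'-Me'8'-Me'9'[1]",
         "-Me'10'-Me'11'[2]-Me'12'-Me'13'-Me'14'-Et'15'-Et'16'-Me'17'")
}

#' Seeded random molecule generator
#'
#' Generates a valid single-part SPICES string with exactly `n_particles`
#' particles for property testing. A random tree is grown (each new particle
#' attaches to the previous one, or with probability `branch_prob` to a
#' uniformly chosen earlier particle), then each particle independently adds
#' a ring-closure bond to a random non-adjacent earlier particle with
#' probability `ring_prob`. Optionally particles receive backbone labels
#' (probability `label_prob` each) and, with probability `tag_prob`, one
#' START/END pair is placed on two distinct particles. The graph is emitted
#' through [serialize_spices()], so the output always validates.
#'
#' @param n_particles number of particles (>= 1).
#' @param branch_prob probability a new particle attaches to a random earlier
#'   particle instead of extending the chain.
#' @param ring_prob per-particle probability of one extra ring-closure bond;
#'   0 guarantees a tree.
#' @param alphabet particle names to draw from.
#' @param seed integer seed; same inputs and seed give the identical string.
#' @param label_prob per-particle backbone-label probability.
#' @param tag_prob probability of placing a START/END tag pair (needs
#'   `n_particles >= 2`).
#' @return A SPICES string.
#' @examples
#' random_molecule(8, seed = 42)
#' @export
random_molecule <- function(n_particles, branch_prob = 0.3, ring_prob = 0,
                            alphabet = c("Et", "Me", "MeAc", "DMPN", "W"),
                            seed = 1L, label_prob = 0, tag_prob = 0) {
  n_particles <- as.integer(n_particles)
  if (is.na(n_particles) || n_particles < 1L) stop("'n_particles' must be >= 1")
  stopifnot(branch_prob >= 0, branch_prob <= 1, ring_prob >= 0, ring_prob <= 1,
            label_prob >= 0, label_prob <= 1, tag_prob >= 0, tag_prob <= 1)
  if (!length(alphabet) || !all(grepl("^[A-Za-z][A-Za-z0-9]*$", alphabet)))
    stop("'alphabet' entries must be letter-initial alphanumeric names")
  set.seed(derive_seed(seed, 0L))
  n <- n_particles
  name <- sample(alphabet, n, replace = TRUE)
  bonds <- list()
  bonded <- function(i, j) any(vapply(bonds, function(b)
    all(sort(b) == sort(c(i, j))), logical(1L)))
  if (n > 1L) {
    for (v in 2:n) {
      parent <- if (stats::runif(1) < branch_prob) sample.int(v - 1L, 1L) else v - 1L
      bonds[[length(bonds) + 1L]] <- c(parent, v)
    }
    if (ring_prob > 0 && n >= 3L) {
      for (v in 3:n) {
        if (length(bonds) && stats::runif(1) < ring_prob) {
          cand <- setdiff(seq_len(v - 1L), v)
          cand <- cand[!vapply(cand, bonded, logical(1L), j = v)]
          if (length(cand))
            bonds[[length(bonds) + 1L]] <- c(sample(cand, 1L), v)
        }
      }
    }
  }
  label <- rep(NA_character_, n)
  pick <- stats::runif(n) < label_prob
  label[pick] <- as.character(which(pick))
  tagS <- tagE <- logical(n)
  if (n >= 2L && stats::runif(1) < tag_prob) {
    st <- sample.int(n, 2L)
    tagS[st[1L]] <- TRUE
    tagE[st[2L]] <- TRUE
  }
  nodes <- data.frame(name = name, part = 1L, backbone_label = label,
                      start = tagS, end = tagE, stringsAsFactors = FALSE)
  serialize_spices(new_spices_molecule(nodes, bonds, 1L))
}

#' Read SPICES strings from a batch file
#'
#' One molecule per line; empty lines and `#`-prefixed comment lines are
#' ignored.
#'
#' @param path file path or connection.
#' @return A character vector of SPICES strings.
#' @export
read_spices_lines <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines, which = "right")
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a particle catalog
#'
#' Reads a two-column tab-separated table of particle names and free-text
#' descriptions. `#`-prefixed lines are comments.
#'
#' @param path file path or connection.
#' @return A data frame with columns `name` and `description`; the `name`
#'   column is suitable as the `catalog` argument of [parse_spices()].
#' @export
read_particle_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1L)) < 1L)
  name <- vapply(parts, `[`, character(1L), 1L)
  if (any(!grepl("^[A-Za-z][A-Za-z0-9]*$", name)))
    stop("catalog contains an invalid particle name")
  desc <- vapply(parts, function(f) if (length(f) >= 2L) f[2L] else "", character(1L))
  data.frame(name = name, description = desc, stringsAsFactors = FALSE)
}
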