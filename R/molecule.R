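#' @keywords internal
new_spices_molecule <- function(nodes, bonds, parts, source_text = NULL) {
  stopifnot(is.data.frame(nodes),
            all(c("name", "part", "backbone_label", "start", "end") %in% names(nodes)))
  bonds <- normalize_bonds(bonds)
  structure(list(nodes = nodes, bonds = bonds, parts = as.integer(parts),
                 source_text = source_text),
            class = "spices_molecule")
}

# canonical bond storage: integer matrix, 2 columns, each row i < j,
# rows sorted by (i, j), duplicates removed
#' @keywords internal
normalize_bonds <- function(bonds) {
  if (is.null(bonds) || (is.matrix(bonds) && nrow(bonds) == 0L) || length(bonds) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  if (is.list(bonds)) bonds <- do.call(rbind, bonds)
  storage.mode(bonds) <- "integer"
  b <- cbind(pmin(bonds[, 1L], bonds[, 2L]), pmax(bonds[, 1L], bonds[, 2L]))
  b <- unique(b)
  b <- b[order(b[, 1L], b[, 2L]), , drop = FALSE]
  dimnames(b) <- list(NULL, c("i", "j"))
  b
}

#' Number of particles in a molecule
#' @param mol a `spices_molecule`.
#' @return Integer particle (node) count.
#' @export
n_particles <- function(mol) {
  stopifnot(inherits(mol, "spices_molecule"))
  nrow(mol$nodes)
}

#' Number of bonds in a molecule
#' @param mol a `spices_molecule`.
#' @return Integer bond count.
#' @export
n_bonds <- function(mol) {
  stopifnot(inherits(mol, "spices_molecule"))
  nrow(mol$bonds)
}

#' @export
print.spices_molecule <- function(x, ...) {
  cat(sprintf("<spices_molecule: %d particle%s, %d bond%s, %d part%s>\n",
              nrow(x$nodes), if (nrow(x$nodes) == 1L) "" else "s",
              nrow(x$bonds), if (nrow(x$bonds) == 1L) "" else "s",
              x$parts, if (x$parts == 1L) "" else "s"))
  if (!is.null(x$source_text))
    cat("  notation: ", x$source_text, "\n", sep = "")
  freq <- sort(table(x$nodes$name), decreasing = TRUE)
  cat("  particles:", paste(sprintf("%s x%d", names(freq), as.integer(freq)),
                            collapse = ", "), "\n")
  invisible(x)
}

# adjacency list (sorted neighbor indices) for a molecule
#' @keywords internal
adjacency_list <- function(mol) {
  n <- nrow(mol$nodes)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  b <- mol$bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      i <- b[r, 1L]; j <- b[r, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, sort)
  }
  adj
}

# check all structural invariants of a spices_molecule; stop() naming the
# violated invariant, invisibly TRUE otherwise
#' @keywords internal
validate_molecule <- function(mol) {
  if (!inherits(mol, "spices_molecule")) stop("not a spices_molecule")
  nd <- mol$nodes
  n <- nrow(nd)
  if (n == 0L) stop("invariant violated: molecule has no particles")
  if (!all(grepl("^[A-Za-z][A-Za-z0-9]*$", nd$name)))
    stop("invariant violated: particle name must be a letter followed by letters/digits")
  lab <- nd$backbone_label
  if (any(!is.na(lab) & !nzchar(lab)))
    stop("invariant violated: backbone label must be non-empty")
  if (any(nd$start & nd$end))
    stop("invariant violated: a particle carries at most one of START, END")
  b <- mol$bonds
  if (nrow(b)) {
    if (any(b < 1L) || any(b > n))
      stop("invariant violated: bond references a nonexistent particle")
    if (any(b[, 1L] == b[, 2L]))
      stop("invariant violated: self-bond")
    if (anyDuplicated(b))
      stop("invariant violated: duplicate bond")
    if (any(nd$part[b[, 1L]] != nd$part[b[, 2L]]))
      stop("invariant violated: bond spans two parts")
  }
  if (!all(sort(unique(nd$part)) == seq_len(mol$parts)))
    stop("invariant violated: part indices must be consecutive 1..parts")
  if (is.unsorted(nd$part))
    stop("invariant violated: parts must be contiguous in notation order")
  for (p in seq_len(mol$parts)) {
    in_p <- nd$part == p
    if (sum(nd$start[in_p]) > 1L)
      stop("invariant violated: more than one START tag in a part")
    if (sum(nd$end[in_p]) > 1L)
      stop("invariant violated: more than one END tag in a part")
    # connectivity of the part
    idx <- which(in_p)
    if (length(idx) > 1L) {
      sub <- b[in_p[b[, 1L]], , drop = FALSE]
      remap <- integer(n); remap[idx] <- seq_along(idx)
      adj <- vector("list", length(idx))
      for (v in seq_along(idx)) adj[[v]] <- integer(0)
      if (nrow(sub)) {
        for (r in seq_len(nrow(sub))) {
          i <- remap[sub[r, 1L]]; j <- remap[sub[r, 2L]]
          adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
        }
      }
      seen <- logical(length(idx)); seen[1L] <- TRUE
      queue <- 1L
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
      if (!all(seen))
        stop("invariant violated: part is not internally connected")
    }
  }
  invisible(TRUE)
}
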