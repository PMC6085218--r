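#' @keywords internal
new_box_record_table <- function(name, xyz, bond_offsets, force_index) {
  n <- length(name)
  stopifnot(nrow(xyz) == n, length(bond_offsets) == n, length(force_index) == n)
  df <- data.frame(name = name,
                   x = as.numeric(xyz[, 1L]),
                   y = as.numeric(xyz[, 2L]),
                   z = as.numeric(xyz[, 3L]),
                   force_index = as.integer(force_index),
                   stringsAsFactors = FALSE)
  df$bond_offsets <- bond_offsets
  df <- df[, c("name", "x", "y", "z", "bond_offsets", "force_index")]
  class(df) <- c("box_record_table", "data.frame")
  df
}

#' Create an empty record table
#'
#' @return A `box_record_table` with zero records.
#' @export
empty_record_table <- function() {
  new_box_record_table(character(0),
                       matrix(numeric(0), ncol = 3L),
                       list(), integer(0))
}

#' @export
print.box_record_table <- function(x, ...) {
  cat(sprintf("<box_record_table: %d records>\n", nrow(x)))
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x), 10L)
    show$bond_offsets <- vapply(show$bond_offsets, format_offsets, character(1L))
    print(show)
    if (nrow(x) > 10L) cat(sprintf("  ... %d more records\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' @keywords internal
format_offsets <- function(off) {
  if (!length(off)) "" else paste(sprintf("%+d", off), collapse = ",")
}

#' Write particle records as a tabular ASCII simulation-input file
#'
#' Writes one record per line in the kernel-input dialect of this package:
#' `#`-prefixed header lines carrying the record count and (when a box is
#' given) the box extents, then tab-separated fields `name`, `x`, `y`, `z`
#' (fixed 6-decimal notation), the comma-joined signed bond offsets (empty
#' field for an unbonded particle) and the force index. With a box and
#' `clamp = TRUE` coordinates are clamped inclusively into `[0, extent]` per
#' axis before writing. `read_box_table(write_box_table(t))` reproduces `t`
#' exactly at the printed coordinate precision, and a write/read/write cycle
#' is a byte fixpoint.
#'
#' @param table a `box_record_table`.
#' @param path file path or connection to write to.
#' @param box optional [simulation_box()] recorded in the header.
#' @param clamp clamp coordinates into the box on write (default: yes when a
#'   box is given).
#' @return `path`, invisibly.
#' @export
write_box_table <- function(table, path, box = NULL, clamp = !is.null(box)) {
  stopifnot(inherits(table, "box_record_table"))
  if (clamp && is.null(box)) stop("clamping requires a 'box'")
  header <- c("# spices particle records",
              sprintf("# records\t%d", nrow(table)))
  if (!is.null(box)) {
    stopifnot(inherits(box, "simulation_box"))
    header <- c(header, sprintf("# box\t%.6f\t%.6f\t%.6f",
                                box$lengths[1L], box$lengths[2L], box$lengths[3L]))
  }
  if (nrow(table)) {
    xyz <- cbind(table$x, table$y, table$z)
    if (clamp) {
      for (a in 1:3) xyz[, a] <- pmin(pmax(xyz[, a], 0), box$lengths[a])
    }
    body <- sprintf("%s\t%.6f\t%.6f\t%.6f\t%s\t%d",
                    table$name, xyz[, 1L], xyz[, 2L], xyz[, 3L],
                    vapply(table$bond_offsets, format_offsets, character(1L)),
                    table$force_index)
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read particle records from a tabular ASCII simulation-input file
#'
#' Parses the dialect written by [write_box_table()]. Malformed lines raise a
#' positional error naming the line number and field.
#'
#' @param path file path or connection to read from.
#' @return A `box_record_table`; when the header carries box extents they are
#'   attached as attribute `"box"` (a [simulation_box()]).
#' @export
read_box_table <- function(path) {
  lines <- readLines(path)
  box <- NULL
  is_header <- startsWith(lines, "#")
  for (h in lines[is_header]) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1L]]
    if (f[1L] == "# box") {
      if (length(f) != 4L) stop("malformed '# box' header line")
      box <- simulation_box(as.numeric(f[2:4]))
    }
  }
  data_idx <- which(!is_header & nzchar(lines))
  n <- length(data_idx)
  name <- character(n); xyz <- matrix(NA_real_, n, 3L)
  offs <- vector("list", n); fidx <- integer(n)
  for (k in seq_len(n)) {
    ln <- data_idx[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    # a trailing empty offsets field may be dropped by strsplit only when it
    # is final; offsets is field 5 of 6, so length must be 6
    if (length(f) != 6L)
      stop(sprintf("line %d: expected 6 tab-separated fields, found %d",
                   ln, length(f)))
    if (!grepl("^[A-Za-z][A-Za-z0-9]*$", f[1L]))
      stop(sprintf("line %d, field 1: invalid particle name '%s'", ln, f[1L]))
    name[k] <- f[1L]
    for (a in 1:3) {
      val <- suppressWarnings(as.numeric(f[1L + a]))
      if (is.na(val))
        stop(sprintf("line %d, field %d: not a coordinate: '%s'", ln, 1L + a, f[1L + a]))
      xyz[k, a] <- val
    }
    if (nzchar(f[5L])) {
      if (!grepl("^[+-][0-9]+(,[+-][0-9]+)*$", f[5L]))
        stop(sprintf("line %d, field 5: malformed bond offsets '%s'", ln, f[5L]))
      offs[[k]] <- sort(as.integer(strsplit(f[5L], ",", fixed = TRUE)[[1L]]))
    } else {
      offs[[k]] <- integer(0)
    }
    fi <- suppressWarnings(as.integer(f[6L]))
    if (is.na(fi) || fi < 0L)
      stop(sprintf("line %d, field 6: invalid force index '%s'", ln, f[6L]))
    fidx[k] <- fi
  }
  out <- new_box_record_table(name, xyz, offs, fidx)
  if (!is.null(box)) attr(out, "box") <- box
  out
}
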