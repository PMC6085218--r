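#' Validate a SPICES string
#'
#' Checks a string against the SPICES grammar and returns a parse report
#' listing every problem found with its position. `validate_spices()` never
#' raises a condition: all problems are data. Unlike [parse_spices()], the
#' validator recovers after each error and keeps scanning so that multiple
#' problems are reported in one pass.
#'
#' @param text a single character string.
#' @return A `parse_report`: a list with `valid` (logical) and `errors`, a
#'   data frame with columns `position` (0-based character offset), `length`
#'   (characters covered) and `message`.
#' @examples
#' validate_spices("Et-Et")            # valid
#' validate_spices("A(-B")             # unclosed branch
#' validate_spices("A-B[1]")           # unmatched ring-closure label
#' @export
validate_spices <- function(text) {
  res <- parse_impl(text)
  new_parse_report(res$errors, text)
}

#' Parse a SPICES string into a molecule graph
#'
#' Builds the particle graph described by a SPICES line notation: particles in
#' notation order, bonds from chain adjacency, branches (bonding to the
#' particle preceding the branch) and ring-closure label pairs; independent
#' parts split at `.`; backbone labels and `[START]`/`[END]` tags attached to
#' the immediately preceding particle; repeat prefixes (`6Et`) expanded to
#' linearly chained copies.
#'
#' @param text a single character string in SPICES notation.
#' @param catalog optional character vector of allowed particle names; when
#'   supplied, any particle name outside the catalog is an error.
#' @return A `spices_molecule`: a list with `nodes` (data frame with columns
#'   `name`, `part`, `backbone_label`, `start`, `end`, one row per particle in
#'   notation order, 1-based indices), `bonds` (two-column integer matrix of
#'   node index pairs), `parts` (part count) and `source_text`.
#' @seealso [validate_spices()] for non-raising diagnostics,
#'   [serialize_spices()] for the inverse operation.
#' @examples
#' mol <- parse_spices("TriMeNP[START]-DMPN(-MeAc-6Et)-MeAc-5Et-Et[END]")
#' n_particles(mol)  # 16
#' parse_spices("A-B[1]-C-D[1]")  # a 4-cycle
#' @export
parse_spices <- function(text, catalog = NULL) {
  res <- parse_impl(text)
  if (length(res$errors)) {
    report <- new_parse_report(res$errors, text)
    e <- report$errors[1L, ]
    stop(structure(
      class = c("spices_parse_error", "error", "condition"),
      list(message = sprintf("invalid SPICES at offset %d: %s", e$position, e$message),
           call = sys.call(-1L), report = report)))
  }
  mol <- res$molecule
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(mol$nodes$name), catalog)
    if (length(unknown)) {
      stop(structure(
        class = c("spices_unknown_particle", "error", "condition"),
        list(message = sprintf("unknown particle name(s): %s",
                               paste(unknown, collapse = ", ")),
             call = sys.call(-1L), names = unknown)))
    }
  }
  mol
}

#' @keywords internal
new_parse_report <- function(errors, text) {
  if (length(errors)) {
    df <- data.frame(
      position = vapply(errors, function(e) as.integer(e$pos), integer(1L)),
      length   = vapply(errors, function(e) as.integer(e$len), integer(1L)),
      message  = vapply(errors, function(e) e$message, character(1L)),
      stringsAsFactors = FALSE)
    df <- df[order(df$position), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(position = integer(0), length = integer(0),
                     message = character(0), stringsAsFactors = FALSE)
  }
  structure(list(valid = nrow(df) == 0L, errors = df, text = text),
            class = "parse_report")
}

#' @export
print.parse_report <- function(x, ...) {
  if (x$valid) {
    cat("<parse_report: valid>\n")
  } else {
    cat(sprintf("<parse_report: invalid, %d error%s>\n", nrow(x$errors),
                if (nrow(x$errors) == 1L) "" else "s"))
    for (r in seq_len(nrow(x$errors)))
      cat(sprintf("  offset %d: %s\n", x$errors$position[r], x$errors$message[r]))
  }
  invisible(x)
}

# Single-pass recursive-descent state machine over the token stream.
# Collects every error (validator semantics); parse_spices() raises on the
# first. Returns list(molecule = <spices_molecule or NULL>, errors = list).
#' @keywords internal
parse_impl <- function(text) {
  toks <- tokenize_spices(text)
  errors <- list()
  add_err <- function(pos, len, msg)
    errors[[length(errors) + 1L]] <<- list(pos = pos, len = len, message = msg)

  # node accumulators
  nm <- character(0); pt <- integer(0); lb <- character(0)
  tS <- logical(0); tE <- logical(0); rep_flag <- logical(0)
  bonds <- list()
  bond_key <- new.env(parent = emptyenv())  # duplicate-bond detection

  add_bond <- function(i, j, pos, len) {
    if (i == j) { add_err(pos, len, "ring closure bonds a particle to itself"); return(invisible()) }
    key <- paste(min(i, j), max(i, j))
    if (!is.null(bond_key[[key]])) {
      add_err(pos, len, "duplicate bond")
    } else {
      bond_key[[key]] <- TRUE
      bonds[[length(bonds) + 1L]] <<- c(i, j)
    }
  }
  add_node <- function(name, part) {
    nm <<- c(nm, name); pt <<- c(pt, part); lb <<- c(lb, NA_character_)
    tS <<- c(tS, FALSE); tE <<- c(tE, FALSE); rep_flag <<- c(rep_flag, FALSE)
    length(nm)
  }

  cur_part <- 1L
  part_has_node <- FALSE
  part_start_seen <- FALSE
  part_end_seen <- FALSE
  ring_open <- list()          # label -> list(node, pos, len)
  stack <- list()              # open branches: list(owner, pos)
  attach <- NA_integer_        # particle the next bonded particle attaches to
  cur <- NA_integer_           # particle postfix tokens apply to
  mode <- "part_start"         # part_start | after_dash | branch_open | postfix
  dash_pos <- NA_integer_

  end_part <- function(pos) {
    # called at '.' or end of input; pos: 0-based offset for structural errors
    if (length(stack)) {
      for (s in stack) add_err(s$pos, 1L, "unclosed branch")
      stack <<- list()
    }
    if (length(ring_open)) {
      for (labname in names(ring_open)) {
        ro <- ring_open[[labname]]
        add_err(ro$pos, ro$len,
                sprintf("unmatched ring closure label %s", labname))
      }
      ring_open <<- list()
    }
    if (!part_has_node) {
      if (cur_part == 1L && length(toks) == 0L)
        add_err(0L, 0L, "empty SPICES string")
      else
        add_err(pos, 0L, "empty part")
    }
  }

  emit_particles <- function(t_name, count, is_repeat) {
    # create count chained copies bonding the first to `attach` (if any)
    first <- NA_integer_
    for (q in seq_len(count)) {
      v <- add_node(t_name$value, cur_part)
      if (q == 1L) first <- v
      if (!is.na(attach)) add_bond(attach, v, t_name$pos, t_name$len)
      attach <<- v
    }
    rep_flag[length(nm)] <<- is_repeat
    cur <<- attach
    part_has_node <<- TRUE
    mode <<- "postfix"
  }

  i <- 1L
  nt <- length(toks)
  while (i <= nt) {
    t <- toks[[i]]
    advance <- TRUE
    if (t$type == "error") {
      add_err(t$pos, t$len, t$message)
      i <- i + 1L
      next
    }
    if (mode %in% c("part_start", "after_dash")) {
      if (t$type == "name") {
        emit_particles(t, 1L, FALSE)
      } else if (t$type == "repeat") {
        if (i + 1L <= nt && toks[[i + 1L]]$type == "name") {
          emit_particles(toks[[i + 1L]], t$value, TRUE)
          i <- i + 1L  # consume the name too
        } else {
          add_err(t$pos, t$len, "repeat count must be followed by a particle name")
        }
      } else if (mode == "after_dash") {
        add_err(dash_pos, 1L, "dangling bond separator")
        mode <- if (part_has_node) "postfix" else "part_start"
        advance <- FALSE  # reprocess this token in the recovered mode
      } else { # mode part_start, non-particle token
        if (t$type == "dash") {
          add_err(t$pos, t$len, "bond separator at start of part")
          dash_pos <- t$pos
          mode <- "after_dash"
        } else if (t$type == "dot") {
          end_part(t$pos)
          cur_part <- cur_part + 1L
          part_has_node <- FALSE; part_start_seen <- FALSE; part_end_seen <- FALSE
          attach <- NA_integer_; cur <- NA_integer_
        } else if (t$type == "lparen") {
          add_err(t$pos, t$len, "branch must follow a particle")
        } else if (t$type == "rparen") {
          add_err(t$pos, t$len, "unmatched ')'")
        } else {
          add_err(t$pos, t$len, "label, tag or ring closure must follow a particle")
        }
      }
    } else if (mode == "branch_open") {
      if (t$type == "dash") {
        dash_pos <- t$pos
        mode <- "after_dash"
      } else if (t$type == "rparen") {
        s <- stack[[length(stack)]]
        add_err(s$pos, 2L, "empty branch")
        stack[[length(stack)]] <- NULL
        attach <- s$owner; cur <- s$owner
        mode <- "postfix"
      } else if (t$type %in% c("name", "repeat")) {
        add_err(t$pos, t$len, "expected '-' after '('")
        mode <- "after_dash"
        dash_pos <- t$pos
        advance <- FALSE
      } else {
        add_err(t$pos, t$len, "expected '-' after '('")
      }
    } else { # postfix
      if (t$type == "label") {
        if (rep_flag[cur]) {
          add_err(t$pos, t$len, "backbone label may not follow a repeat group")
        } else if (!is.na(lb[cur])) {
          add_err(t$pos, t$len, "duplicate backbone label on one particle")
        } else {
          lb[cur] <- t$value
        }
      } else if (t$type == "tag_start") {
        if (rep_flag[cur]) add_err(t$pos, t$len, "tag may not follow a repeat group")
        else if (tS[cur] || tE[cur]) add_err(t$pos, t$len, "particle already carries a tag")
        else if (part_start_seen) add_err(t$pos, t$len, "duplicate [START] tag in part")
        else { tS[cur] <- TRUE; part_start_seen <- TRUE }
      } else if (t$type == "tag_end") {
        if (rep_flag[cur]) add_err(t$pos, t$len, "tag may not follow a repeat group")
        else if (tS[cur] || tE[cur]) add_err(t$pos, t$len, "particle already carries a tag")
        else if (part_end_seen) add_err(t$pos, t$len, "duplicate [END] tag in part")
        else { tE[cur] <- TRUE; part_end_seen <- TRUE }
      } else if (t$type == "ring") {
        key <- as.character(t$value)
        if (!is.null(ring_open[[key]])) {
          add_bond(ring_open[[key]]$node, cur, t$pos, t$len)
          ring_open[[key]] <- NULL
        } else {
          ring_open[[key]] <- list(node = cur, pos = t$pos, len = t$len)
        }
      } else if (t$type == "dash") {
        dash_pos <- t$pos
        mode <- "after_dash"
      } else if (t$type == "lparen") {
        stack[[length(stack) + 1L]] <- list(owner = cur, pos = t$pos)
        mode <- "branch_open"
      } else if (t$type == "rparen") {
        if (!length(stack)) {
          add_err(t$pos, t$len, "unmatched ')'")
        } else {
          s <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          attach <- s$owner; cur <- s$owner
        }
      } else if (t$type == "dot") {
        end_part(t$pos)
        cur_part <- cur_part + 1L
        part_has_node <- FALSE; part_start_seen <- FALSE; part_end_seen <- FALSE
        attach <- NA_integer_; cur <- NA_integer_
        mode <- "part_start"
      } else if (t$type %in% c("name", "repeat")) {
        add_err(t$pos, t$len, "missing bond separator before particle")
        mode <- "after_dash"
        dash_pos <- t$pos
        advance <- FALSE
      }
    }
    if (advance) i <- i + 1L
  }
  # end of input
  eof <- nchar(text)
  if (mode == "after_dash") add_err(dash_pos, 1L, "dangling bond separator")
  if (mode == "branch_open") add_err(eof, 0L, "expected '-' after '('")
  end_part(eof)

  mol <- NULL
  if (!length(errors)) {
    nodes <- data.frame(name = nm, part = pt, backbone_label = lb,
                        start = tS, end = tE, stringsAsFactors = FALSE)
    mol <- new_spices_molecule(nodes, bonds, cur_part, source_text = text)
  }
  list(molecule = mol, errors = errors)
}
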