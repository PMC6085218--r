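#' Tokenize a SPICES string
#'
#' Splits a SPICES line-notation string into lexical tokens. Tokenization is
#' total: unrecognized or malformed input produces `error` tokens rather than
#' raising a condition, so the validator can report every lexical problem with
#' its position.
#'
#' Token types are `name` (particle identifier, a letter followed by letters
#' or digits), `repeat` (a positive integer count prefixing a particle name,
#' `6Et` meaning six chained `Et` particles), `dash` (the bond separator `-`),
#' `lparen`/`rparen` (branch delimiters), `ring` (a bracketed positive integer
#' ring-closure label, e.g. `[1]`), `tag_start`/`tag_end` (`[START]`/`[END]`
#' orientation tags), `label` (a quoted backbone label, e.g. `'12'`), `dot`
#' (part separator) and `error`.
#'
#' @param text a single character string (possibly invalid SPICES).
#' @return A list of tokens. Each token is a list with elements `type`,
#'   `text` (the matched substring), `pos` (0-based character offset into
#'   `text`), `len` (length in characters), `value` (integer ring label or
#'   repeat count, character backbone label, otherwise `NA`) and, for `error`
#'   tokens, `message`.
#' @examples
#' tokenize_spices("Et-Et")
#' tokenize_spices("Me'12'")
#' @export
tokenize_spices <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string")
  chs <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chs)
  toks <- vector("list", n)
  k <- 0L
  add <- function(type, pos, len, txt, value = NA, message = NA_character_) {
    k <<- k + 1L
    toks[[k]] <<- list(type = type, text = txt, pos = pos, len = len,
                       value = value, message = message)
  }
  is_letter <- function(ch) grepl("^[A-Za-z]$", ch)
  is_digit  <- function(ch) grepl("^[0-9]$", ch)

  i <- 1L
  while (i <= n) {
    ch <- chs[i]
    p0 <- i - 1L  # 0-based offset
    code <- utf8ToInt(ch)
    if (is.na(code) || code > 127L) {
      add("error", p0, 1L, ch, message = "non-ASCII character")
      i <- i + 1L
    } else if (grepl("^[ \t\r\n]$", ch)) {
      add("error", p0, 1L, ch, message = "whitespace is not allowed")
      i <- i + 1L
    } else if (is_letter(ch)) {
      j <- i
      while (j < n && grepl("^[A-Za-z0-9]$", chs[j + 1L])) j <- j + 1L
      txt <- paste(chs[i:j], collapse = "")
      add("name", p0, j - i + 1L, txt, value = txt)
      i <- j + 1L
    } else if (is_digit(ch)) {
      j <- i
      while (j < n && is_digit(chs[j + 1L])) j <- j + 1L
      txt <- paste(chs[i:j], collapse = "")
      cnt <- suppressWarnings(as.integer(txt))
      if (is.na(cnt) || cnt < 1L) {
        add("error", p0, j - i + 1L, txt,
            message = "repeat count must be a positive integer")
      } else {
        add("repeat", p0, j - i + 1L, txt, value = cnt)
      }
      i <- j + 1L
    } else if (ch == "-") {
      add("dash", p0, 1L, ch); i <- i + 1L
    } else if (ch == "(") {
      add("lparen", p0, 1L, ch); i <- i + 1L
    } else if (ch == ")") {
      add("rparen", p0, 1L, ch); i <- i + 1L
    } else if (ch == ".") {
      add("dot", p0, 1L, ch); i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chs[j] != "]") j <- j + 1L
      if (j > n) {
        add("error", p0, n - i + 1L, paste(chs[i:n], collapse = ""),
            message = "unterminated '['")
        i <- n + 1L
      } else {
        content <- if (j == i + 1L) "" else paste(chs[(i + 1L):(j - 1L)], collapse = "")
        txt <- paste(chs[i:j], collapse = "")
        len <- j - i + 1L
        if (content == "START") {
          add("tag_start", p0, len, txt)
        } else if (content == "END") {
          add("tag_end", p0, len, txt)
        } else if (grepl("^[0-9]+$", content) && as.integer(content) >= 1L) {
          add("ring", p0, len, txt, value = as.integer(content))
        } else {
          add("error", p0, len, txt,
              message = "bracket must contain a positive ring-closure number, START or END")
        }
        i <- j + 1L
      }
    } else if (ch == "'") {
      j <- i + 1L
      while (j <= n && chs[j] != "'") j <- j + 1L
      if (j > n) {
        add("error", p0, n - i + 1L, paste(chs[i:n], collapse = ""),
            message = "unterminated backbone label quote")
        i <- n + 1L
      } else if (j == i + 1L) {
        add("error", p0, 2L, "''", message = "empty backbone label")
        i <- j + 1L
      } else {
        content <- paste(chs[(i + 1L):(j - 1L)], collapse = "")
        if (any(vapply(strsplit(content, "", fixed = TRUE)[[1L]],
                       function(x) utf8ToInt(x) > 127L, logical(1L)))) {
          add("error", p0, j - i + 1L, paste(chs[i:j], collapse = ""),
              message = "non-ASCII character in backbone label")
        } else {
          add("label", p0, j - i + 1L, paste(chs[i:j], collapse = ""),
              value = content)
        }
        i <- j + 1L
      }
    } else {
      add("error", p0, 1L, ch,
          message = sprintf("unexpected character '%s'", ch))
      i <- i + 1L
    }
  }
  toks[seq_len(k)]
}
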