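# Calendar-quarter helpers. Quarters are strings "YYYYQn" (e.g. "2016Q3");
# internally mapped to the integer index year*4 + quarter-1 so ranges and
# comparisons are ordinary arithmetic.

quarter_index <- function(q) {
  q <- toupper(trimws(as.character(q)))
  m <- regmatches(q, regexec("^([0-9]{4})Q([1-4])$", q))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed quarter string(s): ", paste(unique(q[bad]), collapse = ", "))
  }
  yr <- as.integer(vapply(m, `[`, "", 2L))
  qq <- as.integer(vapply(m, `[`, "", 3L))
  yr * 4L + qq - 1L
}

quarter_label <- function(idx) {
  sprintf("%dQ%d", idx %/% 4L, idx %% 4L + 1L)
}

#' Sequence of calendar quarters
#'
#' @param from,to quarter strings like `"2004Q1"`.
#' @return character vector of quarters from `from` to `to` inclusive.
#' @export
quarter_seq <- function(from, to) {
  i <- quarter_index(from)
  j <- quarter_index(to)
  if (j < i) stop("invalid quarter range: ", from, " > ", to)
  quarter_label(seq.int(i, j))
}

quarter_year <- function(q) quarter_index(q) %/% 4L

# run expr with a private, restored RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
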