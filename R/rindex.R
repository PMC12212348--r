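#' Build the run-length BWT index (r-index) of a text
#'
#' Computes the suffix array (prefix doubling), the BWT and LCP array, then
#' compresses the BWT to maximal same-character runs keeping the SA value at
#' the first and last row of each run, the per-character thresholds (the
#' position of the first minimum of the LCP array between consecutive runs
#' of that character), and the phi predecessor samples used to enumerate
#' occurrences from a single toehold.
#'
#' The last byte of the text is the terminator; it must be unique and
#' strictly smaller than every other byte.  A [build_pangenome_text()]
#' object satisfies this by construction; plain character input (e.g.
#' `"abracadabra$"`) is accepted for experimentation as long as its final
#' character is a unique minimum.
#'
#' @param x a `pm_pangenome_text`, a character scalar, or a raw vector.
#' @param via `"direct"` builds from the text; `"pfp"` first runs
#'   [pfp_parse()] on the text, validates the parse, reconstructs the text
#'   from dictionary and parse alone and builds from the reconstruction
#'   (the documented construction front-end; both paths yield identical
#'   index content).
#' @param w,p prefix-free parsing parameters for `via = "pfp"`.
#' @return A `pm_rindex`: list(cpp = index components, pg = document
#'   layout or NULL, text_len, r).
#' @export
build_rindex <- function(x, via = c("direct", "pfp"), w = 10L, p = 100L) {
  via <- match.arg(via)
  pg <- NULL
  if (inherits(x, "pm_pangenome_text")) {
    text <- x$text
    pg <- x
  } else if (is.character(x)) {
    text <- charToRaw(x)
  } else if (is.raw(x)) {
    text <- x
  } else stop("unsupported input type")
  if (via == "pfp") {
    s <- rawToChar(text)
    # 0x7f as delimiter: never occurs in DNA texts nor in the reserved bytes
    pfp <- pfp_parse(s, w = w, p = p, delim = "\x7f")
    rec <- pfp_reconstruct(pfp)
    core <- substr(rec, pfp$w + 1L, nchar(rec) - pfp$w)
    if (!identical(core, s)) stop("prefix-free parse failed to reconstruct the text")
    text <- charToRaw(core)
  }
  cpp <- cpp_build_rindex(text)
  structure(list(cpp = cpp, pg = pg, text_len = cpp$n, r = cpp$r),
            class = "pm_rindex")
}

#' @export
print.pm_rindex <- function(x, ...) {
  cat("r-index: n =", x$text_len, " r =", x$r,
      if (!is.null(x$pg)) paste(" docs =", length(x$pg$doc_start)) else "", "\n")
  invisible(x)
}

#' Explicit BWT of an indexed text
#'
#' Expanded from the runs; intended for inspection and tests.
#'
#' @param idx a `pm_rindex`.
#' @return Character scalar (non-printable terminator/separator bytes are
#'   kept as-is in the underlying raw; use `as_raw = TRUE` for those texts).
#' @param as_raw return the raw vector instead of a character scalar.
#' @export
rindex_bwt <- function(idx, as_raw = FALSE) {
  b <- cpp_bwt(idx$cpp)
  if (as_raw) b else rawToChar(b)
}

#' Initial (full) backward-search range
#'
#' @param idx a `pm_rindex`.
#' @return list(lo, hi, toehold): half-open row interval covering all rows
#'   and the SA value of the last row.
#' @export
init_range <- function(idx) {
  r <- cpp_init_range(idx$cpp)
  list(lo = r[1], hi = r[2], toehold = r[3])
}

#' One backward-search step
#'
#' Extends the current pattern by one character on the left.  The toehold
#' (SA value of the last row of the range) is maintained from the run
#' boundary samples alone.
#'
#' @param idx a `pm_rindex`.
#' @param range list(lo, hi, toehold).
#' @param char single character.
#' @return Updated range; an empty range has `lo == hi` and NA toehold.
#' @export
backward_step <- function(idx, range, char) {
  r <- cpp_backward_step(idx$cpp, range$lo, range$hi,
                         if (is.na(range$toehold)) 0L else range$toehold,
                         charToRaw(char))
  list(lo = r[1], hi = r[2], toehold = r[3])
}

#' Backward-search a whole pattern
#'
#' @param idx a `pm_rindex`.
#' @param pattern character scalar.
#' @return list(lo, hi, toehold); empty range when the pattern is absent.
#' @export
pattern_range <- function(idx, pattern) {
  r <- cpp_pattern_search(idx$cpp, charToRaw(pattern))
  list(lo = r[1], hi = r[2], toehold = r[3])
}

#' Enumerate the text positions of a backward-search range
#'
#' Starting from the toehold, repeated applications of the phi function
#' recover the SA values of all rows in the range.
#'
#' @param idx a `pm_rindex`.
#' @param range list(lo, hi, toehold).
#' @return Sorted 0-based text positions (one per occurrence).
#' @export
locate_range <- function(idx, range) {
  if (range$lo >= range$hi) return(integer(0))
  sort(cpp_locate(idx$cpp, range$lo, range$hi, range$toehold))
}

#' All occurrences of a pattern
#'
#' @param idx a `pm_rindex`.
#' @param pattern character scalar.
#' @return Sorted 0-based text positions.
#' @export
locate_occurrences <- function(idx, pattern) {
  locate_range(idx, pattern_range(idx, pattern))
}

#' Random access into the indexed text
#'
#' @param idx a `pm_rindex`.
#' @param pos 0-based positions.
#' @return Character vector of single characters.
#' @export
rindex_access <- function(idx, pos) {
  vapply(as.list(cpp_access(idx$cpp, as.integer(pos))),
         function(b) rawToChar(as.raw(b)), character(1))
}

#' LF mapping of a BWT row
#'
#' @param idx a `pm_rindex`.
#' @param row 0-based BWT row.
#' @return 0-based row of the preceding text position's suffix.
#' @export
lf_step <- function(idx, row) cpp_lf(idx$cpp, as.integer(row))

#' Threshold-guided jump after an empty backward step
#'
#' When extending with `char` empties the range at `row`, the thresholds
#' structure picks the neighbouring run of `char` to restart from: the last
#' row of the preceding run when `row` is above the stored minimum-LCP
#' position, else the first row of the following run (a row equal to the
#' threshold jumps down).
#'
#' @param idx a `pm_rindex`.
#' @param row 0-based current row.
#' @param char single character.
#' @return list(found, row, toehold); `found = FALSE` means the character
#'   does not occur in the BWT (the matching statistic resets to 0).
#' @export
threshold_jump <- function(idx, row, char) {
  cpp_threshold_jump(idx$cpp, as.integer(row), charToRaw(char))
}
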