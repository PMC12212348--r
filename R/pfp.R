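#' Find trigger-string occurrences in a delimited text
#'
#' The text must already carry `w` copies of the delimiter on both ends (see
#' [pfp_parse()], which handles the delimiting).  Without an explicit
#' trigger set, a window is a trigger when its Karp-Rabin rolling hash
#' (polynomial over byte values, base 1e9+7, 61-bit Mersenne modulus)
#' reduced modulo `p` equals zero, or when it is the all-delimiter window.
#'
#' @param sprime delimited text (single character string).
#' @param w window length (>= 2).
#' @param p hash modulus (>= 1).
#' @param triggers optional explicit set of w-length trigger strings,
#'   overriding the hash (used by the worked example and tests).
#' @param delim delimiter character, default `"$"`.
#' @return Sorted 1-based occurrence positions.
#' @export
pfp_find_triggers <- function(sprime, w, p = 100, triggers = NULL, delim = "$") {
  trig <- if (is.null(triggers)) NULL else lapply(triggers, charToRaw)
  cpp_pfp_triggers(charToRaw(sprime), as.integer(w), as.numeric(p), trig,
                   charToRaw(delim)) + 1L
}

#' Prefix-free parse of a text
#'
#' Appends `w` delimiters to both ends of `s` (the cyclic representation),
#' finds trigger occurrences, cuts the text into phrases that begin and end
#' at a trigger and contain no other trigger occurrence, and returns the
#' lexicographically sorted dictionary (delimiter sorting below every other
#' character) together with the parse: the sequence of 1-based dictionary
#' ranks, including the cyclic wrap phrase made of the two boundary
#' delimiter runs.
#'
#' @inheritParams pfp_find_triggers
#' @param s input text (must not contain the delimiter).
#' @return list(dictionary, parse, trigger_pos, sprime, w, p, delim) with
#'   class `pm_pfp`.
#' @export
pfp_parse <- function(s, w, p = 100, triggers = NULL, delim = "$") {
  stopifnot(nchar(s) > 0, w >= 2)
  if (grepl(delim, s, fixed = TRUE)) stop("text contains the delimiter")
  if (nchar(s) + 2L * w < w) stop("window longer than the delimited text")
  pad <- strrep(delim, w)
  sprime <- paste0(pad, s, pad)
  tp <- pfp_find_triggers(sprime, w, p, triggers, delim)
  if (length(tp) < 2) stop("no trigger occurrences; increase p or add triggers")
  k <- length(tp)
  phrases <- vapply(seq_len(k - 1L), function(j)
    substr(sprime, tp[j], tp[j + 1L] + w - 1L), character(1))
  wrap <- paste0(substr(sprime, tp[k], tp[k] + w - 1L), substr(sprime, 1, w))
  phrases <- c(phrases, wrap)
  dict <- unique(phrases)
  dict <- dict[order(chartr(delim, "\x01", dict), method = "radix")]
  parse <- match(phrases, dict)
  structure(list(dictionary = dict, parse = parse, trigger_pos = tp,
                 sprime = sprime, w = as.integer(w), p = p, delim = delim),
            class = "pm_pfp")
}

#' Reconstruct the delimited text from a prefix-free parse
#'
#' Overlap-concatenates the parse phrases (consecutive phrases share `w`
#' characters); the cyclic tail contributed by the wrap phrase is dropped, so
#' the result equals the delimited text `sprime`.
#'
#' @param pfp a `pm_pfp` object.
#' @return The reconstructed delimited text.
#' @export
pfp_reconstruct <- function(pfp) {
  ph <- pfp$dictionary[pfp$parse]
  out <- ph[1]
  for (j in seq_along(ph)[-1]) out <- paste0(out, substr(ph[j], pfp$w + 1L, nchar(ph[j])))
  substr(out, 1, nchar(out) - pfp$w)
}

#' Dump a prefix-free parse to text files
#'
#' @param pfp a `pm_pfp` object.
#' @param dict_path one phrase per line.
#' @param parse_path whitespace-separated dictionary ranks.
#' @export
pfp_dump <- function(pfp, dict_path, parse_path) {
  writeLines(pfp$dictionary, dict_path)
  writeLines(paste(pfp$parse, collapse = " "), parse_path)
  invisible(NULL)
}

#' @export
print.pm_pfp <- function(x, ...) {
  cat("prefix-free parse: |D| =", length(x$dictionary),
      " |P| =", length(x$parse), " w =", x$w, "\n")
  invisible(x)
}
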