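#' Canonical spinal segment vocabulary
#'
#' Ganglion segments are labeled by spinal division and number in the
#' rostro-caudal order used for mouse dorsal root and sympathetic chain
#' ganglia: C1-C8, T1-T13, L1-L6, S1-S4, giving 31 positions. The
#' `global_index` column (1-31) is the total order used by distribution
#' centroids and segment profiles.
#'
#' @return A data.frame with columns `label`, `division`, `number`,
#'   `global_index`, one row per segment in canonical order.
#' @export
#' @examples
#' head(segment_table())
segment_table <- function() {
  div <- c("C", "T", "L", "S")
  n <- c(8L, 13L, 6L, 4L)
  data.frame(
    label = unlist(mapply(function(d, k) paste0(d, seq_len(k)), div, n,
                          SIMPLIFY = FALSE), use.names = FALSE),
    division = rep(div, n),
    number = unlist(lapply(n, seq_len)),
    global_index = seq_len(sum(n)),
    stringsAsFactors = FALSE
  )
}

#' Parse segment labels
#'
#' Converts labels such as `"L5"` to their canonical description. Labels
#' outside the mouse vocabulary (e.g. `"L9"`, `"X2"`) are an error.
#'
#' @param x Character vector of segment labels.
#' @return A data.frame with columns `label`, `division`, `number`,
#'   `global_index`, one row per element of `x`.
#' @export
#' @examples
#' parse_segment(c("C8", "T1", "L5"))$global_index
parse_segment <- function(x) {
  x <- toupper(trimws(as.character(x)))
  tab <- segment_table()
  i <- match(x, tab$label)
  if (anyNA(i)) {
    bad <- unique(x[is.na(i)])
    stop("invalid segment label(s): ", paste(bad, collapse = ", "),
         " (expected C1-C8, T1-T13, L1-L6 or S1-S4)", call. = FALSE)
  }
  out <- tab[i, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname parse_segment
#' @return `segment_index()` returns the integer global index (1-31).
#' @export
segment_index <- function(x) parse_segment(x)$global_index
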