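#' Mass-normalize neuron counts
#'
#' Converts raw labeled-neuron counts into densities: for each muscle
#' and neuron class, the counts are summed over ganglion segments and
#' divided by the muscle's wet weight, giving neurons per gram. Muscles
#' present in the weight table but absent from the counts are retained
#' with zero density so clustering input dimensions stay stable.
#'
#' @param counts A segment count table (see [read_count_table()]).
#' @param muscles A muscle table with `name` and `wet_weight` (grams).
#' @return A density matrix (muscles x sensory/sympathetic/motor, per gram).
#' @export
normalize_density <- function(counts, muscles) {
  muscles <- validate_muscle_table(muscles)
  counts <- validate_count_table(counts)
  missing <- setdiff(unique(counts$muscle), muscles$name)
  if (length(missing)) {
    stop("muscle(s) absent from the muscle table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- matrix(0, nrow(muscles), length(NEURON_CLASSES),
              dimnames = list(muscles$name, NEURON_CLASSES))
  if (nrow(counts)) {
    tot <- tapply(counts$count,
                  list(factor(counts$muscle, muscles$name),
                       factor(counts$neuron_class, NEURON_CLASSES)),
                  sum)
    tot[is.na(tot)] <- 0
    X[rownames(tot), colnames(tot)] <- tot
  }
  X / muscles$wet_weight
}

#' Per-segment distribution profile
#'
#' Summarizes where along the rostro-caudal axis a muscle's labeled
#' neurons of one class sit: the proportion of the total count in each
#' occupied ganglion segment, reported in canonical C1-S4 order.
#'
#' @param counts A segment count table.
#' @param muscle Muscle name.
#' @param neuron_class One of `"sensory"`, `"sympathetic"`, `"motor"`.
#' @return An object of class `segment_profile`: a list with `muscle`,
#'   `neuron_class`, `proportions` (named over occupied segments),
#'   `global_index` (their positions 1-31) and `total_count`. Empty for
#'   absent keys.
#' @export
segment_distribution <- function(counts, muscle, neuron_class) {
  counts <- validate_count_table(counts)
  rows <- counts[counts$muscle == muscle & counts$neuron_class == neuron_class &
                   counts$count > 0, , drop = FALSE]
  rows <- rows[order(rows$global_index), , drop = FALSE]
  total <- sum(rows$count)
  structure(list(
    muscle = muscle,
    neuron_class = neuron_class,
    proportions = if (total > 0) stats::setNames(rows$count / total, rows$segment)
                  else stats::setNames(numeric(0), character(0)),
    global_index = rows$global_index,
    total_count = as.integer(total)
  ), class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("Segment profile:", x$muscle, "/", x$neuron_class,
      "-", x$total_count, "neurons over", length(x$proportions), "segment(s)\n")
  if (length(x$proportions)) print(round(x$proportions, 3))
  invisible(x)
}

#' Concentration of a segment profile
#'
#' Entropy-based statistic for how concentrated a distribution of
#' neurons is across ganglion segments: `1 - H(p)/log(n)` over the `n`
#' occupied segments, defined as 1 for a single-segment (point-mass)
#' profile and 0 for a uniform spread over two or more segments. The
#' `"max_share"` method instead reports the largest single-segment
#' proportion. Both are permutation-invariant over segments.
#'
#' @param profile A `segment_profile`.
#' @param method `"entropy"` (default) or `"max_share"`.
#' @return A real in `[0, 1]`.
#' @export
concentration_index <- function(profile, method = c("entropy", "max_share")) {
  method <- match.arg(method)
  p <- profile$proportions
  if (!length(p) || profile$total_count == 0) {
    stop("concentration_index is undefined for an empty profile", call. = FALSE)
  }
  if (method == "max_share") return(max(p))
  if (length(p) == 1) return(1)
  H <- -sum(p * log(p))
  1 - H / log(length(p))
}

#' Rostro-caudal centroid of a segment profile
#'
#' The proportion-weighted mean global segment index (1 = C1 rostral,
#' 31 = S4 caudal); lies within the occupied index range. Lower values
#' mean a more rostral ("higher") distribution.
#'
#' @param profile A `segment_profile`.
#' @return A fractional global index.
#' @export
distribution_centroid <- function(profile) {
  p <- profile$proportions
  if (!length(p) || profile$total_count == 0) {
    stop("distribution_centroid is undefined for an empty profile", call. = FALSE)
  }
  sum(p * profile$global_index)
}
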