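#' Pearson correlation over complete pairs
#'
#' Sample Pearson coefficient over the pairs where both values are
#' present, with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Requires at least 3 complete pairs and non-constant vectors.
#'
#' @param x,y Numeric vectors of equal length; `NA`s are dropped pairwise.
#' @return A list with `r`, `p_value`, `n_pairs`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = n)
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Density-phenotype correlation screen
#'
#' Pearson correlation of each neuron class's density against each
#' muscle phenotype (wet weight, slow-fiber percentage, muscle length,
#' fiber length, pennation angle, PCSA) over pairwise-complete muscles.
#' Correlations with `|r|` at or above `threshold` (default 0.7) are
#' flagged relevant; stars mark raw p < 0.05 (`*`) and < 0.01 (`**`).
#' Benjamini-Hochberg q-values are reported alongside for transparency
#' but never gate relevance. Pairs that cannot be computed (a constant
#' or fully missing phenotype, or fewer than 3 complete pairs) are
#' returned in the `skipped` attribute with the reason.
#'
#' @param X Density matrix.
#' @param muscles Muscle phenotype table.
#' @param threshold Absolute-r relevance threshold.
#' @return A data.frame with columns `x_name`, `y_name`, `n_pairs`, `r`,
#'   `p_value`, `bh_q`, `relevant`, `stars`.
#' @export
phenotype_screen <- function(X, muscles, threshold = 0.7) {
  X <- validate_density_matrix(X)
  muscles <- validate_muscle_table(muscles)
  shared <- intersect(rownames(X), muscles$name)
  if (length(shared) < 3) stop("fewer than 3 muscles shared", call. = FALSE)
  sub <- muscles[match(shared, muscles$name), , drop = FALSE]
  fields <- intersect(PHENOTYPE_FIELDS, names(muscles))
  rows <- list(); skipped <- list()
  for (cls in NEURON_CLASSES) {
    for (f in fields) {
      res <- tryCatch(pearson_r(X[shared, cls], sub[[f]]), error = identity)
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1]] <- data.frame(
          x_name = cls, y_name = f, reason = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          x_name = cls, y_name = f, n_pairs = res$n_pairs, r = res$r,
          p_value = res$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$p_value, method = "BH")
  out$relevant <- abs(out$r) >= threshold
  out$stars <- significance_stars(out$p_value)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}
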