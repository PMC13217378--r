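#' Livak 2^-ddCt relative quantification
#'
#' For one target gene: technical replicates are averaged to one Ct per
#' (sample, gene); `dCt(sample) = Ct_gene - Ct_reference` removes
#' per-sample plate/loading offsets; `ddCt(sample) = dCt(sample) -
#' mean dCt over the control group`; and the relative expression is
#' `fold = 2^-ddCt`, so the control group's mean dCt maps to fold 1 by
#' construction. Per-group mean fold, SEM and an equal-variance
#' two-sided Student t-test against the control group are reported.
#'
#' @param ct Ct table (`sample`, `group`, `gene`, `ct`), see [read_ct_table()].
#' @param gene Target gene.
#' @param reference_gene Normalizer (default `"Gapdh"`).
#' @param control_group Group defining the fold = 1 baseline.
#' @param test_scale Run the group t-tests on the `"fold"` (default) or
#'   `"log2"` (= -ddCt) scale.
#' @return An object of class `fold_change_result`: list with
#'   `samples` (per-sample gene, group, sample, delta_ct, ddct,
#'   fold_change) and `summary` (per-group n, mean_fold, sem,
#'   t_p_value vs control; NA for the control itself).
#' @export
delta_delta_ct <- function(ct, gene, reference_gene = "Gapdh", control_group,
                           test_scale = c("fold", "log2")) {
  test_scale <- match.arg(test_scale)
  ct$ct <- as.numeric(ct$ct)
  # technical replicates -> one Ct per (sample, gene)
  agg <- stats::aggregate(ct["ct"], by = ct[c("sample", "group", "gene")],
                          FUN = mean)
  tgt <- agg[agg$gene == gene, , drop = FALSE]
  ref <- agg[agg$gene == reference_gene, , drop = FALSE]
  if (!nrow(tgt)) stop("no Ct rows for gene ", gene, call. = FALSE)
  i <- match(tgt$sample, ref$sample)
  if (anyNA(i)) {
    stop("missing reference (", reference_gene, ") Ct for sample(s): ",
         paste(tgt$sample[is.na(i)], collapse = ", "), call. = FALSE)
  }
  dct <- tgt$ct - ref$ct[i]
  ctrl <- tgt$group == control_group
  if (!any(ctrl)) stop("control group '", control_group, "' is empty", call. = FALSE)
  ddct <- dct - mean(dct[ctrl])
  samples <- data.frame(gene = gene, group = tgt$group, sample = tgt$sample,
                        delta_ct = dct, ddct = ddct, fold_change = 2^(-ddct),
                        stringsAsFactors = FALSE)
  groups <- unique(tgt$group)
  summary <- do.call(rbind, lapply(groups, function(g) {
    v <- samples$fold_change[samples$group == g]
    p <- if (g == control_group) NA_real_ else {
      tryCatch(group_compare(samples, g, control_group, scale = test_scale),
               error = function(e) NA_real_)
    }
    data.frame(gene = gene, group = g, n = length(v), mean_fold = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               t_p_value = p, stringsAsFactors = FALSE)
  }))
  structure(list(samples = samples, summary = summary,
                 control_group = control_group, reference_gene = reference_gene),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat("2^-ddCt fold changes (reference", x$reference_gene,
      ", control", x$control_group, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Two-group comparison of fold changes
#'
#' Equal-variance two-sided Student t-test between two groups'
#' per-sample relative expressions, on the fold scale (default) or on
#' the log2 (= -ddCt) scale. Each group needs at least 2 samples and
#' the pooled variance must be positive.
#'
#' @param fc A `fold_change_result` or its `samples` data.frame.
#' @param g1,g2 Group names.
#' @param scale `"fold"` or `"log2"`.
#' @return The two-sided p-value.
#' @export
group_compare <- function(fc, g1, g2, scale = c("fold", "log2")) {
  scale <- match.arg(scale)
  samples <- if (inherits(fc, "fold_change_result")) fc$samples else fc
  v <- if (scale == "fold") samples$fold_change else -samples$ddct
  a <- v[samples$group == g1]
  b <- v[samples$group == g2]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
    stop("zero within-group variance with different means: t undefined",
         call. = FALSE)
  }
  stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")$p.value
}
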