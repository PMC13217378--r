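#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability that a gene list overlaps a
#' gene set at least as much as observed, drawing `n_list` genes from a
#' background of `n_background` of which `n_set` belong to the set:
#' `p = P[X >= n_overlap]`. The `"ease"` mode subtracts one from the
#' observed overlap (a conservative variant used by some annotation
#' servers). The list must be contained in the background; the set is
#' intersected with the background first.
#'
#' @param list_genes Character vector, the query gene list.
#' @param set_genes Character vector, the gene set.
#' @param background_genes Character vector, the gene universe.
#' @param mode `"standard"` (default) or `"ease"`.
#' @return The p-value.
#' @export
ora_test <- function(list_genes, set_genes, background_genes,
                     mode = c("standard", "ease")) {
  mode <- match.arg(mode)
  list_genes <- unique(toupper(list_genes))
  set_genes <- unique(toupper(set_genes))
  background_genes <- unique(toupper(background_genes))
  if (!length(list_genes) || !length(background_genes)) {
    stop("empty gene list or background", call. = FALSE)
  }
  out <- setdiff(list_genes, background_genes)
  if (length(out)) {
    stop("gene list is not contained in the background (e.g. ",
         out[1], ")", call. = FALSE)
  }
  set_in_bg <- intersect(set_genes, background_genes)
  ov <- length(intersect(list_genes, set_in_bg))
  q <- if (mode == "ease") max(ov - 1, 0) else ov
  stats::phyper(q - 1, length(set_in_bg),
                length(background_genes) - length(set_in_bg),
                length(list_genes), lower.tail = FALSE)
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [ora_test()] for every set in a GMT-derived collection, sorts
#' by p-value and flags significance at `alpha` on the raw p-value
#' (the default gate) or on the Benjamini-Hochberg q-value
#' (`gate = "bh"`); BH q-values are always reported.
#'
#' @param list_genes Query gene list.
#' @param collection Gene-set collection from [read_gene_sets()].
#' @param background Gene universe; defaults in the pipeline to the
#'   intersected transcriptome gene list.
#' @param alpha Significance level (default 0.05).
#' @param gate `"raw"` or `"bh"`.
#' @param mode Passed to [ora_test()].
#' @return A data.frame with columns `set_id`, `description`, `n_list`,
#'   `n_set`, `n_overlap`, `n_background`, `p_value`, `bh_q`,
#'   `significant`, sorted ascending by `p_value`.
#' @export
enrich_all <- function(list_genes, collection, background, alpha = 0.05,
                       gate = c("raw", "bh"), mode = c("standard", "ease")) {
  gate <- match.arg(gate)
  mode <- match.arg(mode)
  if (!length(collection)) stop("empty gene-set collection", call. = FALSE)
  list_genes <- unique(toupper(list_genes))
  background <- unique(toupper(background))
  rows <- lapply(names(collection), function(id) {
    members <- intersect(toupper(collection[[id]]$members), background)
    data.frame(
      set_id = id,
      description = collection[[id]]$description,
      n_list = length(list_genes),
      n_set = length(members),
      n_overlap = length(intersect(list_genes, members)),
      n_background = length(background),
      p_value = ora_test(list_genes, members, background, mode = mode),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$bh_q <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  out$significant <- if (gate == "raw") out$p_value < alpha else out$bh_q < alpha
  rownames(out) <- NULL
  out
}

#' Top enriched terms
#'
#' Convenience report of the `n` smallest-p terms from an
#' over-representation table (the analogue of a "top clusters" figure
#' panel, without any term-clustering step).
#'
#' @param enrichment Result of [enrich_all()].
#' @param n Number of terms.
#' @return The first `n` rows.
#' @export
top_terms <- function(enrichment, n = 5) {
  utils::head(enrichment, n)
}
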