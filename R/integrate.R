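#' Expression dataset container
#'
#' One public transcriptome dataset for one muscle: a genes x replicates
#' abundance matrix (FPKM or counts; the unit is metadata and becomes
#' irrelevant after ranking) with its accession-style id and platform.
#' Gene symbols are upper-cased on construction so joins across
#' datasets and with GMT files use a single convention.
#'
#' @param dataset_id Unique dataset identifier (e.g. an accession).
#' @param platform Sequencing/array platform label.
#' @param muscle Muscle the samples come from.
#' @param abundance Numeric matrix, genes in rownames, replicate columns.
#' @param unit `"FPKM"` or `"count"`; never mixed within one dataset.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, platform, muscle, abundance,
                               unit = "FPKM") {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance))) {
    stop("abundance matrix needs gene-symbol rownames", call. = FALSE)
  }
  rownames(abundance) <- toupper(rownames(abundance))
  if (anyDuplicated(rownames(abundance))) {
    stop("duplicate gene symbols after case normalization in ", dataset_id,
         call. = FALSE)
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundances must be finite and non-negative in ", dataset_id,
         call. = FALSE)
  }
  structure(list(dataset_id = as.character(dataset_id),
                 platform = as.character(platform),
                 muscle = as.character(muscle),
                 abundance = abundance,
                 unit = unit),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset", x$dataset_id, "(", x$platform, "):",
      x$muscle, "-", nrow(x$abundance), "genes x", ncol(x$abundance),
      "replicates [", x$unit, "]\n")
  invisible(x)
}

#' Shared genes across datasets
#'
#' The sorted intersection of (case-normalized) gene symbols across all
#' datasets; the non-intersecting part of each dataset is discarded
#' before indexing so every platform contributes the same gene universe.
#'
#' @param datasets List of `expression_dataset` objects.
#' @return Sorted character vector of shared gene symbols.
#' @export
intersect_genes <- function(datasets) {
  if (!length(datasets)) stop("need at least one dataset", call. = FALSE)
  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$abundance)))
  if (!length(common)) {
    stop("empty gene intersection; check that datasets share a symbol namespace",
         call. = FALSE)
  }
  sort(common)
}

#' Aggregate replicate columns
#'
#' Arithmetic mean across replicate columns, giving one abundance value
#' per gene before ranking.
#'
#' @param ds An `expression_dataset`.
#' @return Named numeric vector of per-gene mean abundances.
#' @export
aggregate_replicates <- function(ds) {
  rowMeans(ds$abundance)
}

#' Rank-based expression index
#'
#' Genes are ranked in descending abundance (rank 1 = most abundant;
#' ties get the average of their positions) and the index is
#' `1 - rank / N`. The most abundant gene scores `1 - 1/N`, the least
#' scores 0, and any strictly increasing transformation of the
#' abundances - such as a platform-specific distortion - leaves the
#' indices unchanged, which is what makes heterogeneous platforms
#' comparable.
#'
#' @param abundance Named numeric vector of per-gene abundances (N >= 2).
#' @return Named numeric vector of indices in `[0, 1)`.
#' @export
#' @examples
#' expression_index(c(a = 9, b = 7, c = 5, d = 1))
expression_index <- function(abundance) {
  if (length(abundance) < 2) stop("need at least 2 genes", call. = FALSE)
  if (any(!is.finite(abundance))) stop("abundances must be finite", call. = FALSE)
  r <- rank(-abundance, ties.method = "average")
  1 - r / length(abundance)
}

#' Build the cross-platform expression index matrix
#'
#' Per dataset: replicates are averaged, genes restricted to the
#' cross-dataset intersection, and indices computed by
#' [expression_index()]. Muscles profiled by more than one dataset get
#' the per-gene mean of their dataset indices; which datasets fed each
#' muscle is recorded in the `provenance` attribute.
#'
#' @param datasets List of `expression_dataset` objects with unique ids.
#' @return Genes x muscles numeric matrix in `[0, 1)` with attribute
#'   `provenance` (named list muscle -> dataset ids).
#' @export
build_index_matrix <- function(datasets) {
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate dataset_id(s): ", paste(unique(ids[duplicated(ids)]),
                                            collapse = ", "), call. = FALSE)
  }
  common <- intersect_genes(datasets)
  idx <- vapply(datasets, function(d) {
    expression_index(aggregate_replicates(d)[common])
  }, numeric(length(common)))
  rownames(idx) <- common
  muscles <- vapply(datasets, function(d) d$muscle, character(1))
  um <- unique(muscles)
  E <- vapply(um, function(m) rowMeans(idx[, muscles == m, drop = FALSE]),
              numeric(length(common)))
  dimnames(E) <- list(common, um)
  attr(E, "provenance") <- lapply(stats::setNames(um, um),
                                  function(m) ids[muscles == m])
  E
}

#' Gene-density correlation screen
#'
#' Pearson correlation between each gene's expression index and each
#' neuron class's density across the muscles shared by the index matrix
#' and the density matrix (at least 3). Genes whose correlation reaches
#' `threshold` for a class form its positively associated list, genes
#' at or below `-threshold` its negatively associated list. Genes with a
#' constant index across the shared muscles have no defined correlation
#' and are excluded (listed in `excluded`).
#'
#' @param E Expression index matrix from [build_index_matrix()].
#' @param X Density matrix.
#' @param threshold Absolute-r relevance threshold (default 0.7).
#' @return An object of class `gene_screen`: list with `table` (gene,
#'   class, n_pairs, r, p_value), `positive` and `negative` (named
#'   per-class lists of gene symbols), `excluded`, `muscles`.
#' @export
gene_neuron_screen <- function(E, X, threshold = 0.7) {
  X <- validate_density_matrix(X)
  shared <- intersect(colnames(E), rownames(X))
  if (length(shared) < 3) {
    stop("fewer than 3 muscles shared between index and density matrices",
         call. = FALSE)
  }
  Es <- E[, shared, drop = FALSE]
  Xs <- X[shared, , drop = FALSE]
  n <- length(shared)
  sds <- apply(Es, 1, stats::sd)
  excluded <- rownames(Es)[sds == 0]
  keep <- sds > 0
  usable <- Es[keep, , drop = FALSE]
  cls_const <- apply(Xs, 2, stats::sd) == 0
  if (any(cls_const)) {
    stop("constant density for class(es): ",
         paste(colnames(Xs)[cls_const], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(t(usable), Xs)                       # genes x classes
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  tab <- data.frame(
    gene = rep(rownames(R), times = ncol(R)),
    class = rep(colnames(R), each = nrow(R)),
    n_pairs = n,
    r = as.vector(R),
    p_value = as.vector(P),
    stringsAsFactors = FALSE
  )
  positive <- lapply(stats::setNames(colnames(R), colnames(R)),
                     function(cl) rownames(R)[R[, cl] >= threshold])
  negative <- lapply(stats::setNames(colnames(R), colnames(R)),
                     function(cl) rownames(R)[R[, cl] <= -threshold])
  structure(list(table = tab, positive = positive, negative = negative,
                 excluded = excluded, muscles = shared, threshold = threshold),
            class = "gene_screen")
}

#' @export
print.gene_screen <- function(x, ...) {
  cat("Gene-density screen over", length(x$muscles), "muscles, |r| >=",
      x$threshold, "\n")
  for (cl in names(x$positive)) {
    cat("  ", cl, ": +", length(x$positive[[cl]]), " / -",
        length(x$negative[[cl]]), " genes\n", sep = "")
  }
  if (length(x$excluded)) cat("  excluded (constant index):",
                              length(x$excluded), "genes\n")
  invisible(x)
}
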