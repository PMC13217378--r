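#' Consensus clustering of the density matrix
#'
#' Monti-style consensus clustering: for each candidate `k` and each of
#' `n_resamples` resamples, a fraction `p_item` of the muscles is drawn
#' without replacement and partitioned by k-means (greatest-distance
#' seeding, `nstart` restarts, squared-Euclidean objective); the
#' consensus matrix is the proportion of resamples in which two muscles
#' co-clustered among those where both were drawn. The number of
#' clusters is chosen from the areas under the consensus-value CDFs
#' (see [select_k()]), the final partition by average-linkage
#' agglomeration of the chosen consensus matrix ([final_assignment()]),
#' and clusters are named by their dominant neuron class
#' ([characterize_clusters()]). Features are clustered on their
#' original per-gram scale; set `standardize = TRUE` to z-score columns
#' first (changes results; off by default).
#'
#' @param X Density matrix (muscles x classes), see [read_density_matrix()].
#' @param k_range Candidate cluster numbers, consecutive, starting at 2.
#' @param n_resamples Resamples per `k` (default 1000).
#' @param p_item Item subsampling fraction in (0, 1] (default 0.8).
#' @param seed Integer seed; the whole run is reproducible given it.
#' @param rule,tau k-selection rule and delta-area threshold, see [select_k()].
#' @param nstart k-means restarts per resample.
#' @param standardize z-score the class columns before clustering.
#' @return An object of class `consensus_result`: list with
#'   `consensus` (per-k matrices), `cosample_counts`, `cdf_area`,
#'   `delta_area`, `pac`, `chosen_k`, `labels` (named integer vector),
#'   `archetype_names`, and the call parameters.
#' @export
#' @examples
#' res <- consensus_run(atlas_densities(), k_range = 2:6,
#'                      n_resamples = 100, seed = 1)
#' res$chosen_k
consensus_run <- function(X, k_range = 2:10, n_resamples = 1000, p_item = 0.8,
                          seed = 1, rule = c("delta-area", "pac"), tau = 0.1,
                          nstart = 10, standardize = FALSE) {
  X <- validate_density_matrix(X)
  rule <- match.arg(rule)
  n <- nrow(X)
  k_range <- sort(as.integer(k_range))
  if (max(k_range) > n - 1) stop("k_range exceeds n - 1 items", call. = FALSE)
  if (n < 2 * max(k_range)) {
    stop("need at least 2*max(k_range) items for stable resampling", call. = FALSE)
  }
  if (p_item <= 0 || p_item > 1) stop("p_item must be in (0, 1]", call. = FALSE)
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)
  if (all(stats::dist(X) == 0)) {
    stop("all rows are identical; add jitter or check the input", call. = FALSE)
  }
  Z <- if (standardize) scale(X) else X
  m <- as.integer(ceiling(p_item * n))

  set.seed(seed)
  raw <- consensus_counts_cpp(Z, k_range, as.integer(n_resamples), m,
                              as.integer(nstart), 100L)

  consensus <- list()
  cosample <- list()
  areas <- numeric(0)
  pac <- numeric(0)
  for (kc in names(raw)) {
    I <- raw[[kc]]$co_cluster
    S <- raw[[kc]]$co_sample
    M <- ifelse(S > 0, I / S, NA_real_)
    diag(M) <- 1
    dimnames(M) <- list(rownames(X), rownames(X))
    dimnames(S) <- dimnames(M)
    consensus[[kc]] <- M
    cosample[[kc]] <- S
    off <- M[upper.tri(M)]
    off <- off[is.finite(off)]
    areas[kc] <- consensus_cdf_area(off)
    pac[kc] <- mean(off > 0.1 & off < 0.9)
  }

  if (rule == "delta-area") {
    sel <- select_k(areas, rule = "delta-area", tau = tau)
  } else {
    sel <- list(chosen_k = k_range[which.min(pac)],
                delta_area = delta_area_seq(areas))
  }
  chosen_k <- sel$chosen_k
  labels <- final_assignment(consensus[[as.character(chosen_k)]], chosen_k)
  structure(list(
    consensus = consensus,
    cosample_counts = cosample,
    cdf_area = areas,
    delta_area = sel$delta_area,
    pac = pac,
    chosen_k = chosen_k,
    labels = labels,
    archetype_names = characterize_clusters(labels, X),
    k_range = k_range, n_resamples = n_resamples, p_item = p_item,
    seed = seed, rule = rule, tau = tau, standardize = standardize
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over k =", paste(range(x$k_range), collapse = "-"),
      "(", x$n_resamples, "resamples, p_item", x$p_item, ")\n")
  cat("CDF areas:", paste(names(x$cdf_area), round(x$cdf_area, 3),
                          sep = ":", collapse = "  "), "\n")
  cat("Chosen k:", x$chosen_k, "by", x$rule, "rule\n")
  tab <- table(x$labels)
  for (cl in names(tab)) {
    cat("  cluster", cl, "(", x$archetype_names[[cl]], "):", tab[[cl]], "muscles\n")
  }
  invisible(x)
}

# area under the empirical CDF of consensus values, over a fixed grid of
# 100 equal bins on [0, 1]
consensus_cdf_area <- function(v) {
  grid <- seq_len(100) / 100
  sum(stats::ecdf(v)(grid)) / 100
}

#' Empirical CDF of a consensus matrix
#'
#' CDF over the finite off-diagonal consensus entries, with its area
#' computed on a fixed grid of 100 equal bins. Perfect consensus (all
#' entries 0 or 1 with few co-clustered pairs) pushes the area toward
#' its extremes; the area's growth as `k` increases drives [select_k()].
#'
#' @param M A consensus matrix (square, symmetric, diagonal 1).
#' @return A list with `values` (sorted entries), `cdf` (function) and `area`.
#' @export
consensus_cdf <- function(M) {
  v <- M[upper.tri(M)]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite off-diagonal consensus entries", call. = FALSE)
  list(values = sort(v), cdf = stats::ecdf(v), area = consensus_cdf_area(v))
}

delta_area_seq <- function(areas) {
  ks <- as.integer(names(areas))
  d <- c(areas[1], diff(areas) / utils::head(areas, -1))
  names(d) <- ks
  d
}

#' Choose the number of clusters from consensus CDF areas
#'
#' Default `"delta-area"` rule: with `A(k)` the CDF area at `k`, the
#' relative gain is `delta(2) = A(2)` and
#' `delta(k) = (A(k) - A(k-1)) / A(k-1)` for `k > 2`; the chosen `k` is
#' the smallest whose next gain falls below `tau` (default 0.1), i.e.
#' the elbow where adding clusters stops improving stability. If no
#' gain falls below `tau`, the largest candidate is returned. The
#' `"pac"` rule (proportion of ambiguous clustering: share of consensus
#' entries strictly inside (0.1, 0.9)) is available as a second opinion
#' in [consensus_run()].
#'
#' @param areas Named numeric vector of CDF areas for consecutive k
#'   starting at 2 (names are the k values).
#' @param rule Currently `"delta-area"`.
#' @param tau Relative-gain threshold.
#' @return A list with `chosen_k` and the `delta_area` sequence.
#' @export
#' @examples
#' select_k(c(`2` = 0.5, `3` = 0.9, `4` = 0.92, `5` = 0.925))$chosen_k
select_k <- function(areas, rule = "delta-area", tau = 0.1) {
  if (length(areas) < 2) stop("need areas for at least 2 values of k", call. = FALSE)
  ks <- as.integer(names(areas))
  if (is.null(names(areas)) || anyNA(ks)) ks <- seq.int(2, length.out = length(areas))
  if (any(diff(ks) != 1) || ks[1] != 2) {
    stop("areas must be given for consecutive k starting at 2", call. = FALSE)
  }
  names(areas) <- ks
  d <- delta_area_seq(areas)
  chosen <- ks[length(ks)]
  for (i in seq_len(length(ks) - 1)) {
    if (d[i + 1] < tau) { chosen <- ks[i]; break }
  }
  list(chosen_k = chosen, delta_area = d)
}

#' Final partition from a consensus matrix
#'
#' Average-linkage agglomerative clustering on the dissimilarity
#' `1 - M`, cut to `k` clusters. Merge-height ties are resolved by
#' `stats::hclust`'s deterministic ordering (lowest item index first),
#' so the partition is reproducible. Clusters are relabeled 1..k in
#' order of first appearance along the input rows.
#'
#' @param M Consensus matrix with item dimnames.
#' @param k Number of clusters, `2 <= k <= n`.
#' @return Named integer vector of cluster labels.
#' @export
final_assignment <- function(M, k) {
  n <- nrow(M)
  if (k < 1 || k > n) stop("k must be between 1 and n", call. = FALSE)
  D <- 1 - M
  D[!is.finite(D)] <- 1
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  raw <- stats::cutree(hc, k = k)
  relab <- match(raw, unique(raw))
  stats::setNames(as.integer(relab), rownames(M))
}

#' Name clusters by their dominant neuron class
#'
#' A cluster whose mean density is below the grand mean for every class
#' is the "neuron-sparse muscle" archetype; otherwise the cluster is
#' named for the class with the largest ratio of cluster mean to grand
#' mean ("&lt;class&gt; neuron-rich muscle"). Ties fall to the fixed class
#' order sensory, sympathetic, motor.
#'
#' @param labels Named cluster labels over the rows of `X`.
#' @param X Density matrix.
#' @return Named character vector, one archetype name per cluster id.
#' @export
characterize_clusters <- function(labels, X) {
  X <- validate_density_matrix(X)
  X <- X[names(labels), , drop = FALSE]
  grand <- colMeans(X)
  out <- character(0)
  for (cl in sort(unique(labels))) {
    cm <- colMeans(X[labels == cl, , drop = FALSE])
    if (all(cm < grand)) {
      out[as.character(cl)] <- "neuron-sparse muscle"
    } else {
      ratio <- ifelse(grand > 0, cm / grand, 0)
      cls <- NEURON_CLASSES[which.max(ratio)]   # which.max: first of ties
      out[as.character(cl)] <- paste(cls, "neuron-rich muscle")
    }
  }
  out
}

#' Per-cluster phenotype means
#'
#' Arithmetic means of each phenotype within each cluster, computed
#' over non-missing values only (available-case); the number of values
#' actually used is reported per cell as `n_<field>`. A cluster with no
#' non-missing values for a field gets a missing mean. Values are
#' returned at full precision; round only for presentation (the
#' reference tables print grams to 4 decimals, degrees to 2).
#'
#' @param labels Named cluster labels (names are muscle names).
#' @param muscles Muscle phenotype table containing every labeled muscle.
#' @param X Optional density matrix to add per-class mean densities.
#' @return A data.frame, one row per cluster.
#' @export
cluster_phenotype_means <- function(labels, muscles, X = NULL) {
  muscles <- validate_muscle_table(muscles)
  missing <- setdiff(names(labels), muscles$name)
  if (length(missing)) {
    stop("labeled muscle(s) absent from the muscle table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fields <- intersect(PHENOTYPE_FIELDS, names(muscles))
  rows <- lapply(sort(unique(labels)), function(cl) {
    ms <- names(labels)[labels == cl]
    sub <- muscles[match(ms, muscles$name), , drop = FALSE]
    row <- list(cluster = cl, n_muscles = length(ms))
    if (!is.null(X)) {
      cm <- colMeans(validate_density_matrix(X)[ms, , drop = FALSE])
      for (cls in NEURON_CLASSES) row[[paste0("mean_", cls)]] <- cm[[cls]]
    }
    for (f in fields) {
      v <- sub[[f]]
      row[[paste0("mean_", f)]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      row[[paste0("n_", f)]] <- sum(!is.na(v))
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
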