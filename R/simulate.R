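## Seeded generators for every input the pipeline consumes, with planted
## ground truth recorded for parameter-recovery studies. Each generator is
## a pure function of (config, seed): it seeds one generator up front and
## draws per-stage substreams at fixed offsets, so adding a stage never
## perturbs earlier draws.

seed_offsets <- c(densities = 0L, phenotypes = 1000L, segments = 2000L,
                  expression = 3000L, ct = 4000L)

with_substream <- function(seed, stage, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed) + seed_offsets[[stage]])
  expr
}

#' Simulate a muscle innervation atlas with planted archetypes
#'
#' Generates the full input bundle for the density/clustering arm of
#' the pipeline: `k` innervation archetypes (a neuron-sparse baseline
#' plus class-elevated archetypes built from the sensory, sympathetic
#' and motor axes), per-muscle densities as archetype means under
#' lognormal noise, phenotypes monotonically coupled to log total
#' density (wet weight decreasing, pennation angle increasing, plus
#' weakly coupled slow-fiber percentage and decreasing length/PCSA),
#' and raw per-segment counts drawn to be consistent with the densities
#' and weights. Archetype log-mean density triples are spaced by
#' `separation` within-archetype standard deviations, where the SD is
#' that of the archetype's isotropic 3-D scatter (`sqrt(3) * noise_sd`
#' on the log scale), so `separation = 3` plants well-separated
#' clusters.
#'
#' @param n_muscles Number of muscles (>= 2k).
#' @param k Number of planted archetypes (first 7 supported).
#' @param separation Center spacing in units of within-archetype SD.
#' @param noise_sd Within-archetype lognormal sdlog; 0 gives densities
#'   exactly equal to the archetype means.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list with `muscles` (phenotype table), `counts` (segment
#'   count table), `density` (the planted density matrix) and `truth`
#'   (a `simulation_truth` list: `planted_k`, `archetype_of_muscle`,
#'   `archetype_profiles`, `segment_centers`, `segment_spreads`,
#'   `phenotype_coefficients`, `seed`).
#' @export
simulate_muscle_atlas <- function(n_muscles = 28, k = 4, separation = 3,
                                  noise_sd = 0.1, seed = 1) {
  if (n_muscles < 2 * k) stop("need n_muscles >= 2k", call. = FALSE)
  if (separation <= 0) stop("separation must be positive", call. = FALSE)
  # archetype directions on the log-density scale: sparse baseline, one
  # class elevated, then two classes elevated
  dirs <- rbind(c(0, 0, 0), diag(3),
                c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  if (k > nrow(dirs)) stop("at most ", nrow(dirs), " archetypes supported",
                           call. = FALSE)
  mu0 <- log(1000)                    # baseline ~1e3 neurons per gram: with
                                      # mg-scale wet weights this yields raw
                                      # totals in the tens, like tracing data
  # spacing measured against an archetype cloud's isotropic 3-D scatter
  # (sd sqrt(3) * noise_sd on the log scale)
  step <- separation * sqrt(3) * max(noise_sd, 0.05)
  centers <- mu0 + dirs[seq_len(k), , drop = FALSE] * step
  colnames(centers) <- NEURON_CLASSES
  arch <- rep(seq_len(k), length.out = n_muscles)
  muscles_names <- sprintf("muscle_%02d", seq_len(n_muscles))

  density <- with_substream(seed, "densities", {
    exp(centers[arch, , drop = FALSE] +
          matrix(stats::rnorm(n_muscles * 3, 0, noise_sd), n_muscles, 3))
  })
  dimnames(density) <- list(muscles_names, NEURON_CLASSES)

  logtd <- log(rowSums(density))
  z <- logtd - mean(logtd)
  coef <- list(weight_slope = -3, weight_sd = 0.2,
               pennation_slope = 25, pennation_sd = 2,
               slow_fiber_slope = 10, slow_fiber_sd = 8)
  muscles <- with_substream(seed, "phenotypes", {
    w <- exp(log(0.03) + coef$weight_slope * z +
               stats::rnorm(n_muscles, 0, coef$weight_sd))
    penn <- pmax(0, 12 + coef$pennation_slope * z +
                   stats::rnorm(n_muscles, 0, coef$pennation_sd))
    slow <- pmin(100, pmax(0, 25 + coef$slow_fiber_slope * z +
                             stats::rnorm(n_muscles, 0, coef$slow_fiber_sd)))
    mlen <- exp(log(12) - 1.5 * z + stats::rnorm(n_muscles, 0, 0.1))
    flen <- mlen * stats::runif(n_muscles, 0.3, 0.7)
    pcsa <- exp(log(3) - 2 * z + stats::rnorm(n_muscles, 0, 0.2))
    data.frame(name = muscles_names,
               limb = rep(c("upper", "lower"), length.out = n_muscles),
               wet_weight = w, slow_fiber_pct = slow, muscle_length = mlen,
               fiber_length = flen, pennation_angle = penn, pcsa = pcsa,
               stringsAsFactors = FALSE)
  })

  seg_centers <- c(sensory = 25, sympathetic = 26, motor = 24)  # L4-L5 band
  seg_spreads <- c(sensory = 1.5, sympathetic = 0.8, motor = 1.2)
  counts <- with_substream(seed, "segments", {
    rows <- list()
    for (i in seq_len(n_muscles)) {
      for (cls in NEURON_CLASSES) {
        total <- as.integer(round(density[i, cls] * muscles$wet_weight[i]))
        cnt <- simulate_segment_counts(seg_centers[[cls]], seg_spreads[[cls]],
                                       total, seed = NULL)
        occ <- cnt[cnt > 0]
        if (length(occ)) {
          rows[[length(rows) + 1]] <- data.frame(
            muscle = muscles_names[i], neuron_class = cls,
            segment = names(occ), count = as.integer(occ),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(rows)) {
      data.frame(muscle = character(0), neuron_class = character(0),
                 segment = character(0), count = integer(0),
                 stringsAsFactors = FALSE)
    } else do.call(rbind, rows)
  })

  truth <- structure(list(planted_k = k,
                          archetype_of_muscle = stats::setNames(arch, muscles_names),
                          archetype_profiles = exp(centers),
                          segment_centers = seg_centers,
                          segment_spreads = seg_spreads,
                          phenotype_coefficients = coef,
                          seed = seed),
                     class = "simulation_truth")
  list(muscles = muscles, counts = validate_count_table(counts),
       density = density, truth = truth)
}

#' Simulate per-segment neuron counts
#'
#' Multinomial draw of `total` neurons over the 31 canonical ganglion
#' segments, with segment probabilities proportional to a Gaussian
#' kernel on the global index centered at `center` with SD `spread`.
#' Small spreads concentrate all mass at the nearest segment.
#'
#' @param center Real-valued global index (1-31) of the planted center.
#' @param spread Kernel SD in index units (> 0).
#' @param total Total neuron count (>= 0).
#' @param seed Optional seed; `NULL` draws from the current RNG state.
#' @return Named integer vector of counts over all 31 segments.
#' @export
simulate_segment_counts <- function(center, spread, total, seed = NULL) {
  if (spread <= 0) stop("spread must be positive", call. = FALSE)
  if (total < 0) stop("total must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed) + seed_offsets[["segments"]])
  tab <- segment_table()
  p <- stats::dnorm(tab$global_index, mean = center, sd = spread)
  if (sum(p) == 0) {  # spread so small the kernel underflows: point mass
    p <- as.numeric(tab$global_index == round(min(max(center, 1), 31)))
  }
  cnt <- if (total == 0) integer(31) else
    as.integer(stats::rmultinom(1, size = total, prob = p / sum(p)))
  stats::setNames(cnt, tab$label)
}

#' Simulate multi-platform expression datasets with planted gene modules
#'
#' Emulates the cross-platform structure the rank index is built for:
#' a fraction of genes per neuron class ("module genes") has latent
#' abundance affine in that class's density across muscles (plus
#' Gaussian noise of SD `noise_sd`, on the same [0,1] scale as the
#' resulting indices), while background genes are stably expressed
#' (constant latent level across muscles, so their between-muscle
#' variation stays below the rank resolution). Each dataset then
#' applies its own random strictly increasing piecewise-linear
#' distortion (>= 4 knots) and multiplicative replicate noise - only
#' the rank structure survives across platforms.
#'
#' @param n_genes Number of genes (default 2000).
#' @param datasets_per_muscle Datasets per muscle: a single count or a
#'   vector over muscles (default 1; use 2 to emulate a muscle profiled
#'   by two platforms).
#' @param densities Density matrix for >= 3 muscles.
#' @param module_fraction Fraction of genes per class in a module
#'   (default 0.05).
#' @param noise_sd Module-gene latent noise SD (default 0.05).
#' @param n_replicates Replicate columns per dataset (>= 3).
#' @param replicate_sd Technical noise per replicate, additive on the
#'   latent scale before the platform distortion (default 0.01; kept
#'   small so it exercises aggregation without injecting
#'   between-muscle variation into background genes).
#' @param seed Integer seed.
#' @return A list with `datasets` (list of `expression_dataset`) and
#'   `truth` (`gene_module_of`: named class or NA per gene; `seed`).
#' @export
simulate_expression <- function(n_genes = 2000, datasets_per_muscle = 1,
                                densities, module_fraction = 0.05,
                                noise_sd = 0.05, n_replicates = 3,
                                replicate_sd = 0.01, seed = 1) {
  densities <- validate_density_matrix(densities)
  if (nrow(densities) < 3) stop("need at least 3 muscles", call. = FALSE)
  if (module_fraction <= 0 || module_fraction >= 1) {
    stop("module_fraction must be in (0, 1)", call. = FALSE)
  }
  muscles <- rownames(densities)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  n_mod <- max(1L, round(module_fraction * n_genes))
  with_substream(seed, "expression", {
    module_of <- rep(NA_character_, n_genes)
    pick <- sample.int(n_genes, 3 * n_mod)
    for (ci in 1:3) {
      module_of[pick[((ci - 1) * n_mod + 1):(ci * n_mod)]] <- NEURON_CLASSES[ci]
    }
    base <- stats::runif(n_genes)            # per-gene latent baseline
    # class densities rescaled to [-0.5, 0.5] across muscles
    dscale <- apply(densities, 2, function(v) {
      if (max(v) == min(v)) rep(0, length(v))
      else (v - min(v)) / (max(v) - min(v)) - 0.5
    })
    amp <- 1
    latent <- matrix(base, n_genes, length(muscles),
                     dimnames = list(genes, muscles))
    for (ci in 1:3) {
      g <- which(module_of == NEURON_CLASSES[ci])
      latent[g, ] <- latent[g, ] +
        rep(amp * dscale[, ci], each = length(g)) +
        matrix(stats::rnorm(length(g) * length(muscles), 0, noise_sd),
               length(g), length(muscles))
    }
    datasets <- list()
    platforms <- c("Illumina NovaSeq 6000", "Illumina NextSeq 500",
                   "BGISEQ-500", "Affymetrix array")
    n_ds <- rep_len(as.integer(datasets_per_muscle), length(muscles))
    for (m in seq_along(muscles)) {
      for (d in seq_len(n_ds[m])) {
        warp <- monotone_warp(range(latent) + c(-0.1, 0.1))
        reps <- vapply(seq_len(n_replicates), function(j) {
          warp(latent[, m] + stats::rnorm(n_genes, 0, replicate_sd))
        }, numeric(n_genes))
        colnames(reps) <- paste0("rep", seq_len(n_replicates))
        rownames(reps) <- genes
        id <- sprintf("SIM%02d_%d", m, d)
        datasets[[id]] <- expression_dataset(
          id, platforms[(m + d) %% length(platforms) + 1], muscles[m], reps)
      }
    }
    truth <- structure(list(gene_module_of = stats::setNames(module_of, genes),
                            seed = seed),
                       class = "simulation_truth")
    list(datasets = datasets, truth = truth)
  })
}

# random strictly increasing piecewise-linear map from `rng` onto a
# positive abundance-like range, with >= 4 interior knots
monotone_warp <- function(rng, n_knots = 6) {
  pad <- 0.1 * (rng[2] - rng[1]) + 1e-9
  x <- c(rng[1] - pad, sort(stats::runif(n_knots, rng[1], rng[2])), rng[2] + pad)
  gaps <- stats::rexp(length(x) - 1) + 1e-6
  y <- c(0, cumsum(gaps)) / sum(gaps) * 1000    # FPKM-like scale
  function(v) stats::approx(x, y, xout = v, rule = 2)$y + 1e-6 * (v - rng[1])
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Constructs Ct values as `Ct = baseline - log2(expression) + offset +
#' noise`, where per-group log2 expression of each gene is its planted
#' fold over the first (control) group and `offset` is a per-sample
#' plate shift that cancels in dCt. At zero noise the Livak estimator
#' recovers `2^log2_fold` exactly. The reference gene has fold 0 in
#' every group.
#'
#' @param groups Character vector of group names; the first is the control.
#' @param genes Character vector of target genes.
#' @param log2_folds Matrix (genes x groups) of planted log2 fold
#'   changes vs the control, or a single number recycled for all
#'   non-control groups.
#' @param ct_noise_sd Additive Ct noise SD (default 0.1).
#' @param n_per_group Samples per group (default 3).
#' @param reference_gene Name of the reference gene row added with fold 0.
#' @param seed Integer seed.
#' @return A Ct data.frame (`sample`, `group`, `gene`, `ct`) with the
#'   planted folds in attribute `truth`.
#' @export
simulate_ct <- function(groups, genes, log2_folds, ct_noise_sd = 0.1,
                        n_per_group = 3, reference_gene = "Gapdh", seed = 1) {
  if (length(groups) < 2) stop("need a control and at least one other group",
                               call. = FALSE)
  if (!is.matrix(log2_folds)) {
    log2_folds <- matrix(log2_folds, length(genes), length(groups) - 1)
    log2_folds <- cbind(0, log2_folds)
  }
  dimnames(log2_folds) <- list(genes, groups)
  log2_folds[, 1] <- 0                       # control defines the baseline
  with_substream(seed, "ct", {
    base <- stats::setNames(stats::runif(length(genes), 18, 26), genes)
    base_ref <- 16
    rows <- list()
    for (gi in seq_along(groups)) {
      for (s in seq_len(n_per_group)) {
        sample_id <- paste0(groups[gi], "_s", s)
        offset <- stats::rnorm(1, 0, 0.5)    # plate/loading shift
        for (g in genes) {
          rows[[length(rows) + 1]] <- data.frame(
            sample = sample_id, group = groups[gi], gene = g,
            ct = base[[g]] - log2_folds[g, gi] + offset +
              stats::rnorm(1, 0, ct_noise_sd),
            stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample = sample_id, group = groups[gi], gene = reference_gene,
          ct = base_ref + offset + stats::rnorm(1, 0, ct_noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- structure(list(log2_folds = log2_folds,
                                         reference_gene = reference_gene,
                                         seed = seed),
                                    class = "simulation_truth")
    out
  })
}
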