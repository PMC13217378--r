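test_that("with full sampling and unambiguous data the consensus matrix matches a direct co-membership oracle", {
  X <- toy_separated_density()
  truth <- attr(X, "truth")
  res <- consensus_run(X, k_range = 2:4, n_resamples = 50, p_item = 1, seed = 5)
  M <- res$consensus[["3"]]
  # oracle: co-membership of the single deterministic partition
  oracle <- outer(truth, truth, "==") * 1
  dimnames(oracle) <- dimnames(M)
  expect_equal(M, oracle)
  # up to the planted k the optimum is unambiguous, so every off-diagonal
  # entry is exactly 0 or 1 (above it, ties between equal-cost splits make
  # the base learner legitimately resample-dependent)
  for (k in c("2", "3")) {
    off <- res$consensus[[k]][upper.tri(M)]
    expect_true(all(off %in% c(0, 1)))
  }
  expect_equal(res$chosen_k, 3)
})

test_that("consensus runs are bit-reproducible for a fixed seed", {
  X <- toy_separated_density()
  a <- consensus_run(X, k_range = 2:4, n_resamples = 40, seed = 9)
  b <- consensus_run(X, k_range = 2:4, n_resamples = 40, seed = 9)
  expect_identical(a, b)
  c2 <- consensus_run(X, k_range = 2:4, n_resamples = 40, seed = 10)
  expect_false(identical(a$consensus, c2$consensus))
})

test_that("consensus matrices are valid proportions with unit diagonal", {
  sim <- simulate_muscle_atlas(n_muscles = 12, k = 3, seed = 2)
  res <- consensus_run(sim$density, k_range = 2:5, n_resamples = 60, seed = 3)
  for (M in res$consensus) {
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, nrow(M)))
    expect_true(all(M[is.finite(M)] >= 0 & M[is.finite(M)] <= 1))
  }
})

test_that("CDF area matches step-function integrals on degenerate inputs", {
  m <- matrix(0, 4, 4); diag(m) <- 1
  dimnames(m) <- list(letters[1:4], letters[1:4])
  expect_equal(consensus_cdf(m)$area, 1, tolerance = 0.02)
  m1 <- matrix(1, 4, 4)
  dimnames(m1) <- dimnames(m)
  expect_equal(consensus_cdf(m1)$area, 0, tolerance = 0.02)
  mh <- m; mh[1, 2] <- mh[2, 1] <- 0; mh[1, 3] <- mh[3, 1] <- 0
  mh[1, 4] <- mh[4, 1] <- 1; mh[2, 3] <- mh[3, 2] <- 1
  mh[2, 4] <- mh[4, 2] <- 0; mh[3, 4] <- mh[4, 3] <- 1
  # off-diagonal values {0,0,0,1,1,1}: CDF is 1/2 on [0,1), area ~ 0.5
  expect_equal(consensus_cdf(mh)$area, 0.5, tolerance = 0.02)
})

test_that("clustering ambiguity at fixed k falls as the archetype gap grows", {
  # proportion of ambiguous consensus entries (PAC, values inside (0.1, 0.9))
  # shrinks to zero once two archetypes are well separated
  pac_at_gap <- function(gap) {
    set.seed(21)
    centers <- rbind(c(0, 0, 0), c(gap, 0, 0))
    X <- centers[rep(1:2, each = 6), ] + matrix(rnorm(36), 12, 3)
    dimnames(X) <- list(sprintf("m%d", 1:12), c("sensory", "sympathetic", "motor"))
    X <- X - min(X)
    res <- consensus_run(X, k_range = 2:3, n_resamples = 80, seed = 4)
    res$pac[["2"]]
  }
  expect_gt(pac_at_gap(1), pac_at_gap(20))
  expect_equal(pac_at_gap(20), 0)
})

test_that("delta-area k selection follows the stated relative-gain rule", {
  # hand-derived: deltas are 0.5, 0.8, 0.0222, 0.0054 -> first gain below
  # 0.1 is at k = 4, so k = 3 is chosen
  sel <- select_k(c(`2` = 0.5, `3` = 0.9, `4` = 0.92, `5` = 0.925), tau = 0.1)
  expect_equal(sel$chosen_k, 3)
  expect_equal(unname(sel$delta_area),
               c(0.5, 0.8, 0.02 / 0.9, 0.005 / 0.92), tolerance = 1e-12)
  # monotone flat areas: smallest k in range
  expect_equal(select_k(c(`2` = 0.6, `3` = 0.6, `4` = 0.6))$chosen_k, 2)
  # all gains above tau: largest candidate wins
  expect_equal(select_k(c(`2` = 0.2, `3` = 0.4, `4` = 0.8))$chosen_k, 4)
  expect_error(select_k(c(`2` = 0.5)), "at least 2")
  expect_error(select_k(c(`2` = 0.5, `4` = 0.9)), "consecutive")
})

test_that("final assignment recovers perfect blocks and boundary cases", {
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- 1; M[4:6, 4:6] <- 1
  dimnames(M) <- list(letters[1:6], letters[1:6])
  lab <- final_assignment(M, 2)
  expect_equal(unname(lab), rep(1:2, each = 3))
  expect_equal(length(unique(final_assignment(M, 6))), 6)  # singletons at k = n
  expect_error(final_assignment(M, 7), "between")
})

test_that("final assignment tolerates noise on a planted block structure", {
  set.seed(31)
  aris <- replicate(10, {
    truth <- rep(1:3, each = 6)
    M <- outer(truth, truth, "==") * 1
    noise <- matrix(runif(18 * 18, 0, 0.35), 18, 18)
    noise <- (noise + t(noise)) / 2
    M <- pmin(pmax(M + ifelse(M == 1, -noise, noise), 0), 1)
    diag(M) <- 1
    dimnames(M) <- list(sprintf("i%d", 1:18), sprintf("i%d", 1:18))
    ari(final_assignment(M, 3), truth)
  })
  expect_gte(median(aris), 0.9)
})

test_that("archetype naming follows dominant-class ratios with a sparse fallback", {
  X <- atlas_densities()
  lab <- atlas_cluster_labels()[rownames(X)]
  nm <- characterize_clusters(lab, X)
  expect_equal(unname(nm[c("C1", "C2", "C3", "C4")]),
               c("sympathetic neuron-rich muscle", "sensory neuron-rich muscle",
                 "neuron-sparse muscle", "motor neuron-rich muscle"))

  # planted 5x elevation names the planted class
  base <- matrix(10, 6, 3, dimnames = list(sprintf("m%d", 1:6),
                                           c("sensory", "sympathetic", "motor")))
  base[1:2, "motor"] <- 50
  nm2 <- characterize_clusters(setNames(rep(1:2, each = 2), rownames(base)[1:4]),
                               base[1:4, ])
  expect_equal(unname(nm2[1]), "motor neuron-rich muscle")

  # one cluster holding everything: ratios are all 1, tie falls to sensory
  one <- characterize_clusters(setNames(rep(1, 6), rownames(base)), base * 0 + 7)
  expect_equal(unname(one), "sensory neuron-rich muscle")
})

test_that("cluster phenotype means use available cases only", {
  ph <- atlas_phenotypes()
  lab <- atlas_cluster_labels()
  cs <- cluster_phenotype_means(lab, ph)
  c4 <- cs[cs$cluster == "C4", ]
  # three of four muscles have printed angles; the mean skips the missing one
  expect_equal(c4$n_pennation_angle, 3)
  expect_equal(c4$mean_pennation_angle, mean(c(18.56, 18.96, 3.20)))
  # cluster of one muscle: means are that muscle's values
  solo <- cluster_phenotype_means(c(Soleus = 1), ph)
  expect_equal(solo$mean_wet_weight, 0.0068)
  expect_equal(solo$mean_slow_fiber_pct, 69.4)
  # a field that is entirely missing within a cluster yields NA with n = 0
  sub <- ph[ph$name %in% c("Gastrocnemius", "Triceps"), ]
  cs2 <- cluster_phenotype_means(setNames(c(1, 1), sub$name), sub)
  expect_true(is.na(cs2$mean_pcsa))
  expect_equal(cs2$n_pcsa, 0)
})

test_that("consensus on the bundled atlas recovers the published archetypes", {
  res <- consensus_run(atlas_densities(), k_range = 2:10, n_resamples = 200,
                       seed = 17)
  expect_equal(res$chosen_k, 4)
  expect_gte(ari(res$labels, atlas_cluster_labels()[names(res$labels)]), 0.8)
  expect_setequal(unname(res$archetype_names),
                  c("sympathetic neuron-rich muscle", "sensory neuron-rich muscle",
                    "neuron-sparse muscle", "motor neuron-rich muscle"))
})

test_that("degenerate and out-of-range inputs are refused", {
  X <- toy_separated_density()
  expect_error(consensus_run(X, k_range = 2:20), "k_range")
  flat <- matrix(5, 12, 3, dimnames = dimnames(X))
  expect_error(consensus_run(flat, k_range = 2:3, n_resamples = 5), "identical")
  expect_error(consensus_run(X, k_range = 2:4, p_item = 0), "p_item")
})
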