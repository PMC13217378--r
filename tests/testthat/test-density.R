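test_that("normalize_density sums counts over segments and divides by weight", {
  X <- normalize_density(toy_counts(), toy_muscles())
  expect_equal(unname(X["soleus", "sensory"]), 21 / 0.0042)  # 5000 per gram
  expect_equal(unname(X["soleus", "motor"]), 4 / 0.0042)
  expect_equal(unname(X["tibialis", "motor"]), 0)  # no rows -> zero density
  expect_equal(rownames(X), toy_muscles()$name)
})

test_that("normalize_density flags muscles missing from the weight table", {
  expect_error(normalize_density(toy_counts(), toy_muscles()[1, ]), "tibialis")
})

test_that("density scales as one over weight", {
  m <- toy_muscles()
  X1 <- normalize_density(toy_counts(), m)
  m$wet_weight <- m$wet_weight * 2
  expect_equal(normalize_density(toy_counts(), m), X1 / 2)
})

test_that("synthetic atlas densities match brute-force totals over weights", {
  sim <- simulate_muscle_atlas(n_muscles = 10, k = 4, seed = 42)
  X <- normalize_density(sim$counts, sim$muscles)
  # independent oracle: sum the generated table directly
  for (m in sim$muscles$name) {
    for (cls in c("sensory", "sympathetic", "motor")) {
      tot <- sum(sim$counts$count[sim$counts$muscle == m &
                                    sim$counts$neuron_class == cls])
      w <- sim$muscles$wet_weight[sim$muscles$name == m]
      expect_equal(unname(X[m, cls]), tot / w)
    }
  }
})

test_that("segment profiles report proportions in canonical order", {
  counts <- data.frame(muscle = "m", neuron_class = "sensory",
                       segment = c("T1", "C8"), count = c(10L, 30L))
  p <- segment_distribution(counts, "m", "sensory")
  expect_equal(p$proportions, c(C8 = 0.75, T1 = 0.25))  # reordered rostro-caudally
  expect_equal(p$global_index, c(8, 9))
  expect_equal(p$total_count, 40L)

  single <- segment_distribution(toy_counts(), "tibialis", "sensory")
  expect_equal(unname(single$proportions), 1)

  empty <- segment_distribution(toy_counts(), "tibialis", "motor")
  expect_equal(empty$total_count, 0L)
  expect_length(empty$proportions, 0)
})

test_that("profile proportions always sum to one", {
  for (s in 1:10) {
    cnt <- simulate_segment_counts(center = 20, spread = 3, total = 200, seed = s)
    occ <- cnt[cnt > 0]
    counts <- data.frame(muscle = "m", neuron_class = "sensory",
                         segment = names(occ), count = as.integer(occ))
    p <- segment_distribution(counts, "m", "sensory")
    expect_equal(sum(p$proportions), 1, tolerance = 1e-12)
  }
})

test_that("concentration index: point mass 1, uniform 0, entropy oracle in between", {
  prof <- function(p, idx = seq_along(p)) {
    structure(list(muscle = "m", neuron_class = "sensory",
                   proportions = p, global_index = idx,
                   total_count = 100L), class = "segment_profile")
  }
  expect_equal(concentration_index(prof(c(L5 = 1))), 1)
  expect_equal(concentration_index(prof(rep(0.25, 4))), 0)
  # direct-entropy oracle
  p <- c(0.7, 0.2, 0.1)
  H <- -sum(p * log(p))
  expect_equal(concentration_index(prof(p)), 1 - H / log(3))
  # permutation invariance; maximal only at a point mass
  for (s in 1:5) {
    set.seed(s)
    q <- prop.table(runif(6))
    expect_equal(concentration_index(prof(q)), concentration_index(prof(sample(q))))
    expect_lt(concentration_index(prof(q)), 1)
  }
  expect_equal(concentration_index(prof(c(a = 0.6, b = 0.4)), method = "max_share"), 0.6)
  expect_error(concentration_index(segment_distribution(toy_counts(), "x", "motor")),
               "empty")
})

test_that("distribution centroid is the index-weighted mean and respects planted order", {
  prof <- function(p, idx) {
    structure(list(proportions = p, global_index = idx, total_count = 10L),
              class = "segment_profile")
  }
  expect_equal(distribution_centroid(prof(c(C8 = 1), 8)), 8)
  expect_equal(distribution_centroid(prof(c(C8 = 0.5, T1 = 0.5), c(8, 9))), 8.5)

  # planted centers in the order motor < sensory < sympathetic are recovered
  centers <- c(motor = 18, sensory = 21, sympathetic = 24)
  cents <- sapply(names(centers), function(cls) {
    cnt <- simulate_segment_counts(centers[[cls]], 1.2, 500, seed = 7)
    occ <- cnt[cnt > 0]
    counts <- data.frame(muscle = "m", neuron_class = cls,
                         segment = names(occ), count = as.integer(occ))
    distribution_centroid(segment_distribution(counts, "m", cls))
  })
  expect_lt(cents[["motor"]], cents[["sensory"]])
  expect_lt(cents[["sensory"]], cents[["sympathetic"]])
  expect_equal(unname(cents), unname(centers), tolerance = 0.05)
})

test_that("synthetic profiles put their mode at the planted center", {
  cnt <- simulate_segment_counts(center = 26, spread = 1.5, total = 400, seed = 11)
  expect_equal(names(which.max(cnt)), "L5")  # global index 26
  expect_equal(sum(cnt), 400)
})
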