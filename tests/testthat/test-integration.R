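make_ds <- function(id, muscle, abundance, genes = names(abundance), ...) {
  expression_dataset(id, "platform", muscle,
                     matrix(abundance, ncol = 1, dimnames = list(genes, "rep1")),
                     ...)
}

test_that("gene intersection is the sorted case-normalized common set", {
  d1 <- make_ds("d1", "soleus", c(A = 1, B = 2, C = 3))
  d2 <- make_ds("d2", "plantaris", c(b = 5, c = 1, D = 2))
  expect_equal(intersect_genes(list(d1, d2)), c("B", "C"))
  expect_equal(intersect_genes(list(d1)), c("A", "B", "C"))
  d3 <- make_ds("d3", "triceps", c(X = 1, Y = 2, Z = 3))
  expect_error(intersect_genes(list(d1, d3)), "intersection")
})

test_that("synthetic datasets share exactly the planted core genes", {
  core <- sprintf("CORE%03d", 1:50)
  sets <- lapply(1:8, function(i) {
    genes <- c(core, sprintf("PRIV%d_%02d", i, 1:10))
    set.seed(i)
    make_ds(paste0("d", i), paste0("m", i),
            stats::setNames(runif(length(genes), 1, 100), genes))
  })
  expect_equal(intersect_genes(sets), sort(core))
})

test_that("replicate aggregation is the row mean", {
  m <- matrix(c(10, 20, 30, 1, 1, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), paste0("r", 1:3)))
  ds <- expression_dataset("d", "p", "m", m)
  expect_equal(aggregate_replicates(ds), c(A = 20, B = 2))
  # random matrix against brute force
  set.seed(8)
  rm <- matrix(runif(40), 8, 5, dimnames = list(paste0("G", 1:8), paste0("r", 1:5)))
  ds2 <- expression_dataset("d2", "p", "m", rm)
  expect_equal(aggregate_replicates(ds2), apply(rm, 1, mean))
})

test_that("expression index follows 1 - rank/N with average ties", {
  expect_equal(expression_index(c(a = 9, b = 7, c = 5, d = 1)),
               c(a = 0.75, b = 0.5, c = 0.25, d = 0))
  # tied top pair: ranks (1.5, 1.5, 3)
  expect_equal(expression_index(c(x = 5, y = 5, z = 1)),
               c(x = 0.5, y = 0.5, z = 0))
  # all equal: every index is 1 - (N+1)/(2N)
  expect_equal(unname(expression_index(rep(3, 4))), rep(1 - 5 / 8, 4))
  expect_error(expression_index(7), "at least 2")
})

test_that("expression index is invariant under strictly increasing transforms", {
  set.seed(12)
  v <- stats::setNames(rexp(50), paste0("G", 1:50))
  i0 <- expression_index(v)
  expect_equal(expression_index(log1p(v)), i0)
  expect_equal(expression_index(v^3 + 2 * v), i0)
  expect_equal(expression_index(rank(v)), i0)
  # untied indices are a permutation of {0, 1/N, ..., (N-1)/N}
  expect_equal(sort(unname(i0)), (0:49) / 50)
  expect_equal(sum(i0), 49 / 2)
})

test_that("index matrix merges duplicate-muscle datasets by mean index", {
  v <- c(A = 10, B = 5, C = 2, D = 1)
  d1 <- make_ds("d1", "soleus", v)
  expect_equal(unname(build_index_matrix(list(d1))[, "soleus"]),
               unname(expression_index(v)))

  d2 <- make_ds("d2", "soleus", v * 7)          # identical ranking
  E <- build_index_matrix(list(d1, d2))
  expect_equal(E[, "soleus"], expression_index(v)[rownames(E)])
  expect_equal(attr(E, "provenance")$soleus, c("d1", "d2"))

  d3 <- make_ds("d3", "soleus", max(v) + 1 - v)  # reversed ranking
  E2 <- build_index_matrix(list(d1, d3))
  # mean of an index and its reverse: 1 - (N+1)/(2N) for every gene
  expect_equal(unname(E2[, "soleus"]), rep(1 - 5 / 8, 4))

  expect_error(build_index_matrix(list(d1, d1)), "duplicate dataset_id")
})

test_that("gene screen flags perfect trackers and excludes constant genes", {
  X <- recovery_density_7()
  E <- rbind(
    tracker = expression_index(X[, "motor"]),
    constant = rep(0.5, 7),
    anti = expression_index(-X[, "sensory"])
  )
  colnames(E) <- rownames(X)
  scr <- gene_neuron_screen(E, X)
  expect_true("tracker" %in% scr$positive$motor)
  expect_true("constant" %in% scr$excluded)
  expect_true("anti" %in% scr$negative$sensory)
  expect_true(all(!scr$table$gene %in% "constant"))
  # positive and negative lists are disjoint per class
  for (cl in names(scr$positive)) {
    expect_length(intersect(scr$positive[[cl]], scr$negative[[cl]]), 0)
  }
  expect_error(gene_neuron_screen(E[, 1:2], X[1:2, ]), "fewer than 3")
})

test_that("gene screen is invariant under jointly permuting muscles", {
  X <- recovery_density_7()
  sim <- simulate_expression(n_genes = 60, densities = X, seed = 3)
  E <- build_index_matrix(sim$datasets)
  scr1 <- gene_neuron_screen(E, X)
  perm <- c(4, 2, 7, 1, 3, 6, 5)
  scr2 <- gene_neuron_screen(E[, perm], X[perm, ])
  o1 <- scr1$table[order(scr1$table$gene, scr1$table$class), ]
  o2 <- scr2$table[order(scr2$table$gene, scr2$table$class), ]
  expect_equal(o1$r, o2$r, tolerance = 1e-12)
  expect_equal(scr1$positive, scr2$positive)
})

test_that("rank indices survive per-dataset monotone platform distortions", {
  # same latent abundances pushed through two different monotone warps
  # must give identical index matrices
  set.seed(5)
  latent <- matrix(runif(200), 50, 4,
                   dimnames = list(paste0("G", 1:50), paste0("m", 1:4)))
  warp1 <- function(v) exp(3 * v) + v
  warp2 <- function(v) log1p(v) * 100
  mk <- function(warp, tag) {
    lapply(1:4, function(m) {
      expression_dataset(paste0(tag, m), "p", paste0("m", m),
                         matrix(warp(latent[, m]), ncol = 1,
                                dimnames = list(rownames(latent), "rep1")))
    })
  }
  E1 <- build_index_matrix(mk(warp1, "a"))
  E2 <- build_index_matrix(mk(warp2, "b"))
  expect_equal(E1, E2, ignore_attr = TRUE)
})

test_that("planted gene modules are recovered by the relevance screen", {
  X <- recovery_density_7()
  pr <- sapply(1:3, function(s) {
    sim <- simulate_expression(n_genes = 500, densities = X, seed = s)
    scr <- gene_neuron_screen(build_index_matrix(sim$datasets), X)
    module_recovery(sim, scr)
  })
  expect_true(all(pr >= 0.8))
})
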