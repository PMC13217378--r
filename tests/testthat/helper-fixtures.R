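# shared fixture builders; everything is generated in code

toy_counts <- function() {
  data.frame(
    muscle = c("soleus", "soleus", "soleus", "soleus", "tibialis"),
    neuron_class = c("sensory", "sensory", "motor", "sympathetic", "sensory"),
    segment = c("L4", "L5", "L4", "L5", "C8"),
    count = c(10L, 11L, 4L, 6L, 30L),
    stringsAsFactors = FALSE
  )
}

toy_muscles <- function() {
  data.frame(
    name = c("soleus", "tibialis"),
    wet_weight = c(0.0042, 0.045),
    slow_fiber_pct = c(69.4, NA),
    pennation_angle = c(8.5, 0),
    stringsAsFactors = FALSE
  )
}

# three tight, widely separated archetypes: any sensible base learner finds
# the same partition from any start
toy_separated_density <- function(n_per = 4, gap = 100) {
  centers <- rbind(c(0, 0, 0), c(gap, 0, 0), c(0, gap, 0))
  X <- centers[rep(1:3, each = n_per), ] + 0.01 * seq_len(3 * n_per)
  dimnames(X) <- list(sprintf("m%02d", seq_len(3 * n_per)),
                      c("sensory", "sympathetic", "motor"))
  attr(X, "truth") <- rep(1:3, each = n_per)
  X
}

# 7-muscle density design used for gene-module recovery studies: one
# neuron-sparse muscle plus two muscles per class-rich archetype, so the
# three class profiles are only weakly (negatively) inter-correlated
recovery_density_7 <- function() {
  arch <- c(1, 2, 2, 3, 3, 4, 4)
  step <- 3 * sqrt(3) * 0.1
  centers <- log(1000) + rbind(c(0, 0, 0), diag(3)) * step
  X <- exp(centers[arch, ])
  dimnames(X) <- list(sprintf("m%d", 1:7), c("sensory", "sympathetic", "motor"))
  X
}

module_recovery <- function(sim, screen) {
  mo <- sim$truth$gene_module_of
  sapply(c("sensory", "sympathetic", "motor"), function(cl) {
    planted <- names(mo)[!is.na(mo) & mo == cl]
    pos <- screen$positive[[cl]]
    c(precision = if (length(pos)) mean(pos %in% planted) else NA_real_,
      recall = mean(planted %in% pos))
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
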