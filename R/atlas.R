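#' Bundled mouse limb-muscle innervation atlas
#'
#' The package ships the published reference atlas of 25 mouse limb
#' muscles: mass-normalized innervation densities (labeled neurons per
#' gram of wet muscle, from retrograde tracing of sensory, sympathetic
#' and motor neurons) together with the published four-cluster
#' archetype assignment (C1 sympathetic-rich, C2 sensory-rich, C3
#' neuron-sparse, C4 motor-rich), and the companion phenotype table
#' (wet weight measured alongside the tracing; slow-fiber percentage,
#' muscle length, fiber length, pennation angle and PCSA compiled from
#' the muscle-architecture literature). Nine of the 25 muscles have no
#' published mechanics beyond weight and fiber composition; those cells
#' are missing, not zero.
#'
#' @return `atlas_densities()`: a 25 x 3 density matrix (muscles by
#'   sensory/sympathetic/motor, neurons per gram).
#' @export
#' @examples
#' X <- atlas_densities()
#' dim(X)
atlas_densities <- function() {
  read_density_matrix(system.file("extdata", "innervation_density.tsv",
                                  package = "nervatlas", mustWork = TRUE))
}

#' @rdname atlas_densities
#' @return `atlas_cluster_labels()`: the published archetype assignment as a
#'   named character vector (`"C1"`-`"C4"`) over the 25 muscles.
#' @export
atlas_cluster_labels <- function() {
  df <- read_table_raw(system.file("extdata", "innervation_density.tsv",
                                   package = "nervatlas", mustWork = TRUE))
  stats::setNames(as.character(df$cluster), as.character(df$muscle))
}

#' @rdname atlas_densities
#' @return `atlas_phenotypes()`: the 25-muscle phenotype table as a
#'   data.frame (see [read_muscle_table()] for columns).
#' @export
atlas_phenotypes <- function() {
  read_muscle_table(system.file("extdata", "muscle_phenotypes.tsv",
                                package = "nervatlas", mustWork = TRUE))
}
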