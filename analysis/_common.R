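# Shared study conditions for the analysis scripts.
#
# The synthetic cohort emulates the structure of a resting-state study:
# P = 60 ROIs grouped into 4 intrinsic connectivity networks, K = 10 planted
# orthonormal block-structured components of inter-individual variation with
# a geometrically decaying score spectrum (sd 1.5 * 0.9^(k-1)), a shared
# block-structured mean connectome, unstructured edge noise at 10% of the
# per-edge component scale, and per-subject series lengths of 150-200
# timepoints.

library(connbasis)

RESULTS <- file.path("results", "analysis")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

STUDY_SEED <- 20260924L
SPECTRUM <- 1.5 * 0.9^(0:9)
COMM <- even_communities(60, 4)
NOISE_SD <- 0.1 * sqrt(sum(SPECTRUM^2) / n_edges(60))

study_config <- function(n_subjects = 500, with_time_series = TRUE,
                         seed = STUDY_SEED) {
  sim_config(n_subjects = n_subjects, community_assignment = COMM,
             n_components = 10, eigen_spectrum = SPECTRUM,
             mean_connectome_scale = 0.3, edge_noise_sd = NOISE_SD,
             timepoints_range = c(150, 200),
             n_phenotypes = 1,
             phenotype_coefficients = matrix(c(1, 0.8, 0.6, 0.5, 0.4,
                                               0, 0, 0, 0, 0), 10, 1),
             phenotype_noise_sd = 1,
             with_time_series = with_time_series, seed = seed)
}
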