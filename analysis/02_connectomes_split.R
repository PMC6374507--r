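#!/usr/bin/env Rscript
# Stage 2: observed connectomes and the train/test split.
#
# Regenerates the cohort (deterministic in the study seed), converts each
# subject's simulated ROI time series to a Fisher-z connectome, assembles
# the subjects x edges dataset and splits off 100 held-out test subjects.

source(file.path("analysis", "_common.R"))

sim <- simulate_subjects(study_config())
ds <- observed_dataset(sim)
message("observed dataset: ", nrow(ds$X), " subjects x ", ncol(ds$X), " edges")

sp <- split_train_test(ds, n_test = 100, seed = STUDY_SEED + 1L)
write_dataset(sp$train, file.path(RESULTS, "connectomes_train.tsv"))
write_dataset(sp$test, file.path(RESULTS, "connectomes_test.tsv"))

message("train N = ", nrow(sp$train$X), ", test N = ", nrow(sp$test$X))
message("done: observed connectome datasets under ", RESULTS)
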