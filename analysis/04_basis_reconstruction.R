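#!/usr/bin/env Rscript
# Stage 4: the PCA basis set and out-of-sample reconstruction.
#
# Learns the component basis on the training subjects, stores the leading
# 50 components, and traces how well a k-sized basis reconstructs held-out
# connectomes (Pearson correlation across edges, averaged over subjects).

source(file.path("analysis", "_common.R"))

train <- read_dataset(file.path(RESULTS, "connectomes_train.tsv"))
test <- read_dataset(file.path(RESULTS, "connectomes_test.tsv"))

bas <- fit_pca(train)
print(bas)
write_basis(bas, file.path(RESULTS, "basis"), k_keep = min(50L, bas$K_max))

pv <- percent_variance(bas$eigenvalues)
message(sprintf("top-10 components explain %.1f%% of inter-individual variance",
                sum(pv[1:10])))

rc <- reconstruction_curve(bas, test, k_grid = c(0, 1, 2, 5, 10, 20, 50,
                                                 100, 200, bas$K_max))
write.table(rc$curve, file.path(RESULTS, "reconstruction_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(rc$curve)

ceiling_r <- rc$curve$mean_r[rc$curve$k == bas$K_max]
r10 <- rc$curve$mean_r[rc$curve$k == 10]
message(sprintf("held-out reconstruction: r = %.3f at k = 10 (%.0f%% of the k = %d ceiling %.3f)",
                r10, 100 * r10 / ceiling_r, bas$K_max, ceiling_r))
message("done: basis bundle and reconstruction curve under ", RESULTS)
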