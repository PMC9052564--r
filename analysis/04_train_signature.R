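#!/usr/bin/env Rscript
# Select the 5-meta-feature signature on the training cohort by sequential
# forward selection scored with stratified fivefold cross-validated ROC-AUC,
# jointly over the candidate model grid (k-NN, Gaussian naive Bayes, SVM,
# random forest).

suppressPackageStartupMessages(library(larcradiomics))

train <- utils::read.csv("results/metafeatures_train.csv", check.names = FALSE)
x <- as.matrix(train[, setdiff(names(train), c("patient_id", "label"))])
y <- train$label

t0 <- Sys.time()
signature <- select_signature(x, y, grid = default_model_grid(),
                              signature_size = 5L, seed = 1234)
elapsed <- as.numeric(Sys.time() - t0, units = "secs")

dir.create("scratch", showWarnings = FALSE)
saveRDS(signature, "scratch/signature.rds") # fitted-object cache for step 05
jsonlite::write_json(list(
  features = signature$features, model = signature$spec$label,
  fold_aucs = unname(signature$fold_aucs),
  mean_cv_auc = signature$mean_cv_auc, sd_cv_auc = signature$sd_cv_auc,
  selection_path = signature$history),
  "results/signature.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("selected signature in %.1f s: model %s\n", elapsed,
            signature$spec$label))
for (i in seq_along(signature$features))
  cat(sprintf("  %d. %s (running mean CV AUC %.3f)\n", i,
              signature$features[i], signature$history[[i]]$mean_auc))
cat(sprintf("final CV AUC %.3f +/- %.3f over %d folds\n",
            signature$mean_cv_auc, signature$sd_cv_auc,
            length(signature$fold_aucs)))
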