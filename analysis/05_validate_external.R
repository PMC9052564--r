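#!/usr/bin/env Rscript
# Apply the frozen signature to the external validation cohort (cohort B) and
# report the ROC curve and AUC. Nothing is refitted here: scaler, clusters,
# loadings and classifier all come from the training cohort.

suppressPackageStartupMessages(library(larcradiomics))

valid <- utils::read.csv("results/metafeatures_validation.csv",
                         check.names = FALSE)
x <- as.matrix(valid[, setdiff(names(valid), c("patient_id", "label"))])
signature <- readRDS("scratch/signature.rds")

report <- validate_external(signature, x, valid$label)

utils::write.csv(report$roc, "results/roc_validation.csv", row.names = FALSE)
utils::write.csv(data.frame(patient_id = valid$patient_id,
                            label = valid$label, score = report$scores),
                 "results/scores_validation.csv", row.names = FALSE)
jsonlite::write_json(list(auc = report$auc, n = report$n),
                     "results/validation.json", auto_unbox = TRUE, digits = NA)

grDevices::png("results/roc_validation.png", width = 600, height = 600)
plot(report$roc$fpr, report$roc$sensitivity, type = "s", lwd = 2,
     xlab = "1 - specificity", ylab = "sensitivity",
     main = sprintf("External validation ROC (AUC %.3f)", report$auc))
abline(0, 1, lty = 2, col = "grey50")
grDevices::dev.off()

cat(sprintf("external validation on %d cases: AUC %.3f\n", report$n,
            report$auc))
cat(sprintf("training CV AUC was %.3f +/- %.3f\n", signature$mean_cv_auc,
            signature$sd_cv_auc))
cat("ROC points: results/roc_validation.csv\n")
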