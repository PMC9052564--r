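#!/usr/bin/env Rscript
# Fit the feature reduction on the training cohort only: IQR scaling,
# hierarchical clustering of features correlated above |r| > 0.95, one
# first-principal-component meta-feature per cluster, and the variance < 0.3
# exclusion. The frozen reducer is serialised so the validation cohort can be
# projected without refitting.

suppressPackageStartupMessages(library(larcradiomics))

features <- utils::read.csv("results/features.csv", stringsAsFactors = FALSE)
train <- features[features$cohort == "A", ]
valid <- features[features$cohort == "B", ]

reducer <- fit_reducer(train)
x_train <- apply_reducer(reducer, train)
x_valid <- apply_reducer(reducer, valid)

write_reducer(reducer, "results/reducer.json")
utils::write.csv(data.frame(patient_id = train$patient_id,
                            label = train$label, x_train),
                 "results/metafeatures_train.csv", row.names = FALSE)
utils::write.csv(data.frame(patient_id = valid$patient_id,
                            label = valid$label, x_valid),
                 "results/metafeatures_validation.csv", row.names = FALSE)

sizes <- lengths(reducer$clustering$clusters)
cat(sprintf("clustered %d features into %d clusters (largest: %d members)\n",
            sum(sizes), length(sizes), max(sizes)))
cat(sprintf("%d meta-features survive the variance filter (dropped: %d)\n",
            length(reducer$projector$names),
            length(reducer$projector$dropped)))
cat("frozen reducer: results/reducer.json\n")
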