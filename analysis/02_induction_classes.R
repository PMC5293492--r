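#!/usr/bin/env Rscript
# Fold-change normalization and induction classes. Expression values are
# normalized to the snoRNA-202 reference, folded over the naive-group
# mean, filtered with the 1.5-fold x all-replicates rule, and the induced
# features are assigned Class I (learning-specific), II (experience- and
# learning-induced) or III (experience-induced) from Welch tests on log
# fold-changes.

suppressPackageStartupMessages(library(fearmiR))

ind <- file.path("results", "study_inputs")
expr <- read_tsv(file.path(ind, "expression.tsv"))
truth <- read_tsv(file.path(ind, "truth_classes.tsv"))

fc <- normalize_and_fold(expr)
classes <- classify_induction(fc, alpha = 0.05, theta = 1.5)

dir.create(file.path("results", "tables"), showWarnings = FALSE,
           recursive = TRUE)
fearmiR:::write_tsv(fc, file.path("results", "tables", "fold_changes.tsv"))
fearmiR:::write_tsv(classes,
                    file.path("results", "tables", "induction_classes.tsv"))

mirnas <- read_fasta(file.path(ind, "mirnas.fasta"))
panel <- sort(intersect(classes$feature[classes$induced], names(mirnas)))
writeLines(panel, file.path("results", "tables", "induced_panel.txt"))

cat("Induced features (>=1.5-fold in every trained replicate):",
    sum(classes$induced), "of", nrow(classes), "\n")
cat("Induced panel miRNAs:", length(panel), "\n")
cat("Class counts among panel miRNAs:\n")
print(table(classes$class[classes$feature %in% panel]))
agree <- merge(classes, truth, by = "feature")
cat("Agreement with planted classes:",
    round(mean(agree$class.x[agree$feature %in% panel] ==
                 agree$class.y[agree$feature %in% panel]), 3), "\n")
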