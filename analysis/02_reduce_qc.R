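#!/usr/bin/env Rscript
# Reduce raw plate fluorescence to quench-corrected activity rates per gram
# dry soil, then apply the exclusion rules (negative readings, one-per-cell
# IQR outliers) and report the exclusion ledger.

library(soilenzkin)

assay <- read_assay_table("scratch/campaign/assay.csv")
soil <- read_soil_context("scratch/campaign/soil.csv")

rates <- reduce_rates(assay, soil)
qc <- qc_rates(rates)
s <- exclusion_summary(qc$ledger)

cat("Reduced", nrow(rates), "sample wells to activity rates\n")
print(s)
cat(sprintf("Excluded %d of %d data points (%.1f%%)\n",
            attr(s, "total_excluded"), attr(s, "inspected"),
            attr(s, "percent_excluded")))

write.csv(qc$rates, "scratch/rates_qc.csv", row.names = FALSE)
write.csv(s, "results/exclusion_ledger.csv", row.names = FALSE)
cat("Wrote scratch/rates_qc.csv, results/exclusion_ledger.csv\n")
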