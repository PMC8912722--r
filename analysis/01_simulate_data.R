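#!/usr/bin/env Rscript
# Stage 1 -- build the study-scale synthetic dataset.
#
# The deposited SSR genotypes of the two maple species are not
# redistributable here, so the whole workflow runs on a seeded synthetic
# emulation of the study design: 371 + 286 diploid individuals in 20 + 19
# populations, 17 loci, calibrated to the published diversity profile
# (He 0.341/0.261, Ho 0.169/0.180, 61/21 private alleles, Phi_CT 0.478,
# within-species F_ST 0.144/0.106), with 9 high-altitude introgressed
# individuals in A. caudatifolium and 14 introgressed + 1 hybrid + 5
# misassigned in A. morrisonense. Swap in the deposited files with
# read_genepop()/read_metadata_csv() to run the same stages on real data.

library(ssrdemog)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
set.seed(2024)

template <- study_template()
dataset <- generate_dataset(template)
print(dataset)

write_genepop(dataset, "results/data/maples.gen",
              title = "synthetic two-maple SSR dataset")
write_structure_table(dataset, "results/data/maples.str")
write.csv(dataset$geography, "results/data/meta.csv", row.names = FALSE)
write.table(attr(dataset, "truth"), "results/data/truth.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

fm <- attr(dataset, "freq_model")
cat(sprintf("calibrated frequency model: analytic Phi_CT %.3f, inbreeding %.2f/%.2f\n",
            fm$analytic_phi_ct, fm$inbreeding[1], fm$inbreeding[2]))
cat("wrote results/data/{maples.gen, maples.str, meta.csv, truth.tsv}\n")
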