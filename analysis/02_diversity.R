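#!/usr/bin/env Rscript
# Stage 2 -- diversity and differentiation statistics.
#
# Per-species diversity table (Ho, He, F, allele and private-allele counts),
# three-level AMOVA with 9999 permutations, pairwise F_ST within and
# between species, and the regression of per-population private-allele
# frequency on altitude, longitude and latitude.

library(ssrdemog)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
# the STRUCTURE table keeps population labels verbatim (GenePop replaces
# them with the first individual id of each block)
dataset <- attach_metadata(read_structure_table("results/data/maples.str"),
                           read_metadata_csv("results/data/meta.csv"))
set.seed(11)

div <- diversity_table(dataset)
print(div, digits = 3)
write.table(div, "results/tables/diversity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

am <- amova(dataset, "species/population", n_perm = 9999)
print(am)
write.table(am$table, "results/tables/amova.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

pw <- pairwise_fst(dataset)
cat(sprintf("mean pairwise F_ST within species: %s\n",
            paste(sprintf("%s %.3f", names(pw$within_species_mean),
                          pw$within_species_mean), collapse = ", ")))
if (!is.null(pw$species_test))
  cat(sprintf("within-species F_ST contrast (Mann-Whitney): U = %.0f, p = %.3g\n",
              pw$species_test$U, pw$species_test$p))
write.table(round(pw$fst, 4), "results/tables/pairwise_fst.tsv", sep = "\t",
            quote = FALSE)

pa <- private_alleles(dataset)
reg <- geography_regression(pa$pop_freq, dataset$geography)
print(reg, digits = 3)
write.table(reg, "results/tables/private_allele_regressions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

alt <- reg[reg$predictor == "altitude", ]
for (i in seq_len(nrow(alt)))
  cat(sprintf("private alleles vs altitude in %s: t = %.2f, p = %.3f (%s)\n",
              alt$species[i], alt$t[i], alt$p[i],
              if (alt$p[i] < 0.05) "positive association" else "no association"))

jsonlite::write_json(
  list(phi = as.list(am$phi), p = as.list(am$p),
       within_species_fst = as.list(pw$within_species_mean)),
  "results/tables/differentiation.json", auto_unbox = TRUE, digits = NA)
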