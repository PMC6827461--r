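#!/usr/bin/env Rscript
# Variant table -> observed mutant-frequency series.
#
# Sums the allele frequencies of single-nucleotide variants at the ten
# focal copy-number control sites (pBR322 3,027-3,035 and 3,118) per time
# point, drops flickering records, and converts sampling hours to
# generations at the assumed 60-minute generation time.

suppressPackageStartupMessages(library(plasmidhet))

tab <- read_variant_table("results/synthetic_variants.tsv")
series <- variant_series(tab, replicate = "S1")
write_series(series, "results/observed_series.csv")

n_flicker <- sum(!(tab$position %in% focal_site_set()))
cat(sprintf("%d records (%d flickering, excluded) -> %d series points\n",
            nrow(tab), n_flicker, nrow(series)))
print(as.data.frame(series))
cat("wrote results/observed_series.csv\n")
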