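#!/usr/bin/env Rscript
# Haplotype and regional carriage frequencies from the packaged survey
# tables (74 structure-bearing genotypes; 221 wild and 369 cultivated
# accessions sampled; four survey regions).
suppressPackageStartupMessages(library(haplogeo))
dir.create("results", showWarnings = FALSE)

ht <- read_haplotype_table()
freq <- haplotype_frequencies(ht)
write.table(freq, "results/haplotype_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- freq[order(-freq$carriers), ][1:5, ]
cat("five most frequent haplotypes:\n")
print(top, row.names = FALSE)

cat(sprintf("structure frequency: wild %s%%, cultivated %s%%\n",
            structure_frequency(sum(ht$n_rufipogon), 221)$pct,
            structure_frequency(sum(ht$n_sativa), 369)$pct))

reg <- read_region_table()
reg$structure_freq <- vapply(seq_len(nrow(reg)), function(i)
  structure_frequency(reg$n_structure_carriers[i], reg$n_accessions[i])$prop2, 0)
reg$orf79_freq <- vapply(seq_len(nrow(reg)), function(i)
  structure_frequency(reg$n_orf79_carriers[i], reg$n_accessions[i])$prop2, 0)
write.table(reg, "results/regional_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("regional carriage (structures / orf79):\n")
print(reg[, c("region", "structure_freq", "orf79_freq")], row.names = FALSE)
cat("wrote results/haplotype_frequencies.tsv, results/regional_frequencies.tsv\n")
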