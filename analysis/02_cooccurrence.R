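#!/usr/bin/env Rscript
# PTM co-occurrence: what fraction of the MetO-proteome also carries a
# second modification, and is that overlap larger than expected for random
# protein sets of the same size (plain null) and of the same abundance
# profile (quartile-matched null)?

library(metophos)

proteins <- load_proteome("results/data/proteome.fasta",
                          "results/data/abundance.tsv")
sites <- curate_metO(load_sites("results/data/sites.tsv", proteins))
meto <- unique(sites$accession[sites$kind == "sulfoxide"])

rows <- list()
for (kind in c("phospho", "ubiquityl", "acetyl")) {
  other <- unique(sites$accession[sites$kind == kind])
  res <- cooccurrence_test(proteins, meto, other, n_samples = 10000,
                           seed = 101)
  rows[[kind]] <- data.frame(
    other_ptm = kind, observed = res$observed,
    null_mean = mean(res$null$values),
    p = res$p, is_bound = res$is_bound)
  cat(sprintf("MetO vs %-9s overlap %.3f (null mean %.3f), empirical p %s\n",
              kind, res$observed, mean(res$null$values),
              format_empirical_p(res)))
}

matched <- cooccurrence_test(proteins, meto,
                             unique(sites$accession[sites$kind == "phospho"]),
                             n_samples = 10000, seed = 101, matched = TRUE)
cat(sprintf("abundance-matched phospho null: p %s (median sample KS p %.2f)\n",
            format_empirical_p(matched),
            median(matched$diagnostics$ks_p)))

out <- do.call(rbind, rows)
out <- rbind(out, data.frame(other_ptm = "phospho_abundance_matched",
                             observed = matched$observed,
                             null_mean = mean(matched$null$values),
                             p = matched$p, is_bound = matched$is_bound))
dir.create("results", showWarnings = FALSE)
write.table(out, "results/cooccurrence.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote results/cooccurrence.tsv\n")
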