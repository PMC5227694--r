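#!/usr/bin/env Rscript
# Sequence proximity between methionines and phosphosites: are oxidized
# methionines closer to phosphosites than their non-oxidized counterparts,
# both on average and in the "< 7 residues" lower tail? Also tabulates how
# many phosphosites cluster within a 10-residue radius of each methionine.

library(metophos)

proteins <- load_proteome("results/data/proteome.fasta")
sites <- curate_metO(load_sites("results/data/sites.tsv", proteins))

dt <- distance_tables(proteins, sites)
write.table(dt$records, "results/distance_records.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("distance records:", nrow(dt$records), "\n")
print(as.data.frame(dt$coverage))

cmp <- compare_met_meto(dt$records, "any_pSite", threshold = 7)
cat(sprintf("\nmean distance to closest phosphosite: MetO %.1f vs Met %.1f",
            cmp$mean_dist_metO, cmp$mean_dist_met),
    sprintf("(Welch t = %.2f, p = %.2g)\n", cmp$welch_t, cmp$welch_p))
cat(sprintf("proportion < 7 residues from a phosphosite: MetO %.2f vs Met %.2f",
            cmp$prop_within_metO, cmp$prop_within_met),
    sprintf("(Yates chi2 = %.2f, p = %.2g)\n", cmp$yates_chi2, cmp$yates_p))
write.table(cmp, "results/proximity_comparison.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# per-site-kind lower-tail comparison (pSer / pThr / pTyr / non-P acceptor)
for (kind in c("pSer", "pThr", "pTyr", "nonP_acceptor")) {
  r <- dt$records[dt$records$site_kind == kind & !is.na(dt$records$distance), ]
  if (sum(r$met_oxidized) < 2) next
  cat(sprintf("  %-14s prop<7: MetO %.2f, Met %.2f\n", kind,
              proportion_within(r$distance[r$met_oxidized]),
              proportion_within(r$distance[!r$met_oxidized])))
}

hist <- cluster_histogram(proteins, sites, radius = 10)
write.table(hist, "results/cluster_histogram.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
shares <- tapply(hist$n_met, hist$met_oxidized, sum)
cat("\nphosphosite cluster counts written (",
    shares[["TRUE"]], "MetO,", shares[["FALSE"]], "Met )\n")
cat("wrote results/{distance_records,proximity_comparison,cluster_histogram}.tsv\n")
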