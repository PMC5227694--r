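#!/usr/bin/env Rscript
# Structured-subset analysis on toy 3D structures: spatial Met-sulfur to
# acceptor-hydroxyl distances, the sequence-distance comparison restricted
# to structured proteins (same code path as the primary-structure
# analysis), and secondary-structure occupancy of Met vs MetO.

library(metophos)

proteins <- load_proteome("results/data/proteome.fasta")
sites <- curate_metO(load_sites("results/data/sites.tsv", proteins))

# a structured subset of 40 proteins stands in for the PDB-resolved subset
subset <- proteins[1:40, ]
structures <- simulate_structures(subset, seed = 404)

sd <- structure_distances(structures, subset, sites)
write.table(sd, "results/structure_distances.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

ox <- sd$met_oxidized
cat("structured subset:", length(unique(sd$accession)), "proteins,",
    sum(!ox), "Met and", sum(ox), "MetO\n")
if (sum(ox) >= 2) {
  wt_seq <- welch_t(sd$seq_dist[ox], sd$seq_dist[!ox])
  wt_sp <- welch_t(sd$spatial_dist[ox], sd$spatial_dist[!ox])
  cat(sprintf("sequence distance:  MetO %.1f vs Met %.1f (Welch p = %.2g)\n",
              mean(sd$seq_dist[ox]), mean(sd$seq_dist[!ox]), wt_seq$p))
  cat(sprintf("spatial distance:   MetO %.1f vs Met %.1f Angstrom (Welch p = %.2g)\n",
              mean(sd$spatial_dist[ox]), mean(sd$spatial_dist[!ox]), wt_sp$p))
}

props <- ss_proportions(sd)
write.table(props, "results/ss_proportions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nsecondary-structure occupancy (proportion per DSSP code):\n")
print(as.data.frame(props))
cat("wrote results/{structure_distances,ss_proportions}.tsv\n")
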