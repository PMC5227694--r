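#!/usr/bin/env Rscript
# Window statistics around phospho-acceptors: mean Met and MetO per +/-7
# window for phosphosites vs acceptor-resampling nulls (per residue type),
# and the positional P-7..P+7 profile for phosphoserines.

library(metophos)

proteins <- load_proteome("results/data/proteome.fasta")
sites <- curate_metO(load_sites("results/data/sites.tsv", proteins))

aw <- acceptor_windows(proteins, sites, halfwidth = 7)
write.table(aw, "results/acceptor_windows.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

for (r in c("S", "T", "Y")) {
  wr <- aw[aw$acceptor_residue == r, ]
  np <- sum(wr$is_phosphosite)
  if (np == 0) next
  obs <- mean_per_site(wr[wr$is_phosphosite, ])
  nd_met <- acceptor_null(wr, np, "n_met", n_samples = 10000, seed = 505)
  nd_ox <- acceptor_null(wr, np, "n_metO", n_samples = 10000, seed = 505)
  p_met <- empirical_p(nd_met, obs$mean_met, "lower")
  p_ox <- empirical_p(nd_ox, obs$mean_metO, "upper")
  cat(sprintf("p%s: %d phosphosites of %d acceptors\n", r, np, nrow(wr)))
  cat(sprintf("  mean Met/site  %.3f vs null %.3f (lower-tail p %s)\n",
              obs$mean_met, mean(nd_met$values), format_empirical_p(p_met)))
  cat(sprintf("  mean MetO/site %.3f vs null %.3f (upper-tail p %s)\n",
              obs$mean_metO, mean(nd_ox$values), format_empirical_p(p_ox)))
}

pr <- positional_profile(proteins, sites, "S", halfwidth = 7)
write.table(pr$profile, "results/positional_profile_S.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("\npSer positional profile over %d phosphosites;", pr$n_phosphosites),
    sprintf("control band %.2f-%.2f%%\n", pr$control_band["lower"],
            pr$control_band["upper"]))
top <- pr$profile[order(-pr$profile$metO_per_500), ][1:3, ]
cat("offsets with most MetO per 500 phosphosites:",
    paste(sprintf("%+d (%.1f)", top$offset, top$metO_per_500),
          collapse = ", "), "\n")
cat("wrote results/{acceptor_windows,positional_profile_S}.tsv\n")
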