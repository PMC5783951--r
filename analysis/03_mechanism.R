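#!/usr/bin/env Rscript
# Probes the proposed cause of the reversion excess: traits coupled to a
# latent fitness that collapses at the plastic stage and recovers after
# re-adaptation. Finding: the PC > TC fraction q rises as the plastic
# fitness drop deepens, mean PC falls as f_p -> 1, the observed C_RI/C_RV
# tracks the geometric null (1-q)/(1+q) when effects are symmetric, and
# dropping PC > TC traits abolishes the reversion excess.

suppressPackageStartupMessages(library(plastevo))
dir.create("results", showWarnings = FALSE)

cat("Fitness-coupled triplets across plastic fitness drops (n = 10000):\n")
grid <- lapply(c(0.05, 0.1, 0.3, 0.6, 0.9, 1.0), function(fp) {
  s <- summarize_adaptation(classify_traits(
    gen_mechanism_triplets(mechanism_spec(f_p = fp, n_traits = 10000,
                                          seed = 2)), theta = 0.2))
  cat(sprintf("  f_p=%4.2f  q=%.3f  C_RV=%.3f  C_RI=%.3f  mean_PC=%8.3f\n",
              fp, s$q, s$c_rv, s$c_ri, s$mean_pc))
  cbind(data.frame(f_p = fp), s)
})
grid <- do.call(rbind, grid)
write.table(grid, "results/mechanism_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Spearman rho(f_p, mean PC) = %.3f (deeper drops, larger plastic changes)\n\n",
            cor(grid$f_p, grid$mean_pc, method = "spearman")))

cat("Geometric null: observed C_RI/C_RV vs (1-q)/(1+q) at planted q:\n")
law <- lapply(c(0, 0.2, 0.5, 0.85), function(q) {
  s <- summarize_adaptation(classify_traits(gen_planted_q(10000, q, seed = 3),
                                            theta = 0.2))
  cat(sprintf("  q=%4.2f  observed=%.4f  expected=%.4f\n",
              q, s$ri_rv_ratio, expected_ratio(q)))
  data.frame(q = q, observed_ratio = s$ri_rv_ratio,
             expected_ratio = expected_ratio(q))
})
law <- do.call(rbind, law)
write.table(law, "results/mechanism_law.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cl <- classify_traits(gen_planted_q(20000, q = 0.85, seed = 4), theta = 0.2)
after <- summarize_adaptation(drop_pc_gt_tc(cl))
cat(sprintf("\nAfter dropping PC > TC traits at q = 0.85: C_RI = %.3f, C_RV = %.3f (p = %.2f)\n",
            after$c_ri, after$c_rv, after$p_two_tailed))
cat("Wrote results/mechanism_grid.tsv and results/mechanism_law.tsv\n")
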