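#!/usr/bin/env Rscript
# Step 4: open-vs-closed comparison.
#
# Pairs residues between the two conformers, writes the difference-distance
# map with its +/-1.5 A classification and the slowest-mode fluctuation
# difference, and measures the inter-domain rotation angle by two-stage
# Kabsch superposition (domain A fixed, domain B moving). On this synthetic
# pair the angle should recover the generator's 41.3 degrees and the
# within-domain blocks of the difference-distance map should be zero: the
# conformational change is a rigid rotation of intact domains.

library(enmconf)

labels <- jsonlite::read_json("results/structures/synthetic_labels.json",
                              simplifyVector = TRUE)
cfg <- enm_config(fixed_domain = labels$domain_a,
                  moving_domain = labels$domain_b)

res <- run_compare("results/structures/synthetic_open.pdb",
                   "results/structures/synthetic_closed.pdb",
                   "results/compare", cfg)

cat(sprintf("paired %d residues (coverage %.2f)\n", res$n_pairs, res$coverage))
cat(sprintf("inter-domain rotation: %.3f deg (truth %.1f), fixed-domain rmsd %.2e A\n",
            res$rotation$angle_deg, labels$true_angle_deg, res$rotation$rmsd_fixed))

delta <- as.matrix(utils::read.csv("results/compare/difference_distance.csv",
                                   header = FALSE))
ia <- labels$domain_a; ib <- labels$domain_b
cat(sprintf("difference-distance map: max |delta| within domains %.2e A, across domains %.1f A\n",
            max(abs(delta[ia, ia]), abs(delta[ib, ib])), max(abs(delta[ia, ib]))))
cat(sprintf("entries beyond +/-%.1f A: %.1f%% (all cross-domain)\n", res$ddm_threshold,
            100 * mean(abs(delta) >= res$ddm_threshold)))
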