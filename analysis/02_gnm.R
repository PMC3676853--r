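#!/usr/bin/env Rscript
# Step 2: GNM fluctuation analysis of both conformers.
#
# Builds the 7.3 A Kirchhoff matrix for each form, fits kBT/gamma to the
# B-factor column, and writes per-residue profiles (msf, predicted B,
# slowest-mode shape, fast-mode average and contact numbers at 7.3 and 9 A)
# plus the all-mode cross-correlation map. The printed summary reports the
# fitted scale, the B-factor correlation, and the detected hinge and hot
# residues; on this synthetic system the hinges should fall in the labelled
# linker (residues 41-45).

library(enmconf)

for (form in c("open", "closed")) {
  pdb <- file.path("results/structures", sprintf("synthetic_%s.pdb", form))
  res <- run_gnm(pdb, file.path("results", paste0("gnm_", form)))
  cat(sprintf("\n[%s] N = %d residues\n", form, res$n_residues))
  if (!is.null(res$pearson_r)) {
    cat(sprintf("  fitted kBT/gamma = %.3f A^2, B-factor Pearson r = %.3f\n",
                res$scale_kbt_over_gamma, res$pearson_r))
  } else {
    cat("  no B-factor column; profiles written at unit scale\n")
  }
  cat("  hinge residues (slowest mode minima):",
      paste(res$hinge_residues, collapse = ", "), "\n")
  for (h in res$hot_residues) {
    cat(sprintf("  hot residues at %.1f A: %s (mean contact %.1f vs %.1f overall)\n",
                h$cutoff, paste(h$peak_residues, collapse = ", "),
                h$mean_contact_hot, h$mean_contact_all))
  }
}
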