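#!/usr/bin/env Rscript
# Demonstrate the rigid-body helix displacement signature: inject known
# helix III translations into a clean bundle and contrast the in-bundle
# deviation (high) with the isolated-helix fit rmsd (low), plus the
# recovery accuracy of the injected magnitude.

suppressPackageStartupMessages(library(tmbundle))
set.seed(404)
base <- build_bundle()
ref <- extract_bundle(base$chain, base$map)

rows <- NULL
for (d in c(0.5, 1, 2, 4)) {
  ch <- perturb(base$chain, base$map, helix = 3,
                translation = c(d, 0, 0), sigma = 0.2,
                seed = 900 + round(10 * d))
  r <- isolated_helix_comparison(list(extract_bundle(ch, base$map)),
                                 3L, ref, "ssm")
  rows <- rbind(rows, data.frame(
    injected = d, bundle_frame_dev = r$bundle_frame_dev,
    rigid_disp = r$rigid_disp, isolated_rmsd = r$isolated_rmsd,
    recovery_error = abs(r$bundle_frame_dev - d)))
}
dir.create("results", showWarnings = FALSE)
write.table(format(rows, digits = 3), "results/helix3_recovery.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(rows, digits = 3)
cat(sprintf("\nmax recovery error %.3f A; isolated-fit rmsd stays at the noise floor\n",
            max(rows$recovery_error)))
cat("=> in-bundle deviation with an invariant isolated shape is the\n")
cat("   rigid-body displacement signature\n")
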