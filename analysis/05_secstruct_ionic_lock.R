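#!/usr/bin/env Rscript
# Secondary-structure regularity and ionic-lock detection on synthetic
# bundles with full backbones and constructed side chains.

suppressPackageStartupMessages(library(tmbundle))
b <- build_bundle(with_backbone = TRUE)
bb <- backbone_residues(b$chain)
ss <- assign_helix(bb)
def <- bundle_definition()
starts <- cumsum(c(1, head(def$length, -1)))
frac <- vapply(1:7, function(h) {
  sel <- starts[h]:(starts[h] + def$length[h] - 1L)
  mean(ss$labels[sel] == "H")
}, 0)
cat("fraction H per helix:", sprintf("%.2f", frac), "\n")

ca3 <- as.matrix(bb[starts[3]:(starts[3] + def$length[3] - 1L),
                    c("ca_x", "ca_y", "ca_z")])
cat(sprintf("helix III max kink angle: %.1f deg (regular: %s)\n",
            max(kink_angle(ca3)), is_regular_helix(ca3)))

r350 <- bw_to_author(b$map, "3.50")
r630 <- bw_to_author(b$map, "6.30")
rows <- NULL
for (d in c(2.8, 3.5, 4.5)) {
  ch <- add_ionic_lock_sidechains(b$chain, r350, r630, "GLU", d)
  st <- ionic_lock_state(ch, b$map)
  rows <- rbind(rows, data.frame(n_o_distance = d, state = st$state,
                                 measured = round(st$min_distance, 2)))
}
# right residues but no side-chain atoms resolved -> indeterminate
seqs <- rep("A", 200)
seqs[serial_of("3.50") + 1L] <- "R"
seqs[serial_of("6.30") + 1L] <- "E"
bare <- build_bundle(sequence = paste(seqs, collapse = ""))$chain
rows <- rbind(rows, data.frame(n_o_distance = NA,
                               state = ionic_lock_state(bare, b$map)$state,
                               measured = NA))
dir.create("results", showWarnings = FALSE)
write.table(rows, "results/ionic_lock_demo.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(rows)
cat("locked iff an acidic 6.30 carboxylate sits within 4.0 A of the\n")
cat("Arg 3.50 guanidinium; bundles without side chains are indeterminate\n")
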