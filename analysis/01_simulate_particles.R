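#!/usr/bin/env Rscript
# Build the synthetic study particles: a closed 147-bp superhelix wrap and a
# series of clamshell-opened variants, with ground-truth pairing tables.
# Outputs: results/structures/*.pdb, results/duplex_table.csv,
#          results/opening_series.csv

library(gyredyn)

dir.create("results/structures", recursive = TRUE, showWarnings = FALSE)

sh <- make_superhelix_duplex()           # canonical closed particle
write_structure(sh$structure, "results/structures/superhelix_closed.pdb")
duplex_table(sh$duplex, "results/duplex_table.csv")

# verify the generator/detector closure before using the particle downstream
pairs <- detect_base_pairs(sh$structure)
stopifnot(nrow(pairs) == 147L)
dup <- build_duplex(pairs)
stopifnot(identical(dup$pairs$index_from_dyad, sh$duplex$pairs$index_from_dyad))
cat("closure: detector recovered all 147 ground-truth pairs\n")

# clamshell-opened variants: one gyre translated along the superhelix axis
open_tab <- do.call(rbind, lapply(c(0, 5, 10, 15, 20), function(dz) {
  moved <- open_clamshell(sh, delta_z = dz)
  if (dz %in% c(0, 10, 20))
    write_structure(moved$structure,
                    sprintf("results/structures/superhelix_open_dz%02d.pdb", dz))
  cbind(delta_z_A = dz, gyre_metrics(moved$duplex))
}))
write.csv(open_tab, "results/opening_series.csv", row.names = FALSE)
cat("opening series (theta rises with the imposed gapping):\n")
print(open_tab[, c("delta_z_A", "theta_deg", "distance_A")], row.names = FALSE)
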