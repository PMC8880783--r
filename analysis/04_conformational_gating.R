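#!/usr/bin/env Rscript
# Conformational gating between states: per-pair distance deltas with
# threshold-crossing flags, and the rigid-body rotation of the mobile
# C1-bearing domain recovered by core superposition.

suppressMessages(library(cofanet))
seed <- 1L
dir.create("results", showWarnings = FALSE)
lm <- hydabcsl_label_map()

apo <- make_hydabcsl_fixture("apo", seed = seed)
br <- make_hydabcsl_fixture("BR", seed = seed)
pb <- make_hydabcsl_fixture("PB", seed = seed)
cof <- function(s) detect_cofactors(s, label_map = lm)

gates <- compare_states(cof(br), cof(pb),
                        pairs = c("C1:B2", "C1:FMN", "B2:B3"),
                        tau = 14, states = c("BR", "PB"))
print(as.data.frame(gates))
write.table(as.data.frame(gates), "results/gating_br_vs_pb.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nC1-B2 closes from ~19 to ~13.4 A (crosses the 14 A threshold);",
    "B2-B3 remains just outside at ~17 A.\n\n")

apo_pb <- compare_states(cof(apo), cof(pb), pairs = "C1:B2",
                         tau = 14, states = c("apo", "PB"))
print(as.data.frame(apo_pb))

# domain rotation: construct a 24-degree swing of the C1-bearing chain and
# recover it from the coordinates alone
rot <- make_rotated_state(pb, "chain C", 24, c(0.36, 0.48, 0.8),
                          pivot = c(10, 0, 0))
dmn <- domain_rotation(pb, rot, core = "chain A or chain B",
                       domain = "chain C")
cat(sprintf("\nrecovered domain rotation: %.3f degrees about (%.2f, %.2f, %.2f)\n",
            dmn$angle, dmn$axis[1], dmn$axis[2], dmn$axis[3]))
jsonlite::write_json(
  list(angle_deg = dmn$angle, axis = dmn$axis,
       translation_along_axis = dmn$translation_along_axis,
       core_rmsd = dmn$core_rmsd, n_core = dmn$n_core),
  "results/domain_rotation.json", auto_unbox = TRUE, digits = NA)
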