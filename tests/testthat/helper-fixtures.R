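# Shared fixtures, memoized per test run (generation is seeded and cheap,
# but the same structures are used by many files).

.fixture_cache <- new.env(parent = emptyenv())

hyd_fixture <- function(state, seed = 1, dimer = FALSE) {
  key <- paste(state, seed, dimer, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_hydabcsl_fixture(state, dimer = dimer,
                                                   seed = seed)
  .fixture_cache[[key]]
}

hyd_cofactors <- function(state, seed = 1) {
  key <- paste("cof", state, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- detect_cofactors(hyd_fixture(state, seed),
                                              label_map = hydabcsl_label_map())
  .fixture_cache[[key]]
}

hyd_dmat <- function(state, seed = 1) {
  key <- paste("dmat", state, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- distance_matrix(hyd_cofactors(state, seed))
  .fixture_cache[[key]]
}

pair_dist <- function(dmat, a, b) {
  r <- dmat[(dmat$label_a == a & dmat$label_b == b) |
              (dmat$label_a == b & dmat$label_b == a), ]
  stopifnot(nrow(r) == 1)
  r
}

# Minimal Cofactor construction for geometry/graph tests that do not need
# a full Structure.
point_cofactor <- function(label, xyz, type = "FES4") {
  xyz <- matrix(xyz, ncol = 3)
  atoms <- data.frame(
    element = "FE", atom_name = paste0("FE", seq_len(nrow(xyz))),
    residue_name = "SF4", residue_number = 1L, insertion_code = "",
    chain_id = "X", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = "", model_index = 1L, is_hetero = TRUE,
    stringsAsFactors = FALSE)
  cofanet:::new_cofactor(label, type, atoms, atoms)
}

random_cofactors <- function(n, atoms_each = 5, spread = 30) {
  lapply(seq_len(n), function(i) {
    center <- runif(3, -spread, spread)
    xyz <- sweep(matrix(rnorm(3 * atoms_each), ncol = 3), 2, center, "+")
    point_cofactor(sprintf("N%02d", i), xyz)
  })
}

# Structure with two chains of random protein atoms, for superposition
# tests needing many paired atoms.
two_domain_structure <- function(n_core = 60, n_dom = 60) {
  mk <- function(n, chain, offset) if (n == 0) NULL else data.frame(
    element = "C", atom_name = "CA", residue_name = "ALA",
    residue_number = seq_len(n), insertion_code = "", chain_id = chain,
    x = rnorm(n, offset[1], 8), y = rnorm(n, offset[2], 8),
    z = rnorm(n, offset[3], 8),
    occupancy = 1, altloc = "", model_index = 1L, is_hetero = FALSE,
    stringsAsFactors = FALSE)
  structure_from_atoms(rbind(mk(n_core, "A", c(0, 0, 0)),
                             mk(n_dom, "D", c(25, 0, 0))))
}
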