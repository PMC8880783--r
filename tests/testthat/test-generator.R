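# Synthetic constellation generator: determinism, constraint satisfaction,
# packaged fixture properties.

# independent measurement: group atoms by (chain, resnum range) entry and
# take the minimum inter-atom distance between two entries' atom sets
measure_entry_edge <- function(s, ent, la, lb) {
  get_xyz <- function(lab) {
    e <- ent[ent$label == lab, ]
    rn <- e$residue_number + 0:1   # NIFE spans two residue numbers
    a <- s$atoms[s$atoms$chain_id == e$chain_id &
                   s$atoms$residue_number %in% rn, ]
    as.matrix(a[, c("x", "y", "z")])
  }
  oracle_edge_distance(get_xyz(la), get_xyz(lb))
}

test_that("generation is bit-for-bit reproducible given the seed", {
  s1 <- make_hydabcsl_fixture("PB", seed = 5)
  s2 <- make_hydabcsl_fixture("PB", seed = 5)
  expect_identical(s1$atoms, s2$atoms)
  s3 <- make_hydabcsl_fixture("PB", seed = 6)
  expect_false(isTRUE(all.equal(s1$atoms$x, s3$atoms$x)))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(make_hydabcsl_fixture("apo", seed = 2))
  expect_identical(rnorm(1), before)
})

test_that("an empty spec yields an empty structure", {
  s <- make_constellation(placement_spec(data.frame()))
  expect_equal(n_atoms(s), 0)
})

test_that("random feasible specs are realized within tolerance (100 seeds)", {
  set.seed(41)
  types <- c("FES4", "FES2", "FMN", "NAD", "NIFE")
  for (case in 1:100) {
    n <- sample(3:6, 1)
    ent <- data.frame(label = paste0("L", seq_len(n)),
                      type = sample(types, n, replace = TRUE),
                      stringsAsFactors = FALSE)
    # random spanning tree keeps the system feasible by construction
    parent <- vapply(2:n, function(i) sample(i - 1, 1), integer(1))
    con <- data.frame(a = ent$label[parent], b = ent$label[2:n],
                      target = round(runif(n - 1, 16, 24), 2),
                      stringsAsFactors = FALSE)
    spec <- placement_spec(ent, con, repulsion_floor = 15, seed = case)
    s <- make_constellation(spec)
    for (r in seq_len(nrow(con))) {
      got <- measure_entry_edge(s, spec$entries, con$a[r], con$b[r])
      expect_lt(abs(got - con$target[r]), 0.05)
    }
    # unconstrained pairs respect the repulsion floor
    ck <- paste(pmin(con$a, con$b), pmax(con$a, con$b))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      la <- ent$label[i]; lb <- ent$label[j]
      if (paste(pmin(la, lb), pmax(la, lb)) %in% ck) next
      expect_gt(measure_entry_edge(s, spec$entries, la, lb), 15 - 1e-6)
    }
  }
})

test_that("infeasible constraint systems raise an infeasibility error", {
  ent <- data.frame(label = c("P", "Q", "R"), type = "FES2")
  con <- data.frame(a = c("P", "Q", "P"), b = c("Q", "R", "R"),
                    target = c(5, 5, 60))
  spec <- placement_spec(ent, con, repulsion_floor = 4, seed = 1)
  expect_error(make_constellation(spec, max_iter = 60L, restarts = 2L),
               "infeasib")
  # a constraint inside one rigid group can never be solved
  ent2 <- data.frame(label = c("U", "V"), type = "FES2", group = "g")
  expect_error(make_constellation(
    placement_spec(ent2, data.frame(a = "U", b = "V", target = 10))),
    "rigid group")
})

test_that("every encoded fixture distance is realized in each state", {
  tol <- 0.06
  checks <- list(
    apo = list(c("C1", "B2", 19.0), c("B2", "B3", 18.0), c("B5", "C1", 11.0),
               c("B1", "C1", 22.5)),
    BR  = list(c("C1", "B2", 19.0), c("B2", "B3", 18.0),
               c("FMN", "B1", 6.0), c("C1", "FMN", 15.5)),
    PB  = list(c("C1", "B2", 13.4), c("B2", "B3", 17.0), c("C1", "B3", 17.4),
               c("FMN", "B1", 6.0), c("C1", "FMN", 13.0)))
  for (state in names(checks)) {
    dm <- hyd_dmat(state)
    for (ck in checks[[state]]) {
      got <- pair_dist(dm, ck[1], ck[2])$edge_distance
      expect_equal(got, as.numeric(ck[3]), tolerance = tol / as.numeric(ck[3]),
                   info = paste(state, ck[1], ck[2]))
    }
    expect_gt(pair_dist(dm, "B1", "C1")$edge_distance, 22)
  }
})

test_that("the stacked nicotinamide sits at the hydride-transfer contact", {
  for (state in c("BR", "PB")) {
    cofs <- hyd_cofactors(state)
    labs <- vapply(cofs, `[[`, character(1), "label")
    fmn <- cofs[[match("FMN", labs)]]$atoms
    nad <- cofs[[match("NAD", labs)]]$atoms
    n5 <- as.numeric(fmn[fmn$atom_name == "N5", c("x", "y", "z")])
    c4 <- as.numeric(nad[nad$atom_name == "C4", c("x", "y", "z")])
    expect_equal(sqrt(sum((n5 - c4)^2)), 4.2, tolerance = 1e-6)
  }
})

test_that("fixtures round-trip through both formats and re-detect exactly", {
  for (state in c("apo", "PB")) {
    s <- hyd_fixture(state)
    ref <- table(vapply(hyd_cofactors(state), `[[`, character(1), "type"))
    for (fmt in c("pdb", "mmcif")) {
      f <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
      write_structure(s, f, format = fmt)
      got <- table(vapply(
        detect_cofactors(read_structure(f)), `[[`, character(1), "type"))
      expect_equal(as.list(got), as.list(ref), info = paste(state, fmt))
    }
  }
})

test_that("the dimer places the second pentamer beyond transfer distance", {
  s <- hyd_fixture("apo", dimer = TRUE)
  a <- s$atoms[s$atoms$chain_id %in% c("A", "B", "C", "S", "L"), ]
  b <- s$atoms[!(s$atoms$chain_id %in% c("A", "B", "C", "S", "L")), ]
  expect_gt(nrow(b), 0)
  expect_gt(oracle_edge_distance(as.matrix(a[, c("x", "y", "z")]),
                                 as.matrix(b[, c("x", "y", "z")])), 40)
  # both pentamers detected: inventory doubles
  inv <- stoichiometry(detect_cofactors(s))
  expect_equal(inv$fe_total, 82L)
  expect_equal(inv$ni_total, 2L)
})

test_that("fixture pathway properties hold across seeds", {
  for (seed in 2:4) {
    cofs <- detect_cofactors(make_hydabcsl_fixture("PB", seed = seed),
                             label_map = hydabcsl_label_map())
    labs <- vapply(cofs, `[[`, character(1), "label")
    g <- build_et_graph(cofs, tau = 14,
                        terminals = hydabcsl_terminals(labs))
    ps <- enumerate_paths(g, "FMN", "NiFe")
    expect_length(ps, 1)
    expect_equal(ps[[1]]$labels,
                 c("FMN", "B1", "A1", "A2", "A3", "S1", "NiFe"))
    tp <- topology(g)
    expect_true(all(c("A2", "C1") %in% tp$branch_points))
    expect_true(all(c("A5", "B5") %in% tp$dead_ends))
  }
})

test_that("cluster templates keep their internal metal geometry", {
  sf4 <- cofactor_template("FES4")
  fe <- as.matrix(sf4[sf4$element == "FE", c("x", "y", "z")])
  dd <- as.vector(stats::dist(fe))
  expect_true(all(dd >= 2.6 & dd <= 2.8))
  fes <- cofactor_template("FES2")
  fe2 <- as.matrix(fes[fes$element == "FE", c("x", "y", "z")])
  expect_equal(as.vector(stats::dist(fe2)), 2.7, tolerance = 1e-9)
  nife <- cofactor_template("NIFE")
  expect_equal(sqrt(sum((as.numeric(nife[1, c("x", "y", "z")]) -
                           as.numeric(nife[2, c("x", "y", "z")]))^2)),
               2.6, tolerance = 1e-9)
})
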