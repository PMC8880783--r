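# Threshold graphs, topology classification, path enumeration and
# minimax (bottleneck) paths.

random_graph_case <- function(n, spread = 18) {
  cofs <- random_cofactors(n, atoms_each = 3, spread = spread)
  dmat <- distance_matrix(cofs)
  tau <- stats::quantile(dmat$edge_distance, runif(1, 0.3, 0.8))
  list(cofs = cofs, dmat = dmat, tau = unname(tau),
       labels = vapply(cofs, `[[`, character(1), "label"))
}

test_that("state-dependent gating opens and closes the expected edges at 14", {
  edges_of <- function(state) {
    g <- build_et_graph(hyd_cofactors(state), tau = 14)
    apply(igraph::as_edgelist(g$graph), 1,
          function(r) paste(sort(r), collapse = "-"))
  }
  apo <- edges_of("apo"); pb <- edges_of("PB")
  expect_false("B2-C1" %in% apo)
  expect_false("B2-B3" %in% apo)
  expect_true("B2-C1" %in% pb)
  expect_false("B2-B3" %in% pb)
  expect_true("B5-C1" %in% apo)   # the 11 Angstrom apo contact
})

test_that("threshold bounds are enforced and extreme values behave", {
  cofs <- hyd_cofactors("apo")
  expect_error(build_et_graph(cofs, tau = 0), "tau")
  expect_error(build_et_graph(cofs, tau = -3), "tau")
  g <- build_et_graph(cofs, tau = 1e6)
  n <- length(cofs)
  expect_equal(igraph::ecount(g$graph), n * (n - 1) / 2)
  expect_error(build_et_graph(cofs, terminals = "NOPE"), "terminal")
})

test_that("the edge set grows monotonically with the threshold", {
  dmat <- hyd_dmat("PB")
  cofs <- hyd_cofactors("PB")
  prev <- character()
  for (tau in c(3, 6, 9, 12, 14, 17, 20, 30, 60)) {
    g <- build_et_graph(cofs, tau = tau, dmat = dmat)
    cur <- apply(igraph::as_edgelist(g$graph), 1,
                 function(r) paste(sort(r), collapse = "-"))
    expect_true(all(prev %in% cur))
    if (igraph::ecount(g$graph) > 0)
      expect_true(all(igraph::E(g$graph)$edge_distance <= tau))
    prev <- cur
  }
})

test_that("topology classification matches a brute-force degree tally", {
  set.seed(21)
  for (k in 1:15) {
    case <- random_graph_case(sample(4:9, 1))
    terms <- sample(case$labels, sample(0:2, 1))
    g <- build_et_graph(case$cofs, tau = case$tau, terminals = terms)
    adj <- case$dmat[case$dmat$edge_distance <= case$tau, , drop = FALSE]
    deg <- table(factor(c(adj$label_a, adj$label_b), levels = case$labels))
    tp <- topology(g)
    expect_equal(unname(tp$degrees[case$labels]), unname(as.integer(deg)))
    expect_setequal(tp$branch_points, names(deg)[deg >= 3])
    expect_setequal(tp$dead_ends, setdiff(names(deg)[deg == 1], terms))
    expect_setequal(unlist(tp$components), case$labels)
    expect_length(intersect(tp$branch_points, tp$dead_ends), 0)
  }
})

test_that("path enumeration matches an exhaustive DFS oracle", {
  set.seed(22)
  for (k in 1:12) {
    case <- random_graph_case(sample(4:8, 1))
    g <- build_et_graph(case$cofs, tau = case$tau)
    adj <- case$dmat[case$dmat$edge_distance <= case$tau, , drop = FALSE]
    ends <- sample(case$labels, 2)
    got <- enumerate_paths(g, ends[1], ends[2], exclude_terminals = FALSE)
    want <- oracle_simple_paths(as.matrix(adj[, c("label_a", "label_b")]),
                                ends[1], ends[2], case$labels)
    expect_length(got, length(want))
    expect_setequal(vapply(got, function(p) paste(p$labels, collapse = "-"),
                           character(1)),
                    vapply(want, paste, character(1), collapse = "-"))
    # sorted by node count, then bottleneck, then label sequence
    lens <- vapply(got, function(p) length(p$labels), integer(1))
    expect_false(is.unsorted(lens))
    # reported steps agree with the distance table
    if (length(got) > 0) {
      p <- got[[1]]
      if (length(p$labels) > 1) {
        steps <- vapply(seq_len(length(p$labels) - 1), function(i)
          pair_dist(case$dmat, p$labels[i], p$labels[i + 1])$edge_distance,
          numeric(1))
        expect_equal(p$step_distances, steps, tolerance = 1e-12)
        expect_equal(p$max_gap, max(steps), tolerance = 1e-12)
      }
    }
  }
})

test_that("trivial path cases behave: self path and disconnected endpoints", {
  cofs <- hyd_cofactors("apo")
  g <- build_et_graph(cofs, tau = 14)
  self <- enumerate_paths(g, "A2", "A2")
  expect_length(self, 1)
  expect_equal(self[[1]]$labels, "A2")
  expect_equal(self[[1]]$max_gap, 0)
  # B3/B4 are a separate component in the apo state at 14
  expect_length(enumerate_paths(g, "B3", "NiFe"), 0)
})

test_that("minimax paths equal the exhaustive-enumeration oracle", {
  set.seed(23)
  for (k in 1:10) {
    n <- sample(4:7, 1)
    cofs <- random_cofactors(n, atoms_each = 3, spread = 15)
    dmat <- distance_matrix(cofs)
    labs <- vapply(cofs, `[[`, character(1), "label")
    ends <- sample(labs, 2)
    got <- minimax_path(cofs, ends[1], ends[2])
    orc <- oracle_minimax(dmat, ends[1], ends[2])
    expect_equal(got$max_gap, orc$value, tolerance = 1e-9)
    # fewest nodes among optimal paths
    opt_lens <- lengths(orc$paths[orc$vals <= orc$value + 1e-9])
    expect_equal(length(got$labels), min(opt_lens))
  }
  # two nodes: the direct pair distance
  two <- random_cofactors(2)
  direct <- minimax_path(two, "N01", "N02")
  expect_equal(direct$max_gap,
               edge_distance(two[[1]], two[[2]])$distance)
  expect_equal(minimax_path(two, "N01", "N01")$max_gap, 0)
})

test_that("graphs and paths are invariant under a common rigid motion", {
  set.seed(24)
  s <- hyd_fixture("PB")
  m <- random_rigid_motion()
  s2 <- transform_structure(s, m$R, m$t)
  lm <- hydabcsl_label_map()
  g1 <- build_et_graph(detect_cofactors(s, label_map = lm), tau = 14)
  g2 <- build_et_graph(detect_cofactors(s2, label_map = lm), tau = 14)
  e1 <- apply(igraph::as_edgelist(g1$graph), 1,
              function(r) paste(sort(r), collapse = "-"))
  e2 <- apply(igraph::as_edgelist(g2$graph), 1,
              function(r) paste(sort(r), collapse = "-"))
  expect_setequal(e1, e2)
  p1 <- minimax_path(g1, "C1", "B3")
  p2 <- minimax_path(g2, "C1", "B3")
  expect_equal(p1$labels, p2$labels)
  expect_equal(p1$max_gap, p2$max_gap, tolerance = 1e-9)
})

test_that("the flavin-to-catalytic-site chain is unique and excludes the dead arms", {
  cofs <- hyd_cofactors("PB")
  labs <- vapply(cofs, `[[`, character(1), "label")
  g <- build_et_graph(cofs, tau = 14, terminals = hydabcsl_terminals(labs))
  ps <- enumerate_paths(g, "FMN", "NiFe")
  expect_length(ps, 1)
  expect_equal(ps[[1]]$labels,
               c("FMN", "B1", "A1", "A2", "A3", "S1", "NiFe"))
  expect_equal(ps[[1]]$n_intermediate_fes, 5L)
  expect_false(any(c("A4", "A5", "B5") %in% ps[[1]]$labels))
  tp <- topology(g)
  expect_true(all(c("A2", "C1") %in% tp$branch_points))
  expect_true(all(c("A5", "B5") %in% tp$dead_ends))
})
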