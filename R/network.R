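#' Build a threshold electron-transfer graph
#'
#' Cofactors are nodes; an undirected edge joins two cofactors whenever
#' their edge-to-edge distance is at or below the threshold `tau`
#' (default 14 Angstrom, the practical electron-tunneling limit).
#' Edges carry both distance metrics. A terminal set marks designated
#' entry/exit points (catalytic site, substrate-binding cofactors) used by
#' the topology classification.
#'
#' @param cofactors list of `Cofactor` objects.
#' @param tau edge-distance threshold in Angstrom (> 0; default 14).
#' @param terminals character vector of terminal labels.
#' @param dmat optional precomputed [distance_matrix()] table.
#' @return object of class `ETGraph`: fields `graph` (igraph), `dmat`
#'   (distance table), `tau`, `terminals`, `labels`, `types`.
#' @export
build_et_graph <- function(cofactors, tau = 14, terminals = character(),
                           dmat = NULL) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("parameter error: tau must be a positive number")
  labs <- vapply(cofactors, `[[`, character(1), "label")
  types <- vapply(cofactors, `[[`, character(1), "type")
  names(types) <- labs
  unknown <- setdiff(terminals, labs)
  if (length(unknown) > 0)
    stop("unknown terminal label(s): ", paste(unknown, collapse = ", "))
  if (is.null(dmat) && length(cofactors) >= 2)
    dmat <- distance_matrix(cofactors)
  g <- igraph::make_empty_graph(n = length(labs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labs)
  g <- igraph::set_vertex_attr(g, "type_code", value = unname(types))
  if (!is.null(dmat)) {
    keep <- dmat[dmat$edge_distance <= tau, , drop = FALSE]
    if (nrow(keep) > 0) {
      g <- igraph::add_edges(g, rbind(keep$label_a, keep$label_b))
      g <- igraph::set_edge_attr(g, "edge_distance", value = keep$edge_distance)
      g <- igraph::set_edge_attr(g, "center_distance", value = keep$center_distance)
      g <- igraph::set_edge_attr(g, "weight", value = keep$edge_distance)
    }
  }
  out <- list(graph = g, dmat = dmat, tau = tau,
              terminals = terminals, labels = labs, types = types)
  class(out) <- "ETGraph"
  out
}

#' @export
print.ETGraph <- function(x, ...) {
  cat(sprintf("ETGraph: %d cofactors, %d edges at tau = %g Angstrom; terminals: %s\n",
              length(x$labels), igraph::ecount(x$graph), x$tau,
              if (length(x$terminals)) paste(x$terminals, collapse = " ") else "(none)"))
  invisible(x)
}

#' Classify the topology of an electron-transfer graph
#'
#' Branch points are nodes of degree >= 3 (the "Y"-shape centers); dead
#' ends are degree-1 nodes not designated as terminals (leaves interpreted
#' as nonfunctional for transfer); components partition the node set.
#'
#' @param g an `ETGraph`.
#' @return list of class `TopologyReport`: `branch_points`, `dead_ends`,
#'   `degrees` (named), `components` (list of label vectors).
#' @export
topology <- function(g) {
  stopifnot(inherits(g, "ETGraph"))
  deg <- igraph::degree(g$graph)
  comp <- igraph::components(g$graph)
  comps <- split(names(comp$membership), comp$membership)
  names(comps) <- NULL
  out <- list(
    branch_points = sort(names(deg)[deg >= 3]),
    dead_ends = sort(setdiff(names(deg)[deg == 1], g$terminals)),
    degrees = deg,
    components = comps)
  class(out) <- "TopologyReport"
  out
}

#' @export
print.TopologyReport <- function(x, ...) {
  cat("Topology:",
      "\n  branch points:", if (length(x$branch_points)) paste(x$branch_points, collapse = " ") else "(none)",
      "\n  dead ends:    ", if (length(x$dead_ends)) paste(x$dead_ends, collapse = " ") else "(none)",
      "\n  components:   ", length(x$components), "\n")
  invisible(x)
}

path_report <- function(labels, steps, types = NULL) {
  n_fes <- if (is.null(types) || length(labels) <= 2) 0L else
    sum(types[labels[-c(1, length(labels))]] %in% c("FES4", "FES2", "FES3"))
  out <- list(labels = labels,
              step_distances = steps,
              max_gap = if (length(steps)) max(steps) else 0,
              n_intermediate_fes = as.integer(n_fes))
  class(out) <- "PathReport"
  out
}

#' @export
print.PathReport <- function(x, ...) {
  cat(sprintf("Path: %s | max gap %.1f Angstrom, %d intermediate FeS\n",
              paste(x$labels, collapse = " - "), x$max_gap,
              x$n_intermediate_fes))
  invisible(x)
}

edge_lookup <- function(dmat) {
  lk <- c(dmat$edge_distance, dmat$edge_distance)
  names(lk) <- c(paste(dmat$label_a, dmat$label_b, sep = "\r"),
                 paste(dmat$label_b, dmat$label_a, sep = "\r"))
  lk
}

steps_for <- function(labels, lk) {
  if (length(labels) < 2) return(numeric())
  unname(lk[paste(labels[-length(labels)], labels[-1], sep = "\r")])
}

#' Enumerate simple paths between two cofactors
#'
#' All simple paths from `src` to `dst` with at most `max_nodes` nodes,
#' sorted by (node count, max gap, lexicographic label sequence). A
#' disconnected pair yields an empty list; `src == dst` yields one
#' zero-length path.
#'
#' Terminal nodes are entry/exit points of the transfer network (the
#' catalytic site, substrate-binding cofactors): by default a path may
#' start or end at a terminal but not relay through one, so e.g. a
#' flavin-to-catalytic-site path cannot detour through the stacked
#' nicotinamide substrate.
#'
#' @param g an `ETGraph`.
#' @param src,dst cofactor labels.
#' @param max_nodes maximum number of nodes on a path (default unlimited).
#' @param exclude_terminals drop terminal nodes other than `src`/`dst`
#'   from the search (default `TRUE`).
#' @return list of `PathReport` objects.
#' @export
enumerate_paths <- function(g, src, dst, max_nodes = Inf,
                            exclude_terminals = TRUE) {
  stopifnot(inherits(g, "ETGraph"))
  if (!(src %in% g$labels) || !(dst %in% g$labels))
    stop("unknown path endpoint: ", paste(setdiff(c(src, dst), g$labels),
                                          collapse = ", "))
  if (src == dst) return(list(path_report(src, numeric(), g$types)))
  gr <- g$graph
  if (exclude_terminals) {
    drop <- setdiff(g$terminals, c(src, dst))
    if (length(drop) > 0) gr <- igraph::delete_vertices(gr, drop)
  }
  cutoff <- if (is.finite(max_nodes)) max_nodes - 1L else -1L
  ps <- igraph::all_simple_paths(gr, from = src, to = dst,
                                 cutoff = cutoff)
  if (length(ps) == 0) return(list())
  lk <- edge_lookup(g$dmat)
  reports <- lapply(ps, function(p) {
    labels <- igraph::as_ids(p)
    path_report(labels, steps_for(labels, lk), g$types)
  })
  seqs <- vapply(reports, function(r) paste(r$labels, collapse = "\r"), character(1))
  ord <- order(vapply(reports, function(r) length(r$labels), integer(1)),
               vapply(reports, `[[`, numeric(1), "max_gap"),
               seqs)
  reports[ord]
}

#' Minimax (bottleneck) path between two cofactors
#'
#' Over the complete distance graph (no threshold), finds the path from
#' `src` to `dst` minimizing the maximum step edge-to-edge distance. This
#' supports reasoning about gaps slightly outside the tunneling range
#' without committing to a hard cutoff. Ties are broken by fewer nodes,
#' then lexicographic label sequence.
#'
#' @param cofactors list of `Cofactor` objects (or an `ETGraph` whose
#'   distance table covers all pairs).
#' @param src,dst cofactor labels.
#' @param dmat optional precomputed [distance_matrix()].
#' @param exclude labels barred from the interior of the path (for an
#'   `ETGraph` input this defaults to its terminals other than
#'   `src`/`dst`, as in [enumerate_paths()]).
#' @return a `PathReport`.
#' @export
minimax_path <- function(cofactors, src, dst, dmat = NULL, exclude = NULL) {
  if (inherits(cofactors, "ETGraph")) {
    labs <- cofactors$labels; types <- cofactors$types
    if (is.null(dmat)) dmat <- cofactors$dmat
    if (is.null(exclude)) exclude <- cofactors$terminals
  } else {
    labs <- vapply(cofactors, `[[`, character(1), "label")
    types <- vapply(cofactors, `[[`, character(1), "type")
    names(types) <- labs
    if (is.null(dmat) && length(cofactors) >= 2)
      dmat <- distance_matrix(cofactors)
  }
  if (!(src %in% labs) || !(dst %in% labs))
    stop("unknown path endpoint: ", paste(setdiff(c(src, dst), labs),
                                          collapse = ", "))
  if (src == dst) return(path_report(src, numeric(), types))
  drop <- setdiff(exclude, c(src, dst))
  if (length(drop) > 0) {
    labs <- setdiff(labs, drop)
    dmat <- dmat[!(dmat$label_a %in% drop | dmat$label_b %in% drop), ,
                 drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    dmat[, c("label_a", "label_b")], directed = FALSE,
    vertices = data.frame(name = labs))
  igraph::E(g)$weight <- dmat$edge_distance
  # bottleneck value: the largest edge on the src-dst path of a minimum
  # spanning tree is the minimax value
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  sp <- igraph::shortest_paths(mst, from = src, to = dst, weights = NA)
  tree_path <- igraph::as_ids(sp$vpath[[1]])
  lk <- edge_lookup(dmat)
  bottleneck <- max(steps_for(tree_path, lk))
  # among all paths with max step <= bottleneck, prefer fewest nodes then
  # lexicographic sequence: BFS over the bottleneck-feasible subgraph
  keep <- dmat[dmat$edge_distance <= bottleneck + 1e-12, , drop = FALSE]
  sub <- igraph::graph_from_data_frame(
    keep[, c("label_a", "label_b")], directed = FALSE,
    vertices = data.frame(name = labs))
  asp <- igraph::all_shortest_paths(sub, from = src, to = dst, weights = NA)
  vp <- if (!is.null(asp$vpaths)) asp$vpaths else asp$res
  cands <- lapply(vp, igraph::as_ids)
  seqs <- vapply(cands, paste, character(1), collapse = "\r")
  best <- cands[[order(seqs)[1]]]
  path_report(best, steps_for(best, lk), types)
}
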