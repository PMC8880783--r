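#' @title Analysis pipeline and report assembly
#'
#' @description `run_pipeline()` ties the stages together the way the
#' package's analysis scripts use them: read or accept structures, detect
#' cofactors, tabulate both distance metrics, build the threshold graph,
#' classify its topology, enumerate paths between terminals, and (with two
#' inputs) compare states. Artifacts are written as TSV/JSON, graphs also
#' as GraphML/DOT, plus a plain-text summary and a provenance block.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param inputs one or two [Structure] objects or file paths (two inputs
#'   trigger the state comparison).
#' @param tau electron-transfer threshold, Angstrom (default 14).
#' @param nife_pair_cutoff Ni-Fe pairing cutoff, Angstrom (default 3.5).
#' @param coordination_cutoff donor shell cutoff, Angstrom (default 3.0).
#' @param label_map named vector `"chain:resnum" -> label` (default the
#'   packaged fixture map, see [hydabcsl_label_map()], applied only where
#'   keys match).
#' @param terminals terminal labels; labels absent from a model are
#'   dropped.
#' @param pairs label pairs for the state comparison (see
#'   [compare_states()]); default all shared pairs.
#' @param state_names names for the compared states.
#' @param model model index (default 1).
#' @param out_dir output directory (`NULL` = no files written).
#' @param formats subset of `c("tsv", "json", "graphml", "dot", "txt")`.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(inputs, tau = 14, nife_pair_cutoff = 3.5,
                       coordination_cutoff = 3.0, label_map = NULL,
                       terminals = character(), pairs = NULL,
                       state_names = c("A", "B"), model = 1L,
                       out_dir = NULL,
                       formats = c("tsv", "json", "graphml", "dot", "txt")) {
  if (inherits(inputs, "Structure")) inputs <- list(inputs)
  if (is.character(inputs)) inputs <- as.list(inputs)
  stopifnot(length(inputs) >= 1, length(inputs) <= 2)
  stopifnot(tau > 0, nife_pair_cutoff > 0, coordination_cutoff > 0)
  bad <- setdiff(formats, c("tsv", "json", "graphml", "dot", "txt"))
  if (length(bad) > 0) stop("unknown output format(s): ",
                            paste(bad, collapse = ", "))
  out <- list(inputs = inputs, tau = tau,
              nife_pair_cutoff = nife_pair_cutoff,
              coordination_cutoff = coordination_cutoff,
              label_map = label_map, terminals = terminals, pairs = pairs,
              state_names = state_names, model = model,
              out_dir = out_dir, formats = formats)
  class(out) <- "RunConfig"
  out
}

load_input <- function(x) {
  if (inherits(x, "Structure")) return(x)
  read_structure(x)
}

#' Run the full cofactor-network pipeline
#'
#' @param cfg a [run_config()].
#' @return list of class `AnalysisReport`: `inventory`, `cofactors`,
#'   `distances`, `graph` (an `ETGraph`), `topology`, `paths` (per
#'   terminal pair), `comparison` (or `NULL`), `warnings`, `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  warns <- character()
  structures <- lapply(cfg$inputs, load_input)
  lmap <- if (is.null(cfg$label_map)) hydabcsl_label_map() else cfg$label_map
  det <- lapply(structures, function(s)
    withCallingHandlers(
      detect_cofactors(s, nife_pair_cutoff = cfg$nife_pair_cutoff,
                       label_map = lmap, model = cfg$model),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
  cofs <- det[[1]]
  inv <- stoichiometry(cofs)
  labs <- vapply(cofs, `[[`, character(1), "label")
  terms <- intersect(cfg$terminals, labs)
  dmat <- if (length(cofs) >= 2) distance_matrix(cofs) else NULL
  g <- if (length(cofs) >= 1)
    build_et_graph(cofs, tau = cfg$tau, terminals = terms, dmat = dmat)
  else NULL
  topo <- if (!is.null(g)) topology(g) else NULL
  if (length(cofs) == 0)
    warns <- c(warns, "no cofactors detected; empty inventory and graph")
  paths <- list()
  if (!is.null(g) && length(terms) >= 2) {
    tp <- t(utils::combn(terms, 2))
    for (r in seq_len(nrow(tp))) {
      key <- paste(tp[r, 1], tp[r, 2], sep = "-")
      paths[[key]] <- enumerate_paths(g, tp[r, 1], tp[r, 2])
    }
  }
  comparison <- NULL
  if (length(det) == 2) {
    comparison <- compare_states(det[[1]], det[[2]], pairs = cfg$pairs,
                                 tau = cfg$tau, states = cfg$state_names)
  }
  prov <- list(
    package_version = as.character(utils::packageVersion("cofanet")),
    tau = cfg$tau, nife_pair_cutoff = cfg$nife_pair_cutoff,
    coordination_cutoff = cfg$coordination_cutoff,
    model = cfg$model, terminals = terms,
    input_checksums = vapply(cfg$inputs, function(x)
      if (is.character(x)) unname(tools::md5sum(x)) else NA_character_,
      character(1)))
  report <- list(inventory = inv, cofactors = cofs, distances = dmat,
                 graph = g, topology = topo, paths = paths,
                 comparison = comparison, warnings = warns,
                 provenance = prov)
  class(report) <- "AnalysisReport"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir, cfg$formats)
  report
}

#' @export
print.AnalysisReport <- function(x, ...) {
  print(x$inventory)
  if (!is.null(x$graph)) print(x$graph)
  if (!is.null(x$topology)) print(x$topology)
  for (k in names(x$paths)) {
    cat(k, ": ", length(x$paths[[k]]), " path(s)\n", sep = "")
    if (length(x$paths[[k]]) > 0) print(x$paths[[k]][[1]])
  }
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

path_to_list <- function(p) {
  list(labels = p$labels, step_distances = p$step_distances,
       max_gap = p$max_gap, n_intermediate_fes = p$n_intermediate_fes)
}

#' Write the artifacts of an analysis report
#'
#' @param report an `AnalysisReport`.
#' @param out_dir directory (created if needed).
#' @param formats see [run_config()].
#' @return invisible vector of written paths.
#' @export
write_report <- function(report, out_dir,
                         formats = c("tsv", "json", "graphml", "dot", "txt")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  w <- function(p) { written <<- c(written, p); p }
  inv <- report$inventory
  if ("tsv" %in% formats) {
    idf <- data.frame(type = names(inv$counts),
                      count = unlist(inv$counts), stringsAsFactors = FALSE)
    utils::write.table(idf, w(file.path(out_dir, "inventory.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$distances))
      utils::write.table(report$distances,
                         w(file.path(out_dir, "distances.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report$comparison))
      utils::write.table(as.data.frame(report$comparison),
                         w(file.path(out_dir, "comparison.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if ("json" %in% formats) {
    payload <- list(
      inventory = list(counts = inv$counts, fe_total = inv$fe_total,
                       ni_total = inv$ni_total,
                       fe_ni_ratio = inv$fe_ni_ratio),
      topology = if (!is.null(report$topology)) list(
        branch_points = report$topology$branch_points,
        dead_ends = report$topology$dead_ends,
        n_components = length(report$topology$components)),
      paths = lapply(report$paths, function(ps) lapply(ps, path_to_list)),
      comparison = if (!is.null(report$comparison))
        as.data.frame(report$comparison),
      warnings = report$warnings,
      provenance = report$provenance)
    jsonlite::write_json(payload, w(file.path(out_dir, "report.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(report$graph)) {
    if ("graphml" %in% formats)
      igraph::write_graph(report$graph$graph,
                          w(file.path(out_dir, "graph.graphml")),
                          format = "graphml")
    if ("dot" %in% formats)
      igraph::write_graph(report$graph$graph,
                          w(file.path(out_dir, "graph.dot")), format = "dot")
  }
  if ("txt" %in% formats) {
    p <- w(file.path(out_dir, "summary.txt"))
    con <- file(p, "w"); on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    print(report)
    cat("\nProvenance:\n")
    utils::str(report$provenance, give.attr = FALSE)
  }
  invisible(written)
}
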