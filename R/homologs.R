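#' Flavin-proximal [4Fe-4S] to accessory [2Fe-2S] gap in a homolog model
#'
#' In the nonbifurcating homologs of the bifurcating hydrogenase (complex I
#' hydrophilic domain, NADH-dependent formate dehydrogenase), the
#' counterpart of the B1-C1 gap is the distance between the [4Fe-4S]
#' cluster adjacent to the flavin and the accessory [2Fe-2S] cluster
#' carried by the small thioredoxin-like subunit. This helper measures
#' that gap on a user-supplied model (entries are not auto-fetched):
#' the flavin-proximal [4Fe-4S] is the `FES4` with the smallest
#' edge-to-edge distance to a flavin; the accessory [2Fe-2S] is the `FES2`
#' that is the sole FeS cluster of its chain (the closest such cluster to
#' the flavin if several chains qualify, e.g. across symmetry copies).
#'
#' @param path structure file (PDB or mmCIF).
#' @param model model index (default 1).
#' @return list: `edge_distance` (Angstrom, full precision), `rounded`
#'   (0.1 Angstrom), `center_distance`, `fes4_label`, `fes2_label`,
#'   and the chain ids involved.
#' @export
homolog_accessory_gap <- function(path, model = 1L) {
  s <- read_structure(path)
  cofs <- detect_cofactors(s, model = model)
  types <- vapply(cofs, `[[`, character(1), "type")
  flavins <- cofs[types %in% c("FMN", "FAD")]
  fes4 <- cofs[types == "FES4"]
  fes2 <- cofs[types == "FES2"]
  if (length(flavins) == 0 || length(fes4) == 0 || length(fes2) == 0)
    stop("model lacks a flavin, a [4Fe-4S] or a [2Fe-2S] cluster")
  d_to_flavin <- function(cf)
    min(vapply(flavins, function(fl) edge_distance(cf, fl)$distance,
               numeric(1)))
  prox <- fes4[[which.min(vapply(fes4, d_to_flavin, numeric(1)))]]
  # chains holding exactly one FeS cluster
  fes_chains <- vapply(cofs[types %in% c("FES4", "FES2", "FES3")],
                       function(cf) cf$atoms$chain_id[1], character(1))
  counts <- table(fes_chains)
  sole <- fes2[vapply(fes2, function(cf)
    counts[[cf$atoms$chain_id[1]]] == 1L, logical(1))]
  if (length(sole) == 0) sole <- fes2
  acc <- sole[[which.min(vapply(sole, d_to_flavin, numeric(1)))]]
  ed <- edge_distance(prox, acc)
  list(edge_distance = ed$distance,
       rounded = round(ed$distance, 1),
       center_distance = center_distance(prox, acc),
       fes4_label = prox$label, fes2_label = acc$label,
       fes4_chain = prox$atoms$chain_id[1],
       fes2_chain = acc$atoms$chain_id[1])
}
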