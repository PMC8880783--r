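#' Cofactor type dictionary
#'
#' Maps chemical-component codes found in structure files to redox cofactor
#' types, with per-cofactor Fe and Ni atom counts used for stoichiometry:
#' `SF4` -> `FES4` ([4Fe-4S] cubane), `FES`/`FS2` -> `FES2` ([2Fe-2S]
#' rhombic), `F3S` -> `FES3` ([3Fe-4S]), `FMN` -> `FMN`, `FAD` -> `FAD`,
#' `NAD`/`NAI` -> `NAD`. The bimetallic `NIFE` center is not a single
#' component code: it is assembled by [detect_cofactors()] from a Ni atom
#' and its nearest unassigned Fe atom.
#'
#' @return data frame with columns `code` (component code), `type`,
#'   `fe_count`, `ni_count`.
#' @export
cofactor_dictionary <- function() {
  data.frame(
    code = c("SF4", "FES", "FS2", "F3S", "FMN", "FAD", "NAD", "NAI"),
    type = c("FES4", "FES2", "FES2", "FES3", "FMN", "FAD", "NAD", "NAD"),
    stringsAsFactors = FALSE
  )
}

#' Per-type metal content
#'
#' Fe and Ni atoms contributed by one cofactor of each type. `NIFE`
#' counts one Fe and one Ni (the bridged bimetallic pair).
#' @return data frame with columns `type`, `fe_count`, `ni_count`.
#' @export
cofactor_type_metals <- function() {
  data.frame(
    type = c("FES4", "FES2", "FES3", "FMN", "FAD", "NAD", "NIFE", "CUSTOM"),
    fe_count = c(4L, 2L, 3L, 0L, 0L, 0L, 1L, 0L),
    ni_count = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

# Atom names of the fused tricyclic isoalloxazine system (flavins) and of
# the nicotinamide ring (NAD).  Used as the center set for flavin /
# nicotinamide distance measurements.
isoalloxazine_atom_names <- function() {
  c("N1", "C2", "O2", "N3", "C4", "O4", "C4A", "N5", "C5A",
    "C6", "C7", "C7M", "C8", "C8M", "C9", "C9A", "N10", "C10")
}

nicotinamide_atom_names <- function() {
  c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N",
    "N1", "C2", "C3", "C4", "C5", "C6")
}

ring_names_for_type <- function(type) {
  switch(type,
         FMN = isoalloxazine_atom_names(),
         FAD = isoalloxazine_atom_names(),
         NAD = nicotinamide_atom_names(),
         NULL)
}

new_cofactor <- function(label, type, atoms, metal_atoms, ring_atoms = NULL) {
  center_set <- if (!is.null(ring_atoms) && nrow(ring_atoms) > 0) ring_atoms
                else atoms
  out <- list(
    label = label,
    type = type,
    chain_id = unique(atoms$chain_id),
    residue_numbers = unique(atoms$residue_number),
    atoms = atoms,
    metal_atoms = metal_atoms,
    ring_atoms = ring_atoms,
    center = colMeans(as.matrix(center_set[, c("x", "y", "z")]))
  )
  class(out) <- "Cofactor"
  out
}

#' @export
print.Cofactor <- function(x, ...) {
  cat(sprintf("Cofactor %s [%s] chain %s, %d atoms (%d metal), center (%.2f, %.2f, %.2f)\n",
              x$label, x$type, paste(x$chain_id, collapse = "/"),
              nrow(x$atoms), nrow(x$metal_atoms),
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Detect redox cofactors in a Structure
#'
#' Scans hetero residues against a component-code dictionary and emits one
#' `Cofactor` per match. Nickel atoms are handled separately: each Ni is
#' paired with its nearest Fe atom not already assigned to an FeS cluster;
#' if the pair is within `nife_pair_cutoff` a `NIFE` cofactor is emitted
#' (together with any carbonyl/cyanide component atoms within the cutoff of
#' either metal); an unpaired Ni becomes a `CUSTOM` cofactor with a warning.
#'
#' Labels are deterministic: `<chain><ordinal>` in chain-then-source order,
#' unless `label_map` supplies custom labels keyed `"chain:resnum"` (the
#' NiFe pair is keyed by its Ni atom's residue).
#'
#' @param s a [Structure].
#' @param dictionary component-code dictionary, see [cofactor_dictionary()].
#' @param nife_pair_cutoff maximum Ni-Fe separation (Angstrom) for a
#'   bimetallic NiFe center (default 3.5).
#' @param label_map optional named character vector `"chain:resnum" -> label`.
#' @param model model index (default 1).
#' @param include_hydrogens keep hydrogen atoms as cofactor members
#'   (default `FALSE`).
#' @return list of `Cofactor` objects.
#' @export
detect_cofactors <- function(s, dictionary = cofactor_dictionary(),
                             nife_pair_cutoff = 3.5, label_map = NULL,
                             model = 1L, include_hydrogens = FALSE) {
  stopifnot(inherits(s, "Structure"), nrow(dictionary) > 0)
  if (any(duplicated(dictionary$code))) {
    dup <- unique(dictionary$code[duplicated(dictionary$code)])
    stop("ambiguity error: component code(s) mapped to multiple types: ",
         paste(dup, collapse = ", "))
  }
  a <- s$atoms[s$atoms$model_index == model, , drop = FALSE]
  if (!include_hydrogens) a <- a[!(toupper(a$element) %in% c("H", "D")), , drop = FALSE]
  het <- a[a$is_hetero, , drop = FALSE]
  cofs <- list()
  if (nrow(het) == 0) return(cofs)

  key <- paste(het$chain_id, het$residue_number, het$insertion_code, sep = ":")
  # preserve source order of residues
  ukeys <- key[!duplicated(key)]
  assigned_fe <- logical(nrow(het))   # Fe atoms consumed by FeS clusters
  ni_rows <- list()
  free_atoms <- rep(TRUE, nrow(het))  # available for NiFe assembly

  for (k in ukeys) {
    idx <- which(key == k)
    resname <- toupper(het$residue_name[idx[1]])
    hit <- which(toupper(dictionary$code) == resname)
    if (length(hit) == 1) {
      type <- dictionary$type[hit]
      atoms <- het[idx, , drop = FALSE]
      metals <- atoms[toupper(atoms$element) %in% c("FE", "NI"), , drop = FALSE]
      rn <- ring_names_for_type(type)
      ring <- if (!is.null(rn)) atoms[toupper(atoms$atom_name) %in% rn, , drop = FALSE]
      cofs[[length(cofs) + 1L]] <- list(key = k, type = type, atoms = atoms,
                                        metals = metals, ring = ring)
      free_atoms[idx] <- FALSE
      assigned_fe[idx[toupper(het$element[idx]) == "FE"]] <- TRUE
    } else if (resname %in% c("NI", "3NI")) {
      ni_rows[[length(ni_rows) + 1L]] <- idx
      free_atoms[idx] <- FALSE
    }
    # unmatched residues are ignored (solvent, other ligands)
  }

  # Assemble NiFe centers from Ni atoms + nearest unassigned Fe
  for (idx in ni_rows) {
    ni <- het[idx[1], , drop = FALSE]
    fe_pool <- which(toupper(het$element) == "FE" & !assigned_fe)
    paired <- FALSE
    if (length(fe_pool) > 0) {
      d <- sqrt((het$x[fe_pool] - ni$x)^2 + (het$y[fe_pool] - ni$y)^2 +
                (het$z[fe_pool] - ni$z)^2)
      j <- fe_pool[which.min(d)]
      if (min(d) <= nife_pair_cutoff) {
        fe <- het[j, , drop = FALSE]
        assigned_fe[j] <- TRUE
        # pull in diatomic-ligand component atoms (e.g. FCO carbonyl/cyanide)
        # near either metal that are not part of another cofactor
        extra <- integer()
        cand <- which(free_atoms & seq_len(nrow(het)) != j &
                        seq_len(nrow(het)) != idx[1])
        if (length(cand) > 0) {
          dni <- sqrt((het$x[cand] - ni$x)^2 + (het$y[cand] - ni$y)^2 +
                      (het$z[cand] - ni$z)^2)
          dfe <- sqrt((het$x[cand] - fe$x)^2 + (het$y[cand] - fe$y)^2 +
                      (het$z[cand] - fe$z)^2)
          extra <- cand[pmin(dni, dfe) <= nife_pair_cutoff &
                          toupper(het$residue_name[cand]) %in% c("FCO", "CMO", "CYN")]
        }
        atoms <- het[c(idx[1], j, extra), , drop = FALSE]
        metals <- het[c(idx[1], j), , drop = FALSE]
        cofs[[length(cofs) + 1L]] <- list(
          key = paste(ni$chain_id, ni$residue_number, ni$insertion_code, sep = ":"),
          type = "NIFE", atoms = atoms, metals = metals, ring = NULL)
        paired <- TRUE
      }
    }
    if (!paired) {
      warning("Ni atom at ", ni$chain_id, ":", ni$residue_number,
              " has no unassigned Fe within ", nife_pair_cutoff,
              " Angstrom; reported as CUSTOM", call. = FALSE)
      cofs[[length(cofs) + 1L]] <- list(
        key = paste(ni$chain_id, ni$residue_number, ni$insertion_code, sep = ":"),
        type = "CUSTOM", atoms = ni, metals = ni, ring = NULL)
    }
  }

  # deterministic labels: chain + per-chain ordinal (chain order sorted,
  # residues in source order within a chain)
  chains <- vapply(cofs, function(cf) cf$atoms$chain_id[1], character(1))
  ord <- order(chains, seq_along(cofs))
  cofs <- cofs[ord]
  chains <- chains[ord]
  counter <- list()
  out <- vector("list", length(cofs))
  for (i in seq_along(cofs)) {
    cf <- cofs[[i]]
    ch <- chains[i]
    counter[[ch]] <- (if (is.null(counter[[ch]])) 0L else counter[[ch]]) + 1L
    label <- paste0(ch, counter[[ch]])
    resk <- sub(":$", "", cf$key)
    if (!is.null(label_map) && resk %in% names(label_map))
      label <- unname(label_map[[resk]])
    out[[i]] <- new_cofactor(label, cf$type, cf$atoms, cf$metals, cf$ring)
  }
  labs <- vapply(out, `[[`, character(1), "label")
  if (any(duplicated(labs)))
    stop("labeling error: duplicate cofactor labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  out
}

#' Coordination shell of a cofactor
#'
#' Protein side-chain donor atoms (S, N or O, excluding the backbone N, O,
#' C, CA and OXT atoms) within `cutoff` of any metal atom of the cofactor,
#' each listed once with its minimal metal distance, sorted ascending.
#'
#' @param s a [Structure].
#' @param cofactor a `Cofactor` from [detect_cofactors()].
#' @param cutoff donor-to-metal distance cutoff in Angstrom (default 3.0).
#' @param model model index (default 1).
#' @return data frame with columns `chain_id`, `residue_name`,
#'   `residue_number`, `atom_name`, `distance`; attribute `note` carries an
#'   informational message for metal-free cofactors.
#' @export
coordination_shell <- function(s, cofactor, cutoff = 3.0, model = 1L) {
  stopifnot(inherits(s, "Structure"), inherits(cofactor, "Cofactor"),
            cutoff > 0)
  empty <- data.frame(chain_id = character(), residue_name = character(),
                      residue_number = integer(), atom_name = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  metals <- cofactor$metal_atoms
  if (is.null(metals) || nrow(metals) == 0) {
    attr(empty, "note") <- sprintf(
      "cofactor %s (%s) has no metal atoms; coordination shell not defined",
      cofactor$label, cofactor$type)
    return(empty)
  }
  a <- s$atoms[s$atoms$model_index == model & !s$atoms$is_hetero, , drop = FALSE]
  a <- a[toupper(a$element) %in% c("S", "N", "O"), , drop = FALSE]
  a <- a[!(toupper(a$atom_name) %in% c("N", "O", "C", "CA", "OXT")), , drop = FALSE]
  if (nrow(a) == 0) return(empty)
  mm <- as.matrix(metals[, c("x", "y", "z")])
  pp <- as.matrix(a[, c("x", "y", "z")])
  d2 <- outer(rowSums(pp^2), rowSums(mm^2), "+") - 2 * pp %*% t(mm)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  keep <- dmin <= cutoff
  if (!any(keep)) return(empty)
  out <- data.frame(chain_id = a$chain_id[keep],
                    residue_name = a$residue_name[keep],
                    residue_number = a$residue_number[keep],
                    atom_name = a$atom_name[keep],
                    distance = dmin[keep], stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cofactor inventory and Fe:Ni stoichiometry
#'
#' Computes total Fe and Ni atoms, and their ratio, from counts per
#' cofactor type. For the archetypal bifurcating hydrogenase content of
#' eight [4Fe-4S], four [2Fe-2S] and one NiFe center this yields
#' 8*4 + 4*2 + 1 = 41 Fe and 1 Ni, i.e. an expected Fe:Ni ratio of 41.
#'
#' @param counts named integer vector/list of counts per type code
#'   (`FES4`, `FES2`, `FES3`, `FMN`, `FAD`, `NAD`, `NIFE`, `CUSTOM`), or a
#'   list of `Cofactor` objects to be tallied.
#' @return list of class `Inventory`: `counts`, `fe_total`, `ni_total`,
#'   `fe_ni_ratio` (`NA` when `ni_total` is 0: undefined, not an error).
#' @export
stoichiometry <- function(counts) {
  if (is.list(counts) && length(counts) > 0 &&
      all(vapply(counts, inherits, logical(1), "Cofactor"))) {
    counts <- table(vapply(counts, `[[`, character(1), "type"))
  }
  counts <- unlist(counts)
  if (length(counts) > 0 && (any(counts < 0) || any(counts != round(counts))))
    stop("cofactor counts must be non-negative integers")
  tm <- cofactor_type_metals()
  unknown <- setdiff(names(counts), tm$type)
  if (length(unknown) > 0)
    stop("unknown cofactor type(s): ", paste(unknown, collapse = ", "))
  fe <- 0L; ni <- 0L
  for (ty in names(counts)) {
    row <- tm[tm$type == ty, ]
    fe <- fe + counts[[ty]] * row$fe_count
    ni <- ni + counts[[ty]] * row$ni_count
  }
  out <- list(counts = as.list(counts), fe_total = as.integer(fe),
              ni_total = as.integer(ni),
              fe_ni_ratio = if (ni > 0) fe / ni else NA_real_)
  class(out) <- "Inventory"
  out
}

#' @export
print.Inventory <- function(x, ...) {
  cts <- if (length(x$counts) > 0)
    paste(sprintf("%s=%d", names(x$counts), unlist(x$counts)), collapse = " ")
  else "(none)"
  cat(sprintf("Inventory: %s | Fe %d, Ni %d, Fe:Ni %s\n", cts,
              x$fe_total, x$ni_total,
              if (is.na(x$fe_ni_ratio)) "undefined"
              else format(x$fe_ni_ratio)))
  invisible(x)
}
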