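#' @title Synthetic cofactor-constellation generator
#'
#' @description Fixture structures with controlled cofactor constellations:
#' idealized cofactor templates are placed, at seeded random orientations,
#' so that every constrained pair's edge-to-edge distance hits its target
#' within a tolerance and every unconstrained pair stays beyond a repulsion
#' floor. The placement solver is an iterative stress scheme on rigid
#' template positions: a first stage relaxes centers with reach-corrected
#' spring targets; a second stage re-measures true edge-to-edge distances
#' (which depend on template orientation) and moves the two bodies of each
#' violated constraint along their center line by a damped half-error, with
#' a soft push between too-close unconstrained pairs. Unlucky orientation
#' draws are retried with fresh seeded orientations; persistent failure
#' raises an infeasibility error listing the constraints.
#'
#' @name synthetic-constellations
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

empty_atom_table <- function() {
  data.frame(element = character(), atom_name = character(),
             residue_name = character(), residue_number = integer(),
             chain_id = character(), x = numeric(), y = numeric(),
             z = numeric(), is_hetero = logical(), stringsAsFactors = FALSE)
}

#' Placement specification for a synthetic constellation
#'
#' @param entries data frame with columns `label`, `type` (see
#'   [cofactor_template()]) and optionally `chain_id`, `residue_number`,
#'   `group` (entries sharing a group are placed as one rigid unit; an
#'   optional list column `offset` gives each entry's displacement within
#'   its group frame).
#' @param constraints data frame with columns `a`, `b` (labels) and
#'   `target` (edge-to-edge distance, Angstrom); optional column `tol`.
#' @param repulsion_floor minimum edge distance for all unconstrained
#'   pairs (default 15, above the default 14 transfer threshold).
#' @param tol default constraint tolerance in Angstrom (default 0.05).
#' @param seed integer seed.
#' @param exempt optional data frame (`a`, `b`) of label pairs excluded
#'   from the repulsion floor (e.g. a ligand that deliberately sits close
#'   to a rigid partner group).
#' @return list of class `PlacementSpec`.
#' @export
placement_spec <- function(entries, constraints = NULL,
                           repulsion_floor = 15, tol = 0.05, seed = 1L,
                           exempt = NULL) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) > 0)
    stopifnot(all(c("label", "type") %in% names(entries)))
  stopifnot(tol > 0)
  if (any(duplicated(entries$label)))
    stop("duplicate entry labels in placement spec")
  n <- nrow(entries)
  if (is.null(entries$chain_id)) entries$chain_id <- rep("X", n)
  if (is.null(entries$residue_number))
    entries$residue_number <- 900L + 10L * seq_len(n)  # spaced: a NIFE
  # entry expands into two consecutive residue numbers
  if (is.null(entries$group)) entries$group <- entries$label
  if (!is.null(constraints) && NROW(constraints) > 0) {
    constraints <- as.data.frame(constraints, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b", "target") %in% names(constraints)))
    if (is.null(constraints$tol)) constraints$tol <- tol
    bad <- setdiff(unique(c(constraints$a, constraints$b)), entries$label)
    if (length(bad) > 0)
      stop("constraint references unknown label(s): ",
           paste(bad, collapse = ", "))
  } else {
    constraints <- data.frame(a = character(), b = character(),
                              target = numeric(), tol = numeric())
  }
  if (!is.null(exempt)) {
    exempt <- as.data.frame(exempt, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b") %in% names(exempt)))
  }
  out <- list(entries = entries, constraints = constraints,
              repulsion_floor = repulsion_floor, tol = tol,
              seed = as.integer(seed), exempt = exempt)
  class(out) <- "PlacementSpec"
  out
}

# min edge distance between two placed atom sets
.min_pair_dist <- function(pa, pb) {
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  sqrt(max(0, min(d2)))
}

#' Realize a placement specification as a Structure
#'
#' Deterministic given `(spec, seed)`: the same spec always yields the
#' same coordinates. Raises an infeasibility error listing the constraint
#' set if the solver cannot satisfy the spec.
#'
#' @param spec a [placement_spec()].
#' @param max_iter refinement iterations per restart (default 800).
#' @param restarts orientation re-draws before giving up (default 12).
#' @return a [Structure] whose hetero residues realize the constellation.
#' @export
make_constellation <- function(spec, max_iter = 800L, restarts = 12L) {
  stopifnot(inherits(spec, "PlacementSpec"))
  ent <- spec$entries
  n <- nrow(ent)
  if (n == 0)
    return(structure_from_atoms(empty_atom_table(),
                                metadata = list(title = "empty")))
  con <- spec$constraints
  nc <- nrow(con)
  ci <- match(con$a, ent$label); cj <- match(con$b, ent$label)
  if (nc > 0 && any(ent$group[ci] == ent$group[cj]))
    stop("constraint within one rigid group is not solvable")
  groups <- unique(ent$group)
  gidx <- match(ent$group, groups)
  templates <- lapply(ent$type, cofactor_template)
  offsets <- if (!is.null(ent$offset)) ent$offset else
    rep(list(c(0, 0, 0)), n)
  # unconstrained cross-group pair list
  upairs <- NULL
  if (n >= 2) {
    upairs <- t(utils::combn(n, 2))
    drop <- gidx[upairs[, 1]] == gidx[upairs[, 2]]
    if (nc > 0) {
      ck <- paste(pmin(ci, cj), pmax(ci, cj))
      drop <- drop | paste(upairs[, 1], upairs[, 2]) %in% ck
    }
    if (!is.null(spec$exempt) && nrow(spec$exempt) > 0) {
      ei <- match(spec$exempt$a, ent$label)
      ej <- match(spec$exempt$b, ent$label)
      ek <- paste(pmin(ei, ej), pmax(ei, ej))
      drop <- drop | paste(upairs[, 1], upairs[, 2]) %in% ek
    }
    upairs <- upairs[!drop, , drop = FALSE]
  }

  result <- with_seed(spec$seed, {
    res <- NULL
    for (attempt in seq_len(restarts)) {
      rots <- lapply(seq_along(groups), function(i) random_rotation())
      # atom coords of entry k relative to its group position
      rel <- vector("list", n)
      for (k in seq_len(n)) {
        xyz <- as.matrix(templates[[k]][, c("x", "y", "z")])
        xyz <- sweep(xyz, 2, colMeans(xyz))
        xyz <- sweep(xyz, 2, as.numeric(offsets[[k]]), "+")
        rel[[k]] <- xyz %*% t(rots[[gidx[k]]])
      }
      relc <- t(vapply(rel, colMeans, numeric(3)))  # entity center offsets
      reach <- vapply(seq_len(n), function(k)
        max(sqrt(rowSums(sweep(rel[[k]], 2, relc[k, ])^2))), numeric(1))
      span <- max(c(spec$repulsion_floor, con$target, 10)) * 1.2
      gpos <- matrix(stats::runif(3 * length(groups), -span, span), ncol = 3)
      centers <- function() gpos[gidx, , drop = FALSE] + relc

      # stage 1: springs on centers with reach-corrected provisional targets
      for (it in seq_len(250L)) {
        p <- centers()
        for (c_ in seq_len(nc)) {
          i <- ci[c_]; j <- cj[c_]
          v <- p[j, ] - p[i, ]
          d <- sqrt(sum(v^2))
          if (d < 1e-6) { v <- stats::rnorm(3); d <- sqrt(sum(v^2)) }
          err <- d - (con$target[c_] + 0.6 * (reach[i] + reach[j]))
          u <- v / d
          gpos[gidx[i], ] <- gpos[gidx[i], ] + 0.4 * err * u
          gpos[gidx[j], ] <- gpos[gidx[j], ] - 0.4 * err * u
          p <- centers()
        }
        if (!is.null(upairs)) for (r in seq_len(nrow(upairs))) {
          i <- upairs[r, 1]; j <- upairs[r, 2]
          v <- p[j, ] - p[i, ]
          d <- sqrt(sum(v^2))
          if (d < 1e-6) { v <- stats::rnorm(3); d <- 1e-6 }
          lim <- spec$repulsion_floor + reach[i] + reach[j]
          if (d < lim) {
            u <- v / d
            gpos[gidx[i], ] <- gpos[gidx[i], ] - 0.4 * (lim - d) * u
            gpos[gidx[j], ] <- gpos[gidx[j], ] + 0.4 * (lim - d) * u
            p <- centers()
          }
        }
      }

      # stage 2: refine against true edge-to-edge distances
      atoms_at <- function() {
        lapply(seq_len(n), function(k)
          sweep(rel[[k]], 2, gpos[gidx[k], ], "+"))
      }
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        at <- atoms_at()
        worst <- 0
        for (c_ in seq_len(nc)) {
          i <- ci[c_]; j <- cj[c_]
          e <- .min_pair_dist(at[[i]], at[[j]])
          err <- e - con$target[c_]
          worst <- max(worst, abs(err) / max(con$tol[c_], 1e-9))
          if (abs(err) > 0.25 * con$tol[c_]) {
            p <- centers()
            u <- p[j, ] - p[i, ]
            du <- sqrt(sum(u^2))
            if (du < 1e-6) { u <- stats::rnorm(3); du <- sqrt(sum(u^2)) }
            u <- u / du
            step <- 0.45 * err
            gpos[gidx[i], ] <- gpos[gidx[i], ] + step * u
            gpos[gidx[j], ] <- gpos[gidx[j], ] - step * u
            at <- atoms_at()
          }
        }
        viol_rep <- FALSE
        if (!is.null(upairs)) for (r in seq_len(nrow(upairs))) {
          i <- upairs[r, 1]; j <- upairs[r, 2]
          e <- .min_pair_dist(at[[i]], at[[j]])
          if (e < spec$repulsion_floor) {
            viol_rep <- TRUE
            p <- centers()
            u <- p[j, ] - p[i, ]
            du <- sqrt(sum(u^2))
            if (du < 1e-6) { u <- stats::rnorm(3); du <- 1e-6 }
            u <- u / du
            push <- 0.45 * (spec$repulsion_floor - e + 0.2)
            gpos[gidx[i], ] <- gpos[gidx[i], ] - push * u
            gpos[gidx[j], ] <- gpos[gidx[j], ] + push * u
            at <- atoms_at()
          }
        }
        if (worst <= 0.9 && !viol_rep) { ok <- TRUE; break }
      }
      if (ok) {
        at <- atoms_at()
        rows <- vector("list", n)
        for (k in seq_len(n)) {
          tp <- templates[[k]]
          rows[[k]] <- data.frame(
            element = tp$element, atom_name = tp$atom_name,
            residue_name = tp$residue_name,
            residue_number = ent$residue_number[k] + tp$residue_number - 1L,
            chain_id = ent$chain_id[k],
            x = at[[k]][, 1], y = at[[k]][, 2], z = at[[k]][, 3],
            is_hetero = TRUE, stringsAsFactors = FALSE)
        }
        res <- structure_from_atoms(do.call(rbind, rows),
                                    metadata = list(seed = spec$seed))
        break
      }
    }
    res
  })
  if (is.null(result))
    stop("infeasibility error: placement solver failed after ", restarts,
         " restarts; constraints: ",
         paste(sprintf("%s-%s=%.2f", con$a, con$b, con$target),
               collapse = ", "))
  result
}
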