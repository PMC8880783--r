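#' Inter-cofactor distance metrics
#'
#' Two metrics are used throughout: the center-to-center distance (between
#' geometric centers; flavin and nicotinamide centers are the ring systems)
#' and the edge-to-edge ("side-to-side") distance, the minimum non-hydrogen
#' inter-atom distance between the two cofactors. The edge metric is the
#' operative one for electron-tunneling feasibility (~14 Angstrom practical
#' limit); the center metric is the conventional companion figure.
#'
#' @param a,b `Cofactor` objects.
#' @param include_hydrogens include H/D atoms in the edge metric
#'   (default `FALSE`).
#' @return `center_distance()`: numeric Angstrom. `edge_distance()`: list
#'   with `distance` (Angstrom), `atom_a`, `atom_b` (names of the closest
#'   atom pair, ties broken by source atom order).
#' @name cofactor-distances
NULL

cof_xyz <- function(cof, include_hydrogens = FALSE) {
  a <- cof$atoms
  if (!include_hydrogens)
    a <- a[!(toupper(a$element) %in% c("H", "D")), , drop = FALSE]
  if (nrow(a) == 0)
    stop("degenerate-cofactor error: ", cof$label, " has no usable atoms")
  a
}

#' @rdname cofactor-distances
#' @export
center_distance <- function(a, b) {
  stopifnot(inherits(a, "Cofactor"), inherits(b, "Cofactor"))
  if (length(a$center) != 3 || length(b$center) != 3 ||
      !all(is.finite(a$center)) || !all(is.finite(b$center)))
    stop("degenerate-cofactor error: undefined center")
  sqrt(sum((a$center - b$center)^2))
}

#' @rdname cofactor-distances
#' @export
edge_distance <- function(a, b, include_hydrogens = FALSE) {
  aa <- cof_xyz(a, include_hydrogens)
  bb <- cof_xyz(b, include_hydrogens)
  pa <- as.matrix(aa[, c("x", "y", "z")])
  pb <- as.matrix(bb[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2 <- pmax(d2, 0)
  k <- arrayInd(which.min(d2), dim(d2))   # which.min: first = source order
  list(distance = sqrt(d2[k[1], k[2]]),
       atom_a = aa$atom_name[k[1]],
       atom_b = bb$atom_name[k[2]])
}

#' All-pairs cofactor distance table
#'
#' Both metrics for every unordered cofactor pair (n cofactors yield
#' n(n-1)/2 rows).
#'
#' @param cofactors list of `Cofactor` objects with unique labels.
#' @param include_hydrogens include H/D atoms in the edge metric.
#' @return data frame with columns `label_a`, `label_b`, `center_distance`,
#'   `edge_distance`, `atom_a`, `atom_b`.
#' @export
distance_matrix <- function(cofactors, include_hydrogens = FALSE) {
  stopifnot(length(cofactors) >= 2)
  labs <- vapply(cofactors, `[[`, character(1), "label")
  if (any(duplicated(labs)))
    stop("labeling error: duplicate cofactor labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  n <- length(cofactors)
  rows <- vector("list", n * (n - 1) / 2)
  r <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ed <- edge_distance(cofactors[[i]], cofactors[[j]], include_hydrogens)
      r <- r + 1L
      rows[[r]] <- data.frame(
        label_a = labs[i], label_b = labs[j],
        center_distance = center_distance(cofactors[[i]], cofactors[[j]]),
        edge_distance = ed$distance, atom_a = ed$atom_a, atom_b = ed$atom_b,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
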