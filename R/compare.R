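#' Compare cofactor-pair distances between two conformational states
#'
#' For each requested label pair, reports the edge-to-edge distance in both
#' states, the delta (state B minus state A), and whether the pair crosses
#' the electron-transfer threshold `tau` between the states (within range
#' in exactly one of the two). This is the distance-gating summary used to
#' contrast, e.g., a bifurcation-ready and a post-bifurcation conformation.
#'
#' @param cofA,cofB lists of `Cofactor` objects for states A and B.
#' @param pairs label pairs: a 2-column matrix/data frame, or a character
#'   vector of `"LABEL1:LABEL2"` strings; default all pairs shared by both
#'   states.
#' @param tau threshold in Angstrom (default 14).
#' @param states length-2 character vector naming the states (e.g.
#'   `c("apo", "PB")`).
#' @return data frame of class `StateComparison` with columns `label_a`,
#'   `label_b`, `dist_a`, `dist_b`, `delta`, `within_a`, `within_b`,
#'   `crossed_threshold`; attributes `states` and `tau`.
#' @export
compare_states <- function(cofA, cofB, pairs = NULL, tau = 14,
                           states = c("A", "B")) {
  labsA <- vapply(cofA, `[[`, character(1), "label")
  labsB <- vapply(cofB, `[[`, character(1), "label")
  if (is.null(pairs)) {
    shared <- intersect(labsA, labsB)
    if (length(shared) < 2) stop("fewer than two shared labels between states")
    pairs <- t(utils::combn(shared, 2))
  } else if (is.character(pairs)) {
    parts <- strsplit(pairs, ":", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed pair spec: ", paste(pairs[bad], collapse = ", "))
    pairs <- do.call(rbind, parts)
  } else {
    pairs <- as.matrix(pairs)
  }
  for (st in 1:2) {
    labs <- if (st == 1) labsA else labsB
    missing <- setdiff(unique(as.vector(pairs)), labs)
    if (length(missing) > 0)
      stop("mapping error: label(s) ", paste(missing, collapse = ", "),
           " absent from state ", states[st])
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    la <- pairs[i, 1]; lb <- pairs[i, 2]
    da <- edge_distance(cofA[[match(la, labsA)]], cofA[[match(lb, labsA)]])$distance
    db <- edge_distance(cofB[[match(la, labsB)]], cofB[[match(lb, labsB)]])$distance
    rows[[i]] <- data.frame(label_a = la, label_b = lb,
                            dist_a = da, dist_b = db, delta = db - da,
                            within_a = da <= tau, within_b = db <= tau,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$crossed_threshold <- xor(out$within_a, out$within_b)
  attr(out, "states") <- states
  attr(out, "tau") <- tau
  class(out) <- c("StateComparison", class(out))
  out
}
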