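#' Rotation-matrix utilities
#'
#' `rotation_about_axis()` builds the proper rotation matrix for a rotation
#' of `angle` degrees about a unit `axis` (Rodrigues formula).
#' `rotation_angle()` extracts the rotation angle in degrees in \[0, 180\]
#' from a proper rotation matrix; `rotation_axis()` the corresponding unit
#' axis (sign convention handled by the caller).
#'
#' @param axis numeric length-3 vector (need not be normalized, but must be
#'   nonzero).
#' @param angle degrees.
#' @param R 3x3 proper rotation matrix.
#' @name rotations
NULL

#' @rdname rotations
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (!is.finite(n) || n < 1e-12)
    stop("parameter error: rotation axis must be nonzero")
  u <- axis / n
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotations
#' @export
rotation_angle <- function(R) {
  tr <- sum(diag(R))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

#' @rdname rotations
#' @export
rotation_axis <- function(R) {
  th <- rotation_angle(R) * pi / 180
  if (th < 1e-9) return(c(1, 0, 0))      # identity: axis undefined
  if (abs(th - pi) > 1e-6) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(th))
  } else {
    # near 180 degrees: axis from the dominant column of R + I
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    v <- M[, j]
  }
  v / sqrt(sum(v^2))
}

# Kabsch least-squares fit: returns proper rotation R and translation t
# such that R %*% p + t approximates q (both 3 x n column conventions are
# avoided; inputs are n x 3 matrices).
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), ncol(P) == 3, ncol(Q) == 3,
            nrow(P) == nrow(Q))
  if (nrow(P) < 3) stop("pairing error: need at least 3 atom pairs")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    stop("rank error: degenerate (collinear) coordinates, fit underdetermined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- unname(sv$v %*% D %*% t(sv$u))
  t <- unname(cq - as.vector(R %*% cp))
  fitted <- sweep(P %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd, n_pairs = nrow(P))
}

pair_coordinates <- function(mobile, reference, mobile_sel, reference_sel,
                             model = 1L) {
  am <- select_atoms(mobile, mobile_sel, model = model)
  ar <- select_atoms(reference, reference_sel, model = model)
  km <- paste(am$chain_id, am$residue_number, am$insertion_code,
              am$atom_name, sep = "\r")
  kr <- paste(ar$chain_id, ar$residue_number, ar$insertion_code,
              ar$atom_name, sep = "\r")
  if (anyDuplicated(km) || anyDuplicated(kr))
    stop("pairing error: selection yields duplicate atom identities; ",
         "restrict the selection")
  common <- intersect(km, kr)
  if (length(km) != length(kr) || length(common) != length(km))
    stop(sprintf(paste0("pairing error: selections resolve to %d (mobile) vs ",
                        "%d (reference) atoms with %d shared identities; ",
                        "atom pairing is by (chain, residue, atom name)"),
                 length(km), length(kr), length(common)))
  im <- match(common, km); ir <- match(common, kr)
  list(P = as.matrix(am[im, c("x", "y", "z")]),
       Q = as.matrix(ar[ir, c("x", "y", "z")]))
}

#' Least-squares superposition of two structures
#'
#' Optimal proper rotation (det +1) and translation mapping the mobile
#' selection onto the reference selection, with RMSD over the paired atoms.
#' Atoms are paired by (chain, residue number, insertion code, atom name)
#' identity; both selections must resolve to the same atom identities.
#'
#' @param mobile,reference [Structure] objects.
#' @param mobile_sel,reference_sel selection expressions (see [selection]);
#'   default `"all"`.
#' @param model model index (default 1).
#' @return list of class `Superposition`: `rotation` (3x3), `translation`
#'   (length 3), `rmsd`, `n_pairs`.
#' @export
superpose <- function(mobile, reference, mobile_sel = "all",
                      reference_sel = mobile_sel, model = 1L) {
  pc <- pair_coordinates(mobile, reference, mobile_sel, reference_sel, model)
  out <- kabsch(pc$P, pc$Q)
  class(out) <- "Superposition"
  out
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: %d pairs, rmsd %.4f Angstrom, rotation %.2f deg\n",
              x$n_pairs, x$rmsd, rotation_angle(x$rotation)))
  invisible(x)
}

#' Apply a rigid transform to a Structure
#'
#' @param s a [Structure].
#' @param rotation 3x3 proper rotation matrix (or a `Superposition`).
#' @param translation length-3 vector.
#' @param expr optional selection: only matching atoms are moved.
#' @return transformed [Structure].
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0),
                                expr = NULL) {
  stopifnot(inherits(s, "Structure"))
  if (inherits(rotation, "Superposition")) {
    translation <- rotation$translation
    rotation <- rotation$rotation
  }
  a <- s$atoms
  idx <- if (is.null(expr)) seq_len(nrow(a)) else which(parse_selection(expr)(a))
  if (length(idx) > 0) {
    xyz <- as.matrix(a[idx, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(rotation), 2, translation, "+")
    a$x[idx] <- xyz[, 1]; a$y[idx] <- xyz[, 2]; a$z[idx] <- xyz[, 3]
  }
  structure_from_atoms(a, metadata = s$metadata)
}

#' Rigid-body rotation of a domain between two conformational states
#'
#' The two states are first superposed on the `core` selection; the
#' residual motion of the `domain` selection is then extracted as a screw
#' motion: rotation angle theta (degrees, in \[0, 180\], from the rotation
#' matrix trace), rotation axis (unit vector), and the translation
#' component along the axis. The axis sign is chosen so the axis
#' translation is non-negative (first nonzero axis component positive when
#' the translation is ~0), which removes the axis-sign ambiguity; theta is
#' therefore symmetric between the two states.
#'
#' @param stateA,stateB [Structure] objects of the same entity in two
#'   conformations.
#' @param core selection expression for the fixed frame.
#' @param domain selection expression for the moving domain.
#' @param model model index (default 1).
#' @return list of class `DomainMotion`: `angle` (degrees), `axis`,
#'   `translation_along_axis` (Angstrom), `core_rmsd`, `domain_rmsd`,
#'   `n_core`, `n_domain`.
#' @export
domain_rotation <- function(stateA, stateB, core, domain, model = 1L) {
  sp_core <- superpose(stateB, stateA, core, core, model = model)
  alignedB <- transform_structure(stateB, sp_core)
  pc <- pair_coordinates(alignedB, stateA, domain, domain, model)
  fit <- kabsch(pc$P, pc$Q)      # maps aligned-B domain onto A domain
  ang <- rotation_angle(fit$rotation)
  ax <- rotation_axis(fit$rotation)
  t_axis <- sum(ax * fit$translation)
  if (t_axis < 0 || (abs(t_axis) < 1e-9 &&
                     ax[which(abs(ax) > 1e-9)[1]] < 0)) {
    ax <- -ax
    t_axis <- -t_axis
  }
  out <- list(angle = ang, axis = ax, translation_along_axis = t_axis,
              core_rmsd = sp_core$rmsd, domain_rmsd = fit$rmsd,
              n_core = sp_core$n_pairs, n_domain = fit$n_pairs)
  class(out) <- "DomainMotion"
  out
}

#' @export
print.DomainMotion <- function(x, ...) {
  cat(sprintf("DomainMotion: %.2f deg about (%.3f, %.3f, %.3f), %.2f Angstrom along axis\n",
              x$angle, x$axis[1], x$axis[2], x$axis[3],
              x$translation_along_axis))
  invisible(x)
}
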