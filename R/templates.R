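# Idealized cofactor templates: atom names, elements and internal
# coordinates (Angstrom), centered near the origin.  Geometry constants:
# Fe-Fe 2.7 in the cubane and rhombic clusters, Fe-S 2.2-2.3, aromatic
# C-C/C-N 1.4, Ni-Fe 2.6 in the bimetallic center.

template_atoms <- function(names, elements, xyz, residue_name) {
  data.frame(element = elements, atom_name = names,
             residue_name = residue_name, residue_number = 1L,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             is_hetero = TRUE, stringsAsFactors = FALSE)
}

template_fes4 <- function() {
  h <- 2.7 / sqrt(2) / 2          # half cube side for Fe-Fe 2.7
  fe <- rbind(c(h, h, h), c(h, -h, -h), c(-h, h, -h), c(-h, -h, h))
  s  <- rbind(c(-h, -h, -h), c(-h, h, h), c(h, -h, h), c(h, h, -h))
  template_atoms(c("FE1", "FE2", "FE3", "FE4", "S1", "S2", "S3", "S4"),
                 c(rep("FE", 4), rep("S", 4)), rbind(fe, s), "SF4")
}

template_fes2 <- function() {
  half_fefe <- 1.35
  sy <- sqrt(2.2^2 - half_fefe^2)   # Fe-S bond 2.2
  xyz <- rbind(c(-half_fefe, 0, 0), c(half_fefe, 0, 0),
               c(0, sy, 0), c(0, -sy, 0))
  template_atoms(c("FE1", "FE2", "S1", "S2"),
                 c("FE", "FE", "S", "S"), xyz, "FES")
}

# Fused linear tricyclic ring lattice (bond length 1.4), pyrimidine ->
# pyrazine -> benzene, plus the two exocyclic carbonyl oxygens.  Standard
# flavin atom numbering; the full name set is the isoalloxazine center set.
template_fmn <- function() {
  b <- 1.4; sx <- b * sin(pi / 3)  # 1.2124
  pos <- rbind(
    N1  = c(0, b, 0),
    C2  = c(-sx, b / 2, 0),
    N3  = c(-sx, -b / 2, 0),
    C4  = c(0, -b, 0),
    C4A = c(sx, -b / 2, 0),
    C10 = c(sx, b / 2, 0),
    N5  = c(2 * sx, -b, 0),
    C5A = c(3 * sx, -b / 2, 0),
    C9A = c(3 * sx, b / 2, 0),
    N10 = c(2 * sx, b, 0),
    C6  = c(4 * sx, -b, 0),
    C7  = c(5 * sx, -b / 2, 0),
    C8  = c(5 * sx, b / 2, 0),
    C9  = c(4 * sx, b, 0),
    O2  = c(-2 * sx * 0.95, b * 1.05, 0),
    O4  = c(0, -b - 1.22, 0),
    C7M = c(6 * sx, -b, 0),
    C8M = c(6 * sx, b, 0))
  template_atoms(rownames(pos),
                 ifelse(grepl("^N", rownames(pos)), "N",
                        ifelse(grepl("^O", rownames(pos)), "O", "C")),
                 pos, "FMN")
}

# Nicotinamide ring (hexagon, bond 1.4) with the amide branch; C4 is the
# hydride-transfer carbon.
template_nad <- function() {
  ang <- (c(-90, -30, 30, 90, 150, 210)) * pi / 180
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  rownames(ring) <- c("N1", "C2", "C3", "C4", "C5", "C6")
  c3 <- ring["C3", ]
  c7 <- c3 + 1.5 * c(cos(pi / 6), sin(pi / 6), 0)
  o7 <- c7 + c(1.1, 0.5, 0)
  n7 <- c7 + c(0.5, -1.2, 0)
  pos <- rbind(ring, C7N = c7, O7N = o7, N7N = n7)
  template_atoms(rownames(pos),
                 ifelse(grepl("^N", rownames(pos)), "N",
                        ifelse(grepl("^O", rownames(pos)), "O", "C")),
                 pos, "NAD")
}

# Bridged bimetallic Ni-Fe pair (2.6 Angstrom), emitted as the two
# single-atom component residues a structure file would carry.
template_nife <- function() {
  out <- template_atoms(c("NI", "FE"), c("NI", "FE"),
                        rbind(c(-1.3, 0, 0), c(1.3, 0, 0)), "NI")
  out$residue_name <- c("NI", "FE")
  out$residue_number <- c(1L, 2L)
  out
}

#' Idealized cofactor template
#'
#' Returns the idealized atom set (names, elements, internal coordinates in
#' Angstrom) used by the synthetic-structure generator for one cofactor of
#' the given type.
#' @param type one of `"FES4"`, `"FES2"`, `"FMN"`, `"NAD"`, `"NIFE"`.
#' @return data frame of template atoms.
#' @export
cofactor_template <- function(type) {
  switch(type,
         FES4 = template_fes4(),
         FES2 = template_fes2(),
         FMN  = template_fmn(),
         NAD  = template_nad(),
         NIFE = template_nife(),
         stop("no template for cofactor type ", type))
}
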