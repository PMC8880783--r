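#' @title Atomic structure container
#'
#' @description A `Structure` is a light container for an atomic model: a
#' data frame of atoms plus free-form metadata. It is the common currency of
#' the package: cofactor detection, distance measurement, graph construction
#' and superposition all operate on it.
#'
#' The atom table has one row per atom and the columns
#' `element`, `atom_name`, `residue_name`, `residue_number`,
#' `insertion_code`, `chain_id`, `x`, `y`, `z` (Angstrom), `occupancy`,
#' `altloc`, `model_index`, `is_hetero`.
#'
#' @param atoms data frame with the columns listed above (missing
#'   `occupancy`, `altloc`, `insertion_code`, `model_index` columns are
#'   filled with defaults 1.0, `""`, `""`, `1L`).
#' @param metadata named list of free-form metadata (title, source path,
#'   format dialect).
#' @return An object of class `Structure`.
#' @export
structure_from_atoms <- function(atoms, metadata = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "atom_name", "residue_name", "residue_number",
            "chain_id", "x", "y", "z", "is_hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1.0, n)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  if (is.null(atoms$altloc)) atoms$altloc <- rep("", n)
  atoms$altloc[is.na(atoms$altloc)] <- ""
  if (is.null(atoms$insertion_code)) atoms$insertion_code <- rep("", n)
  atoms$insertion_code[is.na(atoms$insertion_code)] <- ""
  if (is.null(atoms$model_index)) atoms$model_index <- rep(1L, n)
  atoms$residue_number <- as.integer(atoms$residue_number)
  atoms$model_index <- as.integer(atoms$model_index)
  atoms$is_hetero <- as.logical(atoms$is_hetero)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (n > 0 && !all(is.finite(xyz)))
    stop("non-finite atom coordinates")
  if (n > 0 && (any(atoms$occupancy < 0) || any(atoms$occupancy > 1)))
    stop("occupancy outside [0, 1]")
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, metadata = metadata)
  class(out) <- "Structure"
  out
}

#' Number of atoms in a Structure
#' @param s a `Structure`.
#' @param model optional model index; default counts all models.
#' @return integer atom count.
#' @export
n_atoms <- function(s, model = NULL) {
  stopifnot(inherits(s, "Structure"))
  if (is.null(model)) return(nrow(s$atoms))
  sum(s$atoms$model_index == model)
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure: %d atoms, %d model(s), chains [%s]\n",
              nrow(a), length(unique(a$model_index)),
              paste(sort(unique(a$chain_id)), collapse = " ")))
  het <- a[a$is_hetero, , drop = FALSE]
  if (nrow(het) > 0) {
    tab <- table(het$residue_name)
    cat("  hetero components:",
        paste(sprintf("%s(%d)", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

# Fallback element-by-atom-name table for legacy records whose element
# column is blank.  Metal names are matched whole; otherwise the first
# alphabetic character wins (after stripping leading digits).
.element_fallback <- c(
  FE = "FE", NI = "NI", ZN = "ZN", MG = "MG", MN = "MN", CU = "CU",
  MO = "MO", CO = "CO", "NA" = "NA", K = "K", CL = "CL", SF = "S", SG = "S"
)

infer_element <- function(atom_name, is_hetero) {
  nm <- toupper(trimws(atom_name))
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    n <- sub("^[0-9']+", "", nm[i])
    root <- sub("[0-9']+$", "", n)
    if (!is.na(.element_fallback[root]) && (is_hetero[i] || root %in% c("SF", "SG"))) {
      out[i] <- .element_fallback[[root]]
    } else if (root %in% c("FE", "NI") ) {
      out[i] <- root
    } else {
      out[i] <- substr(n, 1, 1)
    }
  }
  # title-case: FE -> Fe for consistency with format conventions,
  # but keep canonical uppercase symbol internally
  out
}

normalize_element <- function(el) toupper(trimws(el))

# Keep the highest-occupancy altloc per atom site; tie breaks to altloc "A"
# then first occurrence.
resolve_altlocs <- function(atoms) {
  al <- atoms$altloc
  if (all(al == "")) return(atoms)
  key <- paste(atoms$model_index, atoms$chain_id, atoms$residue_number,
               atoms$insertion_code, atoms$residue_name, atoms$atom_name,
               sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  dupk <- unique(key[duplicated(key)])
  for (k in dupk) {
    idx <- which(key == k)
    occ <- atoms$occupancy[idx]
    best <- idx[occ == max(occ)]
    if (length(best) > 1) {
      a <- best[atoms$altloc[best] == "A"]
      best <- if (length(a) > 0) a[1] else best[1]
    } else best <- best[1]
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- tryCatch(readLines(path, n = 50L, warn = FALSE),
                   error = function(e) stop("cannot read file: ", path))
  if (any(grepl("^data_", head)) || any(grepl("_atom_site\\.", head)))
    return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|REMARK|CRYST1|MODEL)", head)))
    return("pdb")
  stop("cannot determine structure format of ", path,
       " (expected PDB or mmCIF)")
}

#' Read an atomic model from PDB or mmCIF
#'
#' All `ATOM`/`HETATM` records of all models are captured. When the element
#' column is absent or blank, the element is inferred from the atom name
#' (with a fallback table for common metal and inorganic-sulfur names).
#' Alternate locations are collapsed to the highest-occupancy altloc
#' (ties resolved to altloc `A`). Coordinates are in Angstrom.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (sniff from extension, then
#'   content).
#' @return A [Structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") format <- guess_format(path)
  pdb <- switch(format,
    pdb   = tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                     error = function(e) stop("PDB parse error in ", path,
                                              ": ", conditionMessage(e))),
    mmcif = tryCatch(suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
                     error = function(e) stop("mmCIF parse error in ", path,
                                              ": ", conditionMessage(e)))
  )
  a <- pdb$atom
  nmod <- max(1L, nrow(pdb$xyz))
  one <- data.frame(
    element = character(nrow(a)),
    atom_name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_number = a$resno,
    insertion_code = ifelse(is.na(a$insert) | a$insert == " ", "", a$insert),
    chain_id = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1.0, a$o),
    altloc = ifelse(is.na(a$alt) | a$alt == " ", "", a$alt),
    model_index = 1L,
    is_hetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  elesy <- if (!is.null(a$elesy)) trimws(a$elesy) else rep("", nrow(a))
  elesy[is.na(elesy)] <- ""
  blank <- elesy == ""
  one$element <- normalize_element(elesy)
  if (any(blank))
    one$element[blank] <- infer_element(one$atom_name[blank],
                                        one$is_hetero[blank])
  atoms <- one
  if (nmod > 1L) {
    reps <- vector("list", nmod)
    for (m in seq_len(nmod)) {
      mi <- one
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      mi$x <- xyz[, 1]; mi$y <- xyz[, 2]; mi$z <- xyz[, 3]
      mi$model_index <- m
      reps[[m]] <- mi
    }
    atoms <- do.call(rbind, reps)
  }
  # occupancy occasionally encoded >1 in legacy files; clamp rather than fail
  atoms$occupancy <- pmin(pmax(atoms$occupancy, 0), 1)
  atoms <- resolve_altlocs(atoms)
  structure_from_atoms(atoms,
    metadata = list(source = path, format = format))
}

#' Write an atomic model to PDB or mmCIF
#'
#' The emitted file re-parses to an equal `Structure` (coordinates at the
#' format's precision: 3 decimals for PDB). Chain identifiers longer than
#' one character, residue numbers above 9999 or atom names longer than four
#' characters do not fit the PDB fixed columns; writing such a structure as
#' PDB raises a capacity error advising mmCIF.
#'
#' @param s a [Structure].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"` (default from file extension).
#' @param model model index to write; `NULL` writes all models (PDB) or
#'   model 1 (mmCIF).
#' @return the path, invisibly.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mmcif"),
                            model = NULL) {
  stopifnot(inherits(s, "Structure"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  a <- s$atoms
  if (!is.null(model)) a <- a[a$model_index == model, , drop = FALSE]
  if (format == "pdb") {
    if (nrow(a) > 0) {
      if (any(nchar(a$chain_id) > 1))
        stop("format-capacity error: chain identifiers longer than one ",
             "character cannot be written as PDB; use mmCIF")
      if (any(a$residue_number > 9999 | a$residue_number < -999))
        stop("format-capacity error: residue numbers outside PDB fixed ",
             "columns; use mmCIF")
      if (any(nchar(a$atom_name) > 4))
        stop("format-capacity error: atom names longer than 4 characters; ",
             "use mmCIF")
    }
    write_pdb_file(a, path)
  } else {
    write_mmcif_file(a, path, title = s$metadata$title)
  }
  invisible(path)
}

write_pdb_file <- function(a, path) {
  if (nrow(a) == 0) {
    writeLines(c("REMARK   generated by cofanet", "END"), path)
    return(invisible(path))
  }
  models <- sort(unique(a$model_index))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   generated by cofanet", con)
  for (m in models) {
    am <- a[a$model_index == m, , drop = FALSE]
    if (length(models) > 1) writeLines(sprintf("MODEL     %4d", m), con)
    # PDB atom-name column convention: names of 1-3 chars for 1-2 letter
    # elements start in column 14; 4-char names fill columns 13-16.
    nm <- am$atom_name
    el <- am$element
    fmt_name <- ifelse(nchar(nm) >= 4 | nchar(el) >= 2,
                       formatC(nm, width = -4),
                       paste0(" ", formatC(nm, width = -3)))
    recs <- sprintf("%-6s%5d %4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    ifelse(am$is_hetero, "HETATM", "ATOM"),
                    (seq_len(nrow(am)) - 1L) %% 99999L + 1L,
                    fmt_name,
                    ifelse(am$altloc == "", " ", am$altloc),
                    am$residue_name,
                    ifelse(am$chain_id == "", " ", am$chain_id),
                    am$residue_number,
                    ifelse(am$insertion_code == "", " ", am$insertion_code),
                    am$x, am$y, am$z, am$occupancy, 0,
                    formatC(am$element, width = 2))
    writeLines(recs, con)
    if (length(models) > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

write_mmcif_file <- function(a, path, title = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("data_%s", if (is.null(title)) "cofanet" else gsub("\\s+", "_", title)), con)
  writeLines("#", con)
  if (nrow(a) > 0) {
    writeLines(c("loop_",
      "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
      "_atom_site.label_atom_id", "_atom_site.label_alt_id",
      "_atom_site.label_comp_id", "_atom_site.label_asym_id",
      "_atom_site.label_entity_id", "_atom_site.label_seq_id",
      "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
      "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
      "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num"), con)
    q <- function(x, blank = ".") ifelse(x == "" | is.na(x), blank, x)
    recs <- sprintf("%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s %d",
                    ifelse(a$is_hetero, "HETATM", "ATOM"),
                    seq_len(nrow(a)), q(a$element, "X"), a$atom_name,
                    q(a$altloc), a$residue_name, q(a$chain_id, "A"),
                    a$residue_number, q(a$insertion_code, "?"),
                    a$x, a$y, a$z, a$occupancy, 0,
                    a$residue_number, a$residue_name, q(a$chain_id, "A"),
                    a$atom_name, a$model_index)
    writeLines(recs, con)
  }
  writeLines("#", con)
  invisible(path)
}
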