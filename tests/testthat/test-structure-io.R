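# Reading, writing and selecting atoms in PDB/mmCIF models.

legacy_pdb_lines <- c(
  "HEADER    TEST MODEL",
  # SF4 cubane with blank element columns (element must be inferred)
  "HETATM    1 FE1  SF4 A 901       0.000   0.000   0.000  1.00 10.00",
  "HETATM    2 FE2  SF4 A 901       2.700   0.000   0.000  1.00 10.00",
  "HETATM    3 FE3  SF4 A 901       0.000   2.700   0.000  1.00 10.00",
  "HETATM    4 FE4  SF4 A 901       0.000   0.000   2.700  1.00 10.00",
  "HETATM    5  S1  SF4 A 901       2.200   2.200   0.000  1.00 10.00",
  "HETATM    6  S2  SF4 A 901       2.200   0.000   2.200  1.00 10.00",
  "HETATM    7  S3  SF4 A 901       0.000   2.200   2.200  1.00 10.00",
  "HETATM    8  S4  SF4 A 901       2.200   2.200   2.200  1.00 10.00",
  # a protein residue with A/B altlocs at different occupancies
  "ATOM      9  N   CYS B  10      10.000  10.000  10.000  1.00 10.00           N",
  "ATOM     10  CA  CYS B  10      11.000  10.000  10.000  1.00 10.00           C",
  "ATOM     11  SG ACYS B  10      12.000  10.000  10.000  0.70 10.00           S",
  "ATOM     12  SG BCYS B  10      12.500  10.000  10.000  0.30 10.00           S",
  "END")

write_legacy_pdb <- function() {
  f <- tempfile(fileext = ".pdb")
  writeLines(legacy_pdb_lines, f)
  f
}

test_that("fixed-column PDB parsing captures hetero records and infers elements", {
  s <- read_structure(write_legacy_pdb())
  sf4 <- s$atoms[s$atoms$residue_name == "SF4", ]
  expect_equal(nrow(sf4), 8)
  expect_true(all(sf4$is_hetero))
  expect_equal(sort(unique(sf4$element)), c("FE", "S"))
  expect_equal(sum(sf4$element == "FE"), 4)
  # altloc collapsed to the higher-occupancy A conformer
  sg <- s$atoms[s$atoms$atom_name == "SG", ]
  expect_equal(nrow(sg), 1)
  expect_equal(sg$occupancy, 0.7)
  expect_equal(sg$x, 12.0)
})

test_that("parsing is deterministic", {
  f <- write_legacy_pdb()
  s1 <- read_structure(f)
  s2 <- read_structure(f)
  expect_identical(s1$atoms, s2$atoms)
})

test_that("write/read round-trips preserve atoms in both formats", {
  s <- hyd_fixture("PB")
  for (fmt in c("pdb", "mmcif")) {
    f <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(s, f, format = fmt)
    r <- read_structure(f)
    expect_equal(n_atoms(r), n_atoms(s))
    expect_equal(r$atoms$residue_name, s$atoms$residue_name)
    expect_equal(r$atoms$chain_id, s$atoms$chain_id)
    expect_equal(r$atoms$element, s$atoms$element)
    expect_lt(max(abs(as.matrix(r$atoms[, c("x", "y", "z")]) -
                        as.matrix(s$atoms[, c("x", "y", "z")]))), 1e-3)
  }
})

test_that("format auto-detection works from content as well as extension", {
  s <- hyd_fixture("apo")
  f <- tempfile(fileext = ".dat")
  write_structure(s, f, format = "mmcif")
  expect_equal(n_atoms(read_structure(f)), n_atoms(s))
  f2 <- tempfile(fileext = ".dat")
  write_structure(s, f2, format = "pdb")
  expect_equal(n_atoms(read_structure(f2)), n_atoms(s))
})

test_that("an empty Structure writes a valid header-only file", {
  s <- structure_from_atoms(cofanet:::empty_atom_table())
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  lines <- readLines(f)
  expect_false(any(grepl("^(ATOM|HETATM)", lines)))
  f2 <- tempfile(fileext = ".cif")
  write_structure(s, f2)
  expect_true(any(grepl("^data_", readLines(f2))))
})

test_that("PDB fixed-column capacity violations advise mmCIF", {
  s <- hyd_fixture("apo")
  s$atoms$chain_id[1] <- "AB"
  expect_error(write_structure(s, tempfile(fileext = ".pdb")), "mmCIF")
  # the same structure is representable in mmCIF
  f <- tempfile(fileext = ".cif")
  write_structure(s, f)
  r <- read_structure(f)
  expect_true("AB" %in% r$atoms$chain_id)
})

test_that("missing files and unreadable content raise I/O and format errors", {
  expect_error(read_structure(tempfile()), "exist")
  f <- tempfile()
  writeLines(c("no structure here", "just text"), f)
  expect_error(read_structure(f), "format")
})

test_that("selection terms restrict atoms exactly and in source order", {
  s <- hyd_fixture("PB")
  b <- select_atoms(s, "chain B and resnum 901-905")
  expect_true(all(b$chain_id == "B"))
  expect_true(all(b$residue_number >= 901 & b$residue_number <= 905))
  expect_false(any(c("FMN", "NAD") %in% b$residue_name))

  sf4 <- select_atoms(s, "hetero and resname SF4")
  expect_equal(length(unique(paste(sf4$chain_id, sf4$residue_number))), 8)

  fe <- select_atoms(s, "elem FE and not resname SF4,FES")
  expect_equal(nrow(fe), 1)   # the NiFe iron
  expect_equal(fe$chain_id, "L")
})

test_that("selection algebra obeys complement, union and idempotence laws", {
  s <- hyd_fixture("BR")
  all_keys <- paste(s$atoms$chain_id, s$atoms$residue_number,
                    s$atoms$atom_name)
  for (expr in c("chain A", "hetero", "resnum 901-903", "elem FE",
                 "resname FMN or elem S")) {
    inside <- select_atoms(s, expr)
    outside <- select_atoms(s, paste("not (", expr, ")"))
    keys <- c(paste(inside$chain_id, inside$residue_number, inside$atom_name),
              paste(outside$chain_id, outside$residue_number,
                    outside$atom_name))
    expect_setequal(keys, all_keys)
    expect_equal(nrow(inside) + nrow(outside), nrow(s$atoms))
    # idempotence: re-applying the predicate to its own result changes nothing
    again <- subset_structure(subset_structure(s, expr), expr)
    expect_identical(again$atoms, subset_structure(s, expr)$atoms)
  }
})

test_that("selection syntax errors name the offending position", {
  s <- hyd_fixture("apo")
  expect_error(select_atoms(s, "chain A and"), "position")
  expect_error(select_atoms(s, "frobnicate B"), "unknown term")
  expect_error(select_atoms(s, "(chain A"), "\\)")
  expect_error(select_atoms(s, "resnum x"), "residue number")
})
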