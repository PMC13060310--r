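test_that("PDB parsing keeps heavy atoms, maps MSE, drops waters and hydrogens", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path, with_water = TRUE, with_mse = TRUE)
  s <- read_structure(path)
  expect_s3_class(s, "burial_structure")
  expect_equal(n_residues(s), 3)
  expect_equal(residue_types(s), c("ALA", "GLY", "MET"))  # MSE -> MET
  expect_false(any(s$element == "H"))
  expect_false(any(s$res_name %in% c("HOH", "MSE")))
  expect_true(all(s$radius > 0))
  expect_equal(s$res_index, sort(s$res_index))
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path, altloc = TRUE)
  s <- read_structure(path)
  ca2 <- s[s$res_index == 2 & s$atom_name == "CA", ]
  expect_equal(nrow(ca2), 1)
  expect_equal(ca2$x, 4.000)          # the occ 0.6 conformer
  expect_equal(ca2$occupancy, 0.6)
  # and with the occupancies reversed the B conformer wins
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path2, altloc = TRUE, altloc_occ = c(0.3, 0.7))
  s2 <- read_structure(path2)
  cb2 <- s2[s2$res_index == 2 & s2$atom_name == "CA", ]
  expect_equal(cb2$x, 4.100)
  expect_equal(cb2$occupancy, 0.7)
})

test_that("files without standard residues and absent chains error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "O", "HOH", "A", 1, 0, 0, 0, elem = "O",
                        rectype = "HETATM"), "END"), path)
  expect_error(read_structure(path), "no standard")
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(path2)
  expect_error(read_structure(path2, chain = "Z"), "chain")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("write/read round-trip preserves coordinates to PDB precision", {
  s <- helix_fixture(8)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  s2 <- read_structure(path)
  expect_equal(n_residues(s2), 8)
  expect_equal(nrow(s2), nrow(s))
  expect_lt(max(abs(s2$x - s$x), abs(s2$y - s$y), abs(s2$z - s$z)), 1e-3)
  expect_equal(s2$radius, s$radius)  # SCB radii rematched from the table
})

test_that("gzipped PDB files parse identically", {
  s <- helix_fixture(6)
  plain <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, plain)
  gz <- withr::local_tempfile(fileext = ".pdb.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(plain), con)
  close(con)
  expect_equal(read_structure(gz)$x, read_structure(plain)$x)
})

test_that("radii config files load and swap into parsing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("res_name\tatom_name\telement\tradius",
               "*\t*\tC\t1.9", "*\t*\tN\t1.6", "*\t*\tO\t1.5",
               "*\t*\tS\t1.8", "*\t*\tX\t1.7"), path)
  tab <- read_radii(path)
  expect_equal(nrow(tab), 5)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(pdb)
  s <- read_structure(pdb, radii = tab)
  expect_equal(unique(s$radius[s$element == "C"]), 1.9)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("res_name\tatom_name\telement\tradius", "*\t*\tC\t-1"), bad)
  expect_error(read_radii(bad), "positive")
})

test_that("identical sequences align to the identity mapping", {
  s <- helix_fixture(10, seed = 3)
  ap <- align_and_trim(s, s)
  expect_equal(ap$mapping$target_index, 1:10)
  expect_equal(ap$mapping$model_index, 1:10)
  expect_equal(n_residues(ap$target), n_residues(ap$model))
})

test_that("terminal overhangs are trimmed so lengths match exactly", {
  seq_core <- c("MET", "LYS", "VAL", "LEU", "TRP", "GLU", "PHE", "ARG",
                "ASP", "ILE")
  target <- build_backbone(list(c("helix", 10)), sequence = seq_core, seed = 1)
  model <- build_backbone(list(c("helix", 12)),
                          sequence = c("GLY", "GLY", seq_core), seed = 1)
  ap <- align_and_trim(target, model)
  expect_equal(n_residues(ap$model), 10)
  expect_equal(n_residues(ap$target), 10)
  expect_equal(ap$mapping$model_index, 3:12)  # two N-terminal extras removed
  # trimming is symmetric in the arguments (mirrored mapping)
  ap2 <- align_and_trim(model, target)
  expect_equal(ap2$mapping$target_index, ap$mapping$model_index)
  expect_equal(ap2$mapping$model_index, ap$mapping$target_index)
})

test_that("global alignment score matches brute-force enumeration on short peptides", {
  sub <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  from1 <- function(s) {
    vapply(strsplit(s, "")[[1]], function(a)
      names(burialcode:::AA1)[burialcode:::AA1 == a], "")
  }
  mk <- function(s) {
    build_backbone(list(c("coil", nchar(s))), seed = 1, sequence = from1(s),
                   collapse_iter = 0)
  }
  cases <- list(c("MKV", "MKV"), c("MKVL", "MKV"), c("WMA", "AMW"),
                c("KREW", "NQDH"))
  for (cs in cases) {
    got <- align_and_trim(mk(cs[1]), mk(cs[2]))$score
    want <- align_score_oracle(cs[1], cs[2], sub)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("pairs whose optimal alignment needs interior gaps are rejected", {
  from1 <- function(s) {
    vapply(strsplit(s, "")[[1]], function(a)
      names(burialcode:::AA1)[burialcode:::AA1 == a], "")
  }
  t <- build_backbone(list(c("coil", 8)), seed = 1,
                      sequence = from1("MKVLWEFR"), collapse_iter = 0)
  m <- build_backbone(list(c("coil", 7)), seed = 1,
                      sequence = from1("MKVWEFR"), collapse_iter = 0)
  expect_error(align_and_trim(t, m), "interior")
})

test_that("self-alignment scores at least as high as alignment to any other sequence", {
  set.seed(7)
  for (r in 1:5) {
    a <- helix_fixture(8, seed = r)
    b <- helix_fixture(8, seed = r + 100)
    expect_gte(align_and_trim(a, a)$score, align_and_trim(a, b)$score)
  }
})
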