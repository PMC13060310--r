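# Fixtures are generated in code; nothing is read from disk except temp
# files the tests write themselves.

# bare-bones structure from explicit atom positions (one CA per residue by
# default); radius defaults to carbon
fixture_structure <- function(xyz, res_name = "ALA", atom_name = "CA",
                              element = "C", radius = 1.7,
                              res_index = seq_len(nrow(xyz))) {
  n <- nrow(xyz)
  burialcode:::new_structure(tibble::tibble(
    res_index = as.integer(res_index),
    res_name = rep_len(res_name, n),
    res_number = as.integer(res_index),
    ins = "",
    atom_name = rep_len(atom_name, n),
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1,
    radius = rep_len(radius, n)
  ))
}

# two-residue structure with CA atoms exactly `d` apart
fixture_pair_at <- function(d) {
  fixture_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
}

helix_fixture <- function(n = 12, seed = 1) {
  build_backbone(list(c("helix", n)), seed = seed)
}

# a small PDB text fixture exercising altloc, waters, hydrogens and MSE
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, elem = "C", alt = " ", rectype = "ATOM  ") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rectype, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resname, chain, resno, x, y, z, occ, 0, elem)
}

write_tiny_pdb <- function(path, altloc = FALSE, with_water = FALSE,
                           with_mse = FALSE, altloc_occ = c(0.6, 0.4)) {
  lines <- c(
    pdb_line(1, "N", "ALA", "A", 1, 0.000, 0.000, 0.000, elem = "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.458, 0.000, 0.000),
    pdb_line(3, "C", "ALA", "A", 1, 2.009, 1.420, 0.000),
    pdb_line(4, "O", "ALA", "A", 1, 1.251, 2.390, 0.000, elem = "O"),
    pdb_line(5, "H", "ALA", "A", 1, -0.500, -0.800, 0.000, elem = "H"),
    pdb_line(6, "N", "GLY", "A", 2, 3.332, 1.536, 0.000, elem = "N"),
    if (altloc) c(
      pdb_line(7, "CA", "GLY", "A", 2, 4.000, 2.800, 0.000,
               occ = altloc_occ[1], alt = "A"),
      pdb_line(8, "CA", "GLY", "A", 2, 4.100, 2.900, 0.100,
               occ = altloc_occ[2], alt = "B")
    ) else pdb_line(7, "CA", "GLY", "A", 2, 4.000, 2.800, 0.000),
    pdb_line(9, "C", "GLY", "A", 2, 5.400, 2.500, 0.000),
    pdb_line(10, "O", "GLY", "A", 2, 6.100, 3.500, 0.000, elem = "O"),
    if (with_mse) c(
      pdb_line(11, "N", "MSE", "A", 3, 6.000, 1.200, 0.000, elem = "N",
               rectype = "HETATM"),
      pdb_line(12, "CA", "MSE", "A", 3, 7.400, 1.000, 0.000, rectype = "HETATM"),
      pdb_line(13, "C", "MSE", "A", 3, 8.000, -0.400, 0.000, rectype = "HETATM"),
      pdb_line(14, "O", "MSE", "A", 3, 7.300, -1.400, 0.000, elem = "O",
               rectype = "HETATM")
    ),
    if (with_water) pdb_line(20, "O", "HOH", "A", 90, 9, 9, 9, elem = "O",
                             rectype = "HETATM"),
    "END"
  )
  writeLines(lines, path)
  path
}

# shared small benchmark, built once per test run
.bench_env <- new.env()
bench_small <- function() {
  if (is.null(.bench_env$b)) {
    .bench_env$b <- make_benchmark(n_targets = 2, n_decoys = 16, seed = 42)
  }
  .bench_env$b
}

# independent LDDT oracle: direct double loop over pairs and thresholds
lddt_oracle <- function(ta, mo, radius = 15, thresholds = c(0.5, 1, 2, 4)) {
  n <- nrow(ta)
  per <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fr <- c()
    for (t in thresholds) {
      kept <- 0; tot <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        dt <- sqrt(sum((ta[i, ] - ta[j, ])^2))
        if (dt >= radius) next
        tot <- tot + 1
        dm <- sqrt(sum((mo[i, ] - mo[j, ])^2))
        if (abs(dt - dm) < t) kept <- kept + 1
      }
      if (tot > 0) fr <- c(fr, kept / tot)
    }
    if (length(fr)) per[i] <- mean(fr)
  }
  mean(per, na.rm = TRUE)
}

# brute-force global alignment score by enumeration over all alignments of
# two short sequences (affine gaps; first gap position charged open+extend)
align_score_oracle <- function(a, b, sub, open = -10, extend = -0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- -Inf
  # recursive enumeration of alignment columns
  rec <- function(i, j, score, prev) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      rec(i + 1, j + 1, score + sub[a[i], b[j]], "m")
    }
    if (i <= length(a)) {
      pen <- if (prev == "da") extend else open + extend
      rec(i + 1, j, score + pen, "da")
    }
    if (j <= length(b)) {
      pen <- if (prev == "db") extend else open + extend
      rec(i, j + 1, score + pen, "db")
    }
  }
  rec(1, 1, 0, "none")
  best
}
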