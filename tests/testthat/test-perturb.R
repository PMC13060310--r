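test_that("label flips hit the requested probability and are reproducible", {
  b <- rep(c(0L, 1L), 50)
  expect_equal(flip_labels(b, 0, seed = 1)$perturbed, b)
  expect_equal(flip_labels(b, 0, seed = 1)$f_flip, 0)
  f1 <- flip_labels(b, 1, seed = 1)
  expect_equal(f1$perturbed, 1L - b)
  expect_equal(f1$f_flip, 1)
  n <- 10000
  big <- rep(c(0L, 1L), n / 2)
  for (p in c(0.1, 0.5, 0.9)) {
    fr <- flip_labels(big, p, seed = 7)$f_flip
    expect_lt(abs(fr - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_identical(flip_labels(big, 0.3, seed = 5)$perturbed,
                   flip_labels(big, 0.3, seed = 5)$perturbed)
  expect_error(flip_labels(b, 1.2), "p must")
})

test_that("composing two independent flips has the expected net flip rate", {
  n <- 20000
  b <- rep(0L, n)
  p <- 0.2; q <- 0.3
  f1 <- flip_labels(b, p, seed = 11)$perturbed
  f2 <- flip_labels(f1, q, seed = 12)$perturbed
  net <- mean(f2 != b)
  want <- p * (1 - q) + q * (1 - p)
  expect_lt(abs(net - want), 3 * sqrt(want * (1 - want) / n))
})

test_that("robustness curve starts at the unperturbed correlation and degrades", {
  b <- bench_small()
  rc <- robustness_curve(b, p_values = c(0, 0.25, 0.5), n_repeats = 4,
                         n_boot = 200, seed = 31)
  expect_equal(nrow(rc), 3)
  # p = 0 reproduces the unperturbed rho exactly
  phis <- unlist(lapply(b$targets, function(t) {
    vapply(t$decoys$burial, function(bp) {
      burialcode:::phi_pair_fast(t$native$burial, bp)
    }, numeric(1))
  }))
  ld <- unlist(lapply(b$targets, function(t) t$decoys$lddt))
  rho0 <- as.numeric(flattened_spearman(phis, ld, n_boot = 200, seed = 99))
  expect_equal(rc$f_flip[1], 0)
  expect_equal(rc$rho[1], rho0, tolerance = 0.06)  # same phis, bootstrap noise only
  expect_gt(rc$rho[1], rc$rho[3])          # noise degrades the correlation
  expect_equal(rc$f_flip[2], 0.25, tolerance = 0.1)
  expect_true(all(rc$rho >= -1 & rc$rho <= 1))
})

test_that("external predictions reduce to planted flip fractions", {
  b <- bench_small()
  truth <- lapply(b$targets, function(t) t$native$burial)
  p0 <- external_predictor_point(b, truth, n_boot = 200, seed = 3)
  expect_equal(p0$f_flip, 0)
  # plant exactly k errors in the first target
  k <- 5
  planted <- truth
  planted[[1]][1:k] <- 1L - planted[[1]][1:k]
  pk <- external_predictor_point(b, planted, n_boot = 200, seed = 3)
  total_n <- sum(vapply(b$targets, `[[`, numeric(1), "n"))
  expect_equal(pk$f_flip, k / total_n)
  # all-core predictions: degenerate phi everywhere, rho defined (no NaN)
  allcore <- lapply(b$targets, function(t) rep(1L, t$n))
  pa <- external_predictor_point(b, allcore, n_boot = 200, seed = 3)
  expect_false(is.na(pa$rho))
  expect_error(external_predictor_point(b, list(truth[[1]])), "per target")
})

test_that("core hydrophobicity sums only over buried residues", {
  scale <- setNames(rep(0, 20), burialcode:::AA3)  # synthetic scale
  scale["LEU"] <- 0.7
  attr(scale, "scale") <- "synthetic"
  types <- c("LEU", rep("GLY", 9))
  expect_equal(as.numeric(core_hydrophobicity(rep(0L, 10), types, scale)), 0)
  expect_equal(as.numeric(core_hydrophobicity(c(1L, rep(0L, 9)), types, scale)),
               0.07)
  set.seed(19)
  sc2 <- setNames(rnorm(20), burialcode:::AA3)
  attr(sc2, "scale") <- "synthetic2"
  ty <- sample(burialcode:::AA3, 50, TRUE)
  bu <- sample(0:1, 50, TRUE)
  expect_equal(as.numeric(core_hydrophobicity(bu, ty, sc2)),
               sum(sc2[ty] * bu) / 50, tolerance = 1e-12)
  expect_error(core_hydrophobicity(bu, c(ty[-1], "XXX"), sc2), "missing")
})

test_that("delta hydrophobicity is antisymmetric with the documented sign", {
  scale <- hydro_scale("consensus")
  types <- c("LEU", "ILE", "ARG", "GLY", "SER")
  hn <- core_hydrophobicity(c(1L, 0L, 0L, 0L, 0L), types, scale)
  hp <- core_hydrophobicity(c(1L, 1L, 0L, 0L, 0L), types, scale)
  d <- delta_hydrophobicity(hn, hp)
  expect_lt(d, 0)  # the model buried an extra hydrophobic residue
  expect_equal(delta_hydrophobicity(hp, hn), -d)
  expect_equal(delta_hydrophobicity(hn, hn), 0)
  bad <- hp
  attr(bad, "scale") <- "other"
  expect_error(delta_hydrophobicity(hn, bad), "different scales")
})

test_that("per-type rates recover planted base rates, entropies and accuracies", {
  # type A always surface and always right; type B half core; type C 1/4 core
  types <- c(rep("ALA", 40), rep("VAL", 40), rep("LEU", 40))
  native <- c(rep(0L, 40), rep(c(0L, 1L), 20), rep(c(1L, 0L, 0L, 0L), 10))
  predicted <- native
  predicted[41:60] <- 1L - predicted[41:60]  # half of VAL mislabelled
  tr <- suppressWarnings(type_rates(native, predicted, types))
  ala <- tr[tr$res_name == "ALA", ]
  expect_equal(ala$p_c, 0)
  expect_equal(ala$entropy, 0)
  expect_equal(ala$accuracy, 1)
  val <- tr[tr$res_name == "VAL", ]
  expect_equal(val$p_c, 0.5)
  expect_equal(val$entropy, 1)
  expect_equal(val$accuracy, 0.5)
  leu <- tr[tr$res_name == "LEU", ]
  expect_equal(leu$p_c, 0.25)
  expect_equal(leu$entropy, -0.25 * log2(0.25) - 0.75 * log2(0.75),
               tolerance = 1e-12)
  expect_warning(type_rates(native, predicted, types), "omitted")
})

test_that("base-rate entropy is symmetric and maximal at half burial", {
  ent <- function(p) {
    tr <- suppressWarnings(type_rates(
      native = c(rep(1L, round(p * 100)), rep(0L, 100 - round(p * 100))),
      predicted = rep(0L, 100), types = rep("TRP", 100)))
    tr$entropy
  }
  expect_equal(ent(0.3), ent(0.7), tolerance = 1e-12)
  expect_gt(ent(0.5), ent(0.3))
  expect_gt(ent(0.5), ent(0.9))
})
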