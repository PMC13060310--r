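test_that("information model recovers closed-form bit values", {
  m <- fit_information(list(c(1, 1, 0, 0)), alphabet = c("0", "1"))
  expect_equal(m$iota, c(1, 1))
  m2 <- fit_information(list(rep(c(0, 0, 0, 1), 25)), alphabet = c("0", "1"))
  expect_equal(m2$p, c(0.75, 0.25))
  expect_equal(m2$iota[m2$outcome == "1"], 2)
  expect_equal(m2$iota[m2$outcome == "0"], -log2(0.75), tolerance = 1e-12)
})

test_that("pooled frequencies match brute-force counting; unseen outcomes stay finite", {
  set.seed(41)
  corpus <- lapply(1:5, function(i) sample(c("H", "E", "C"), 30, TRUE))
  m <- fit_information(corpus, alphabet = c("H", "E", "C"))
  pooled <- unlist(corpus)
  for (o in c("H", "E", "C")) {
    expect_equal(m$count[m$outcome == o], sum(pooled == o))
  }
  expect_equal(sum(m$p), 1)
  # zero-count outcome: Jeffreys pseudo-count keeps iota finite
  m0 <- fit_information(list(rep("H", 10)), alphabet = c("H", "E", "C"))
  expect_true(all(is.finite(m0$iota)))
  expect_equal(sum(m0$p), 1)
  expect_error(fit_information(list()), "at least one label")
})

test_that("flattened Spearman reproduces rank-perfect and degenerate cases", {
  ld <- seq(0.05, 0.95, length.out = 40)
  up <- as.numeric(flattened_spearman(ld * 2 - 0.3, ld, seed = 1, n_boot = 200))
  dn <- as.numeric(flattened_spearman(-ld, ld, seed = 1, n_boot = 200))
  expect_equal(up, 1)
  expect_equal(dn, -1)
  tied <- flattened_spearman(rep(0.4, 40), ld, seed = 1)
  expect_equal(as.numeric(tied), 0)
  expect_true(attr(tied, "degenerate"))
  expect_error(flattened_spearman(1:10 / 10, rep(0.01, 10)), "bins")
  expect_error(flattened_spearman(1:2, 1:2 / 2), "3 observations")
})

test_that("flattening agrees with plain Spearman when LDDT is already uniform", {
  set.seed(43)
  ld <- runif(400)
  ph <- ld + rnorm(400, 0, 0.1)
  flat <- as.numeric(flattened_spearman(ph, ld, seed = 2, n_boot = 400))
  plain <- cor(ph, ld, method = "spearman")
  expect_equal(flat, plain, tolerance = 0.05)
  # invariance under strictly monotone transforms of phi
  flat2 <- as.numeric(flattened_spearman(exp(3 * ph), ld, seed = 2, n_boot = 400))
  expect_equal(flat, flat2, tolerance = 1e-12)
})

test_that("restraint subsampling at fraction 1 reproduces the full channel", {
  b <- bench_small()
  info <- benchmark_information(b, "burial")
  d <- subsample_restraints(b, "burial", 1, info = info, seed = 5)
  expect_equal(d$n_r, sum(vapply(b$targets, `[[`, numeric(1), "n")))
  # phi equals the full-channel phi for every decoy
  full <- unlist(lapply(b$targets, function(t) {
    vapply(t$decoys$burial, function(bp) {
      burialcode:::phi_pair_fast(t$native$burial, bp)
    }, numeric(1))
  }))
  expect_equal(d$scores$phi, unname(full), tolerance = 1e-12)
  # I at fraction 1 is the mean iota of the native labels (per target)
  want <- mean(vapply(b$targets, function(t) {
    sum(info$iota[match(as.character(t$native$burial), info$outcome)]) / t$n
  }, numeric(1)))
  expect_equal(d$I, want, tolerance = 1e-12)
  # determinism: same seed, same draw
  d2 <- subsample_restraints(b, "burial", 0.3, info = info, seed = 9)
  d3 <- subsample_restraints(b, "burial", 0.3, info = info, seed = 9)
  expect_identical(d2$selected, d3$selected)
  expect_equal(d2$scores$phi, d3$scores$phi)
  expect_error(subsample_restraints(b, "burial", 0), "fraction")
})

test_that("information spent scales linearly with the sampled fraction", {
  # balanced binary channel: iota = 1 bit, so I(f) ~ f bits per residue
  n <- 10000
  bal <- list(rep(c(0L, 1L), n / 2))
  info <- fit_information(bal, alphabet = c("0", "1"))
  fake <- list(targets = list(list(
    name = "t", n = n,
    native = list(burial = rep(c(0L, 1L), n / 2)),
    decoys = tibble::tibble(decoy_id = c("d1", "d2", "d3"),
                            lddt = c(0.3, 0.6, 0.9),
                            burial = list(rep(c(0L, 1L), n / 2),
                                          rep(c(1L, 0L), n / 2),
                                          rep(c(0L, 1L), n / 2)))
  )))
  class(fake) <- "burial_benchmark"
  for (f in c(0.25, 0.5, 1)) {
    d <- subsample_restraints(fake, "burial", f, info = info, seed = 3)
    expect_equal(d$I, f, tolerance = 3 * sqrt(0.25 / n))
  }
})

test_that("sparse contact labels carry more information than non-contacts", {
  b <- bench_small()
  m <- benchmark_information(b, "contacts")
  expect_lt(m$p[m$outcome == "1"], 0.5)  # contacts are the minority class
  expect_gt(m$iota[m$outcome == "1"], m$iota[m$outcome == "0"])
})

test_that("rho-vs-I curves are consistent and monotone on the benchmark", {
  b <- bench_small()
  cv <- rho_vs_I_curve(b, "burial", fractions = c(0.05, 0.3, 1), n_repeats = 6,
                       n_boot = 200, seed = 21)
  expect_equal(nrow(cv), 3)
  expect_true(all(diff(cv$i_bits) > 0))    # I increases with the fraction
  expect_gt(cv$rho[3], cv$rho[1])          # more information, better rho
  # fraction 1 point equals the directly computed full-information point
  info <- benchmark_information(b, "burial")
  d <- subsample_restraints(b, "burial", 1, info = info, seed = 1)
  expect_equal(cv$i_bits[3], d$I, tolerance = 1e-12)
})

test_that("I* interpolates crossings and reports unreachable thresholds absent", {
  cv <- tibble::tibble(fraction = c(0.1, 1), i_bits = c(0.4, 0.8),
                       rho = c(0.85, 0.95))
  expect_equal(i_star(cv, 0.9), 0.6)
  low <- tibble::tibble(fraction = 1, i_bits = c(0.2, 0.9), rho = c(0.5, 0.8))
  expect_true(is.na(i_star(low, 0.9)))
  first <- tibble::tibble(fraction = 1, i_bits = c(0.3, 0.9), rho = c(0.93, 0.97))
  expect_equal(i_star(first, 0.9), 0.3)
  expect_error(i_star(tibble::tibble()), "empty")
  # uniformly larger rho can only lower I*
  up <- cv
  up$rho <- up$rho + 0.04
  expect_lte(i_star(up, 0.9), i_star(cv, 0.9))
})
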