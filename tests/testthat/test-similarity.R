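test_that("confusion matrices tally label pairs exactly", {
  M <- build_confusion(c(1, 1, 0, 0), c(1, 1, 0, 0), alphabet = c("0", "1"))
  expect_equal(unclass(M)[cbind(c("0", "1"), c("0", "1"))], c(2L, 2L),
               ignore_attr = TRUE)
  M2 <- build_confusion(c(1, 0), c(0, 1), alphabet = c("0", "1"))
  expect_equal(as.integer(unclass(M2)), c(0L, 1L, 1L, 0L))
  set.seed(3)
  a <- sample(0:1, 10, TRUE)
  b <- sample(0:1, 10, TRUE)
  M3 <- unclass(build_confusion(a, b, alphabet = c("0", "1")))
  for (i in 0:1) for (j in 0:1) {
    expect_equal(M3[i + 1, j + 1], sum(a == i & b == j), ignore_attr = TRUE)
  }
  expect_error(build_confusion(c(0, 1), c(0, 1, 1)), "length")
})

test_that("binary phi: perfect agreement, no correlation, and the Pearson oracle", {
  both <- c(rep(1, 5), rep(0, 5))
  expect_equal(as.numeric(phi(both, both, alphabet = c("0", "1"))), 1)
  M <- build_confusion(c(0, 0, 1, 1), c(0, 1, 0, 1), alphabet = c("0", "1"))
  expect_equal(as.numeric(phi_binary(M)), 0)
  M2 <- matrix(c(3, 1, 1, 3), 2, 2)
  expect_equal(as.numeric(phi_binary(M2)), 0.5)
  # independent oracle: binary MCC equals the Pearson correlation of the
  # 0/1 vectors
  set.seed(11)
  for (r in 1:20) {
    a <- sample(0:1, 50, TRUE)
    b <- sample(0:1, 50, TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(as.numeric(phi(a, b, alphabet = c("0", "1"))), cor(a, b),
                 tolerance = 1e-12)
    expect_equal(burialcode:::phi_pair_fast(a, b), cor(a, b), tolerance = 1e-12)
  }
})

test_that("degenerate margins yield phi = 0 with a flag, never NaN", {
  M <- build_confusion(c(1, 1, 0, 0), c(1, 1, 1, 1), alphabet = c("0", "1"))
  p <- phi_binary(M)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))
  expect_false(is.nan(as.numeric(p)))
})

test_that("phi is symmetric in its arguments and invariant to relabeling", {
  set.seed(5)
  a <- sample(0:1, 40, TRUE)
  b <- sample(0:1, 40, TRUE)
  expect_equal(as.numeric(phi(a, b, alphabet = c("0", "1"))),
               as.numeric(phi(b, a, alphabet = c("0", "1"))), tolerance = 1e-12)
  expect_equal(as.numeric(phi(a, b, alphabet = c("0", "1"))),
               as.numeric(phi(1 - a, 1 - b, alphabet = c("0", "1"))),
               tolerance = 1e-12)
})

test_that("multiclass phi reduces to the binary formula and is 1 on diagonals", {
  set.seed(17)
  for (r in 1:200) {
    M <- matrix(sample(0:9, 4, TRUE), 2, 2)
    class(M) <- c("confusion_matrix", "matrix")
    b <- phi_binary(M)
    m <- phi_multiclass(M)
    expect_equal(as.numeric(b), as.numeric(m), tolerance = 1e-12)
  }
  D <- diag(c(3L, 2L, 5L))
  expect_equal(as.numeric(phi_multiclass(D)), 1)
  # alphabet permutation invariance
  set.seed(23)
  a <- sample(c("H", "E", "C"), 60, TRUE)
  b <- sample(c("H", "E", "C"), 60, TRUE)
  p1 <- as.numeric(phi(a, b, alphabet = c("H", "E", "C")))
  p2 <- as.numeric(phi(a, b, alphabet = c("C", "H", "E")))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("multiclass phi is centered at zero under the permutation null", {
  set.seed(29)
  n <- 10000
  phis <- vapply(1:40, function(r) {
    a <- sample(1:3, n, TRUE)
    b <- sample(1:3, n, TRUE)
    burialcode:::phi_multi_fast(a, b, 3)
  }, numeric(1))
  se <- sd(phis) / sqrt(length(phis))
  expect_lt(abs(mean(phis)), 3 * se + 1e-3)
})

test_that("LDDT is exact on identity, rigid motions, and a brute-force oracle", {
  s <- helix_fixture(10, seed = 9)
  expect_equal(lddt(s, s)$global, 1)
  th <- 0.9
  rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  s2 <- burialcode:::transform_structure(s, rot, c(7, -1, 2))
  expect_equal(lddt(s, s2)$global, 1, tolerance = 1e-9)
  # 4-residue toy: displace one CA by 3 A and enumerate pairs directly
  ta <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0))
  mo <- ta
  mo[2, ] <- mo[2, ] + c(0, 3, 0)
  got <- lddt(fixture_structure(ta), fixture_structure(mo))
  expect_equal(got$global, lddt_oracle(ta, mo), tolerance = 1e-12)
  # asymmetry: the first argument defines the reference pair set
  big <- ta * 1.5
  expect_false(isTRUE(all.equal(
    lddt(fixture_structure(ta), fixture_structure(big))$global,
    lddt(fixture_structure(big), fixture_structure(ta))$global)))
})

test_that("LDDT stays within [0, 1] and respects strict thresholds", {
  set.seed(31)
  s <- helix_fixture(8, seed = 13)
  for (sig in c(0.1, 1, 5)) {
    d <- s
    d$x <- d$x + rnorm(nrow(d), 0, sig)
    d$y <- d$y + rnorm(nrow(d), 0, sig)
    d$z <- d$z + rnorm(nrow(d), 0, sig)
    g <- lddt(s, d)$global
    expect_gte(g, 0)
    expect_lte(g, 1)
  }
  # exactly-at-threshold displacement is not preserved (strict <)
  ta <- rbind(c(0, 0, 0), c(4, 0, 0))
  mo <- rbind(c(0, 0, 0), c(8, 0, 0))  # |d_t - d_m| = 4 = largest threshold
  expect_equal(lddt(fixture_structure(ta), fixture_structure(mo))$global, 0)
  far <- fixture_structure(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_error(lddt(far, far), "reference pairs")
  expect_error(lddt(helix_fixture(4), helix_fixture(6)), "equal length")
})
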