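test_that("difference matrices subtract element-wise and check labels", {
  bands <- quickBands()
  a <- randomSM(bands, paste0("r", 1:4))
  b <- randomSM(bands, paste0("r", 1:4))
  expect_true(all(dsm(a, a)@matrix == 0))
  expect_equal(dsm(a, b)@matrix, -dsm(b, a)@matrix)
  expect_equal(dsm(a, b)@matrix, a@matrix - b@matrix)
  other <- randomSM(bands, paste0("x", 1:4))
  expect_error(dsm(a, other), "labels")
})

test_that("sign-flip window test hits the floor for a constant strong effect", {
  set.seed(40)
  dsms <- lapply(1:16, function(i)
    matrix(rnorm(9, mean = c(5, rep(0, 8)), sd = 0.5), 3))
  pr <- permWindowTest(dsms, nPerm = 2000, seed = 2, q = 0.05)
  expect_lte(pr@p[1, 1], 2 / 2001)   # at or adjacent to the floor
  expect_true(pr@mask[1, 1])
  expect_gte(min(pr@p), 1 / 2001)
  # identical seed reproduces identical results bit for bit
  pr2 <- permWindowTest(dsms, nPerm = 2000, seed = 2, q = 0.05)
  expect_identical(pr@p, pr2@p)
  expect_error(permWindowTest(dsms[1]), "2 subjects")
  expect_warning(permWindowTest(dsms[1:3], nPerm = 50, seed = 1),
                 "100 permutations")
})

test_that("Monte-Carlo window test agrees with exhaustive enumeration", {
  set.seed(41)
  v <- rnorm(12, mean = 0.4)
  exact <- enumSignFlipP(v)   # all 2^12 sign assignments
  dsms <- lapply(v, function(x) matrix(x, 1, 1))
  pr <- permWindowTest(dsms, nPerm = 20000, seed = 5)
  expect_lt(abs(pr@p[1, 1] - exact), 0.01)
})

test_that("window-test p-values are uniform under the null", {
  set.seed(42)
  p <- unlist(lapply(1:20, function(s) {
    dsms <- lapply(1:23, function(i) matrix(rnorm(36), 6))
    as.vector(permWindowTest(dsms, nPerm = 2000, seed = s)@p)
  }))
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH mask matches the textbook step-up rule", {
  expect_equal(fdrBH(c(0.001, 0.2, 0.9), 0.05), c(TRUE, FALSE, FALSE))
  expect_equal(fdrBH(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_length(fdrBH(numeric(0), 0.05), 0L)
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(fdrBH(p, q), handFdrStepUp(p, q))
  }
})

test_that("BH control holds empirically under a full null", {
  set.seed(44)
  nRep <- 1000; m <- 6000; q <- 0.05
  anyDisc <- vapply(seq_len(nRep), function(i)
    any(fdrBH(runif(m), q)), TRUE)
  # under the complete null FDR equals FWER; binomial upper bound
  expect_lte(mean(anyDisc), q + 2.58 * sqrt(q * (1 - q) / nRep))
})

test_that("effect-of-diagnosis is the group mean difference", {
  set.seed(45)
  bands <- quickBands()
  cc <- nullCohort(5, 5, bands, paste0("r", 1:4))
  D <- effectOfDiagnosis(cc)
  stack <- t(vapply(cc@sms, function(s) as.vector(s@matrix),
                    numeric(64)))
  manual <- colMeans(stack[1:5, ]) - colMeans(stack[6:10, ])
  expect_equal(as.vector(D@matrix), manual)
  # identical groups cancel exactly
  ccSame <- cohortConnectivity(cc@sms[c(1:5, 1:5)], cc@table)
  expect_true(all(abs(effectOfDiagnosis(ccSame)@matrix) < 1e-15))
  # swapping group labels negates the matrix
  tb <- cc@table
  tb$group <- rev(tb$group)
  tb$severity <- rev(tb$severity)
  ccSwap <- cohortConnectivity(cc@sms, tb)
  expect_equal(effectOfDiagnosis(ccSwap)@matrix, -D@matrix)
})

test_that("severity PCA extracts the shared factor with a fixed sign gauge", {
  set.seed(46)
  f <- rnorm(50)
  collinear <- cbind(2 * f, -0.5 * f, 3 * f)
  s <- severityPCA(collinear)
  expect_gt(abs(cor(s, f)), 1 - 1e-12)
  expect_gt(attr(s, "loadings")[1], 0)
  # isotropic noise: first component explains about a third
  iso <- matrix(rnorm(600), 200, 3)
  expect_lt(abs(attr(severityPCA(iso), "varExplained") - 1 / 3), 0.1)
  # global negation flips at most the sign of the scores
  s2 <- severityPCA(-collinear)
  expect_equal(abs(as.numeric(s2)), abs(as.numeric(s)))
  expect_error(severityPCA(cbind(f, f, rep(1, 50))), "constant")
  expect_error(severityPCA(collinear[1:2, ]), "3 patients")
})

test_that("effect-of-severity matches the analytic correlation null", {
  set.seed(47)
  bands <- quickBands()
  cc <- nullCohort(4, 23, bands, paste0("r", 1:5))
  S <- effectOfSeverity(cc)
  r <- as.vector(S@matrix)
  r <- r[r != 0]
  # under independence r*sqrt(n-2)/sqrt(1-r^2) ~ t(n-2)
  tstat <- r * sqrt(21) / sqrt(1 - r^2)
  ks <- suppressWarnings(ks.test(tstat, "pt", df = 21))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(r)), 0.1)
})

test_that("tile correlation uses each tile's unique elements", {
  bands <- quickBands()
  R <- 5
  idx <- tileIndices(bands, R)
  expect_named(idx, c("alpha", "beta", "alpha:beta"))
  expect_length(idx$alpha, R * (R - 1) / 2)
  expect_length(idx$`alpha:beta`, R * R - R)
  D <- randomSM(bands, paste0("r", 1:R))
  expect_equal(unname(tileCorrelation(D, D)), rep(1, 3))
  S <- randomSM(bands, paste0("r", 1:R))
  expect_true(all(abs(tileCorrelation(D, S)) < 0.99))
  # a shared spatial pattern planted only in the alpha tile dominates
  set.seed(48)
  hits <- 0
  for (i in 1:5) {
    D2 <- randomSM(bands, paste0("r", 1:R))
    S2 <- randomSM(bands, paste0("r", 1:R))
    pat <- matrix(runif(R * R, -0.4, 0.4), R)
    pat <- (pat + t(pat)) / 2; diag(pat) <- 0
    D2@matrix[1:R, 1:R] <- D2@matrix[1:R, 1:R] + pat
    S2@matrix[1:R, 1:R] <- S2@matrix[1:R, 1:R] + pat
    rt <- abs(tileCorrelation(D2, S2))
    if (which.max(rt) == 1L) hits <- hits + 1
  }
  expect_gte(hits, 4)
  expect_error(tileCorrelation(D@matrix, S@matrix), "band list")
})

test_that("dual-permutation tile test is calibrated under the null", {
  set.seed(49)
  bands <- quickBands()
  nSeeds <- 200
  flags <- 0; tiles <- 0
  for (s in seq_len(nSeeds)) {
    cc <- nullCohort(8, 8, bands, paste0("r", 1:5))
    res <- suppressWarnings(
      permTileCorrelation(cc, nPerm = 400, seed = s))
    flags <- flags + sum(res@p < res@alphaCorrected)
    tiles <- tiles + length(res@p)
  }
  # per-tile type-I at the corrected threshold 0.05/(2*3)
  nominal <- 0.05 / 6
  expect_lte(flags / tiles,
             nominal + 2.58 * sqrt(nominal * (1 - nominal) / tiles))
  # corrected threshold follows the band count
  cc <- nullCohort(6, 6, bands, paste0("r", 1:5))
  res <- suppressWarnings(permTileCorrelation(cc, nPerm = 200, seed = 1))
  expect_equal(res@alphaCorrected, 0.05 / (2 * 3))
  expect_equal(res@trendThreshold, 0.025)
  expect_gte(min(res@p), 1 / 201)
})

test_that("edge selection is empty at alpha = 0 and calibrated under the null", {
  set.seed(50)
  bands <- quickBands()
  cc <- nullCohort(8, 8, bands, paste0("r", 1:5))
  none <- edgeSelection(cc, "alpha", alpha = 0, nPerm = 200, seed = 1)
  expect_equal(nrow(none), 0L)
  # conjunction null: selected fraction stays near alpha^2
  alpha <- 0.1
  tot <- 0; sel <- 0
  for (s in 1:50) {
    cc <- nullCohort(8, 8, bands, paste0("r", 1:5))
    es <- edgeSelection(cc, "alpha", alpha = alpha, nPerm = 300,
                        seed = s)
    sel <- sel + nrow(es)
    tot <- tot + nrow(attr(es, "all"))
  }
  expect_lte(sel / tot, 5 * alpha^2)
})
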