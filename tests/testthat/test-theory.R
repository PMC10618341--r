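test_that("realized components are the hand-computed quadratic forms", {
  dec <- gpdDecompose(couplingPanel())   # D = [[1,1],[1,1]], same chromosome
  rc <- realizedComponents(dec, c(1, 1))
  expect_equal(rc[c("Vg", "Cw", "VA", "b")],
               list(Vg = 2, Cw = 2, VA = 4, b = 1))
  rc2 <- realizedComponents(dec, c(1, -1))
  expect_equal(rc2$VA, 0)
  expect_equal(rc2$Cw, -2)
  expect_equal(rc2$b, -1)                # lower bound attained
  rc0 <- realizedComponents(dec, c(0, 0))
  expect_equal(unlist(rc0[c("VA", "Vg", "Cw", "Cb", "C")]),
               c(VA = 0, Vg = 0, Cw = 0, Cb = 0, C = 0))
  expect_false(rc0$ratiosDefined)        # flagged, not an exception
  expect_true(is.na(rc0$b))
  expect_error(realizedComponents(dec, 1), "length")
})

test_that("V_g + C_w + C_b = V_A to machine precision for random draws", {
  for (seed in 1:4) {
    dec <- randomDecomposition(seed)
    set.seed(seed + 100)
    for (k in 1:10) {
      a <- rnorm(length(dec@p))
      rc <- realizedComponents(dec, a)
      expect_equal(rc$Vg + rc$Cw + rc$Cb, rc$VA, tolerance = 1e-12)
      expect_gte(rc$VA, -1e-12)
      if (rc$ratiosDefined) {
        expect_gte(rc$b, -1 - 1e-12)
        expect_equal(rc$b, rc$bw + rc$bb)
      }
    }
  }
})

test_that("conditional moments are the trace identities", {
  cm <- conditionalMoments(gpdDecompose(couplingPanel()))
  expect_equal(cm[c("E_VA", "var_Vg", "var_Cw", "var_VA", "var_bw", "var_bb")],
               c(E_VA = 2, var_Vg = 4, var_Cw = 4, var_VA = 8,
                 var_bw = 1, var_bb = 0))
  expect_equal(cm[["E_Cw"]], 0)
  expect_equal(cm[["E_Cb"]], 0)
  ## no between-chromosome disequilibrium -> var_Cb = var_bb = 0
  expect_equal(unname(cm[c("var_Cb", "var_bb")]), c(0, 0))
  ## diagonal D (independent loci): var_VA = var_Vg, var_b = 0
  xo <- genotypeMatrix(rbind(c(2, 2), c(2, 0), c(0, 2), c(0, 0)),
                       evenMap(1, 2))
  cmo <- conditionalMoments(gpdDecompose(xo))
  expect_equal(cmo[["var_VA"]], cmo[["var_Vg"]])
  expect_equal(cmo[["var_b"]], 0)
  ## all loci monomorphic: ratio moments undefined
  xm <- genotypeMatrix(rbind(c(2, 2), c(2, 2)), evenMap(1, 2))
  expect_true(all(is.na(conditionalMoments(gpdDecompose(xm))[
    c("var_bw", "var_bb", "var_b")])))
})

test_that("variance additivity is exact and both code paths agree", {
  for (seed in 1:5) {
    x <- randomPanel(seed)
    dec <- gpdDecompose(x)
    cm <- conditionalMoments(dec)
    expect_equal(cm[["var_VA"]],
                 cm[["var_Vg"]] + cm[["var_Cw"]] + cm[["var_Cb"]])
    expect_equal(cm[["var_b"]], cm[["var_bw"]] + cm[["var_bb"]])
    ## trace algebra: the three squared-trace terms tile trace(D^2)
    expect_equal(sum(gpdD(dec)^2),
                 sum(diag(gpdV(dec))^2) + sum(gpdW(dec)^2) + sum(gpdB(dec)^2))
    ## fast GenotypeMatrix path equals the matrix path
    expect_equal(conditionalMoments(x), cm)
  }
})

test_that("b lower bound is the smallest generalized eigenvalue, always >= -1", {
  expect_equal(bLowerBound(gpdDecompose(couplingPanel())), -1)  # D singular
  xo <- genotypeMatrix(rbind(c(2, 2), c(2, 0), c(0, 2), c(0, 0)),
                       evenMap(1, 2))
  expect_equal(bLowerBound(gpdDecompose(xo)), 0)                # D diagonal
  for (seed in 1:3) {
    dec <- randomDecomposition(seed, nLines = 12)
    bmin <- bLowerBound(dec)
    expect_gte(bmin, -1)
    expect_lte(bmin, 0)
    ## brute-force oracle: random unit vectors never undercut the bound
    set.seed(seed)
    L <- length(dec@p)
    A <- matrix(rnorm(2e4 * L), ncol = L)
    num <- rowSums((A %*% (gpdW(dec) + gpdB(dec))) * A)
    den <- rowSums((A %*% gpdV(dec)) * A)
    expect_gte(min(num / den), bmin - 1e-3)
  }
  xm <- genotypeMatrix(rbind(c(2, 2), c(2, 2)), evenMap(1, 2))
  expect_error(bLowerBound(gpdDecompose(xm)), "no polymorphic")
})

test_that("Monte-Carlo moments converge to the trace identities", {
  ## diagonal D: mean of V_A within 4 SE of trace(D)
  xo <- genotypeMatrix(rbind(c(2, 2), c(2, 0), c(0, 2), c(0, 0)),
                       evenMap(1, 2))
  deco <- gpdDecompose(xo)
  mc <- monteCarloMoments(deco, nSamples = 10000, seed = 11)
  se <- sqrt(mc["VA", "var"] / mc["VA", "n"])
  expect_lt(abs(mc["VA", "mean"] - sum(diag(gpdD(deco)))), 4 * se)
  ## coupling fixture: var of V_A within 10% of the theoretical 8
  dec <- gpdDecompose(couplingPanel())
  mc2 <- monteCarloMoments(dec, nSamples = 10000, seed = 12)
  expect_lt(abs(mc2["VA", "var"] - 8) / 8, 0.10)
  ## many coupled pairs give positively skewed C | X (a single pair is the
  ## symmetric product 2 a1 a2, so the skew needs >= 2 disequilibrium pairs)
  x4 <- genotypeMatrix(rbind(rep(2, 4), rep(0, 4)), evenMap(1, 4))
  mc4 <- monteCarloMoments(gpdDecompose(x4), nSamples = 10000, seed = 13)
  expect_gt(mc4["C", "skewness"], 0)
  expect_gt(mc4["VA", "skewness"], 0)
  ## reproducible under a fixed seed
  expect_identical(monteCarloMoments(dec, 500, seed = 7),
                   monteCarloMoments(dec, 500, seed = 7))
  expect_error(monteCarloMoments(dec, nSamples = 10), "at least 100")
})

test_that("P[C < 0 | X] reflects the sign asymmetry of QTL covariances", {
  ## a single disequilibrium pair: sign of a_i a_j is symmetric -> prob 0.5
  dec1 <- gpdDecompose(couplingPanel())
  p1 <- signAsymmetryProbability(dec1, nSamples = 20000, seed = 5)
  expect_lt(abs(p1$prob - 0.5), 4 * p1$se)
  ## >= 4 loci in all-positive coupling: P[C < 0] > 0.5
  map4 <- evenMap(1, 4)
  x4 <- genotypeMatrix(rbind(rep(2, 4), rep(0, 4)), map4)
  p4 <- signAsymmetryProbability(gpdDecompose(x4), nSamples = 20000, seed = 6)
  expect_gt(p4$prob - 4 * p4$se, 0.5)
  ## diagonal D: C is identically zero, probability degenerate
  xo <- genotypeMatrix(rbind(c(2, 2), c(2, 0), c(0, 2), c(0, 0)),
                       evenMap(1, 2))
  pd <- signAsymmetryProbability(gpdDecompose(xo), nSamples = 1000, seed = 7)
  expect_true(pd$degenerate)
  expect_true(is.na(pd$prob))
})

test_that("b_b can fall below -1 when b_w exceeds 1, while b stays >= -1", {
  dec <- gpdDecompose(coupledRepulsedPanel())
  ## effects aligned with the coupled block, strong opposite effect on the
  ## repulsed chromosome-2 locus
  rc <- realizedComponents(dec, c(1, 1, 1, sqrt(3)))
  expect_gte(rc$bw, 1)
  expect_lt(rc$bb, -1)
  expect_gte(rc$b, -1 - 1e-12)
  ## and some standard-normal draw reproduces it
  set.seed(21)
  draws <- gpdVA:::.componentsMany(dec, matrix(rnorm(4000), ncol = 4))
  hit <- !is.na(draws$bb) & draws$bb < -1
  expect_gt(sum(hit), 0)
  expect_true(all(draws$b[!is.na(draws$b)] >= -1 - 1e-9))
})
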