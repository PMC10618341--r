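test_that("meiosis reproduces Haldane recombination fractions", {
  ## F1 of two inbreds differing everywhere: haplotype origin is readable
  ## straight off the gamete alleles
  map <- geneticMap(c("m1", "m2", "m3"), c("1", "1", "2"), c(0, 50, 0))
  founders <- biparentalFounders(map)
  f1 <- sampleProgeny(founders, designCrosses(c("A", "B"), "DC"), 1, seed = 1)
  g <- meiosis(f1, rep(1L, 10000), seed = 2)
  ## same position (d = 0): alleles always co-inherited
  map0 <- geneticMap(c("a", "b"), c("1", "1"), c(25, 25))
  f10 <- sampleProgeny(biparentalFounders(map0),
                       designCrosses(c("A", "B"), "DC"), 1, seed = 1)
  g0 <- meiosis(f10, rep(1L, 2000), seed = 3)
  expect_true(all(g0[, 1] == g0[, 2]))
  ## d = 50 cM: r = (1 - exp(-1))/2 ~ 0.31606, inside the exact binomial
  ## 99% interval over 10,000 meioses
  rec12 <- sum(g[, 1] != g[, 2])
  expect_true(all(rec12 >= binomRange(10000, haldane(50))[1],
                  rec12 <= binomRange(10000, haldane(50))[2]))
  ## different chromosomes: fraction 0.5
  rec13 <- sum(g[, 1] != g[, 3])
  expect_true(all(rec13 >= binomRange(10000, 0.5)[1],
                  rec13 <= binomRange(10000, 0.5)[2]))
})

test_that("the Markov walk composes Haldane fractions with no interference", {
  ## loci at 0, 20, 30 cM: r13 must equal r12 + r23 - 2 r12 r23 = haldane(30)
  map <- geneticMap(c("m1", "m2", "m3"), c("1", "1", "1"), c(0, 20, 30))
  f1 <- sampleProgeny(biparentalFounders(map),
                      designCrosses(c("A", "B"), "DC"), 1, seed = 4)
  g <- meiosis(f1, rep(1L, 20000), seed = 5)
  rec13 <- sum(g[, 1] != g[, 3])
  expect_true(all(rec13 >= binomRange(20000, haldane(30))[1],
                  rec13 <= binomRange(20000, haldane(30))[2]))
})

test_that("DH derivation doubles one gamete", {
  map <- evenMap(2, 5, 10)
  founders <- biparentalFounders(map)
  ## DH of a fully homozygous parent is a clone of that parent
  dhF <- makeDH(founders, seed = 6)
  expect_true(isDH(dhF))
  expect_equal(dhF@hapA, founders@hapA, ignore_attr = TRUE)
  ## DH of an F1: each locus from parent A or B with probability 1/2
  f1 <- sampleProgeny(founders, designCrosses(c("A", "B"), "DC"), 500,
                      seed = 7)
  dh <- makeDH(f1, seed = 8)
  expect_true(isDH(dh))
  x <- asGenotypeMatrix(dh)
  expect_true(all(scores(x) %in% c(0, 2)))
  cnt <- colSums(scores(x) == 2)
  rng <- binomRange(500, 0.5, conf = 1 - 0.01 / nLoci(x))  # Bonferroni
  expect_true(all(cnt >= rng[1] & cnt <= rng[2]))
})

test_that("biparental DH disequilibrium matches the 1 - 2r closed form", {
  ## coupling-phase pair at r = 0.25 <-> d ~ 34.66 cM: E[d_ij] = 0.5;
  ## gamete-frequency oracle f_AB = (1 - r)/2 in d_ij = 4 (f_ij - p_i p_j)
  d <- -50 * log(1 - 2 * 0.25)
  map <- geneticMap(c("m1", "m2"), c("1", "1"), c(0, d))
  f1 <- sampleProgeny(biparentalFounders(map),
                      designCrosses(c("A", "B"), "DC"), 1, seed = 9)
  set.seed(10)
  dij <- replicate(40, {
    dh <- asGenotypeMatrix(makeDH(sampleProgeny(biparentalFounders(map),
      designCrosses(c("A", "B"), "DC"), 200)))
    gpdD(gpdDecompose(dh))[1, 2]
  })
  expect_lt(abs(mean(dij) - 0.5), 3 * sd(dij) / sqrt(length(dij)))
})

test_that("cross plans follow the design combinatorics", {
  p4 <- paste0("P", 1:4)
  expect_equal(nrow(designCrosses(p4, "DC", seed = 1)@crosses), 2)
  expect_equal(nrow(designCrosses(p4, "FC", seed = 1)@crosses), 4)
  expect_equal(nrow(designCrosses(p4, "HC")@crosses), 6)
  expect_equal(nrow(designCrosses(paste0("P", 1:16), "HC")@crosses), 120)
  ## each parent used exactly once in DC
  dc <- designCrosses(p4, "DC", seed = 2)@crosses
  expect_setequal(c(dc$mother, dc$father), p4)
  ## P = 2: a single cross under every design
  for (dsn in c("DC", "FC", "HC"))
    expect_equal(nrow(designCrosses(c("A", "B"), dsn, seed = 3)@crosses), 1)
  expect_error(designCrosses(paste0("P", 1:3), "DC"), "even")
  expect_error(designCrosses("P1", "HC"), "at least two")
})

test_that("progeny sampling is uniform over crosses with replacement", {
  map <- evenMap(1, 2, 10)
  set.seed(11)
  panel <- genotypeMatrix(2 * (matrix(runif(8), 4) > 0.5), map, paste0("P", 1:4))
  founders <- founderPopulation(panel)
  plan <- designCrosses(paste0("P", 1:4), "HC")
  g1 <- sampleProgeny(founders, plan, 6000, seed = 12)
  expect_equal(nIndividuals(g1), 6000)
  tab <- table(paste(pedigree(g1)$mother, pedigree(g1)$father))
  se <- sqrt(6000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(tab - 1000) <= 3 * se))
  ## single-cross plan: all pedigree records point to the same cross, and
  ## with homozygous parents all N F1s are genetically identical
  plan2 <- designCrosses(c("P1", "P2"), "DC")
  g2 <- sampleProgeny(founders, plan2, 50, seed = 13)
  expect_setequal(unique(paste(pedigree(g2)$mother, pedigree(g2)$father)),
                  paste(plan2@crosses$mother, plan2@crosses$father))
  expect_equal(nrow(unique(cbind(g2@hapA, g2@hapB))), 1)
})

test_that("random mating excludes selfing and conserves allele frequency", {
  map <- evenMap(2, 3, 15)
  spec <- founderSpec(nLines = 40, nChromosomes = 2,
                      chromLengths = c(60, 60), nLoci = 6,
                      monoFraction = 0, poolSize = 8)
  panel <- synthAncestral(spec, seed = 14, calibrate = FALSE)$panel
  g1 <- sampleProgeny(founderPopulation(panel),
                      designCrosses(rownames(scores(panel))[1:8], "HC"),
                      10000, seed = 15)
  g2 <- randomMate(g1, seed = 16)
  expect_false(any(pedigree(g2)$mother == pedigree(g2)$father))
  p1 <- colMeans(g1@hapA + g1@hapB) / 2
  p2 <- colMeans(g2@hapA + g2@hapB) / 2
  tol <- 3 * sqrt(pmax(p1 * (1 - p1), 1e-9) / (2 * 10000))
  expect_true(all(abs(p2 - p1) <= 3 * tol))
  single <- sampleProgeny(founderPopulation(panel),
                          designCrosses(rownames(scores(panel))[1:2], "DC"),
                          1, seed = 17)
  expect_error(randomMate(single), "at least 2")
})

test_that("one replication wires designs, generations and DH together", {
  spec <- founderSpec(nLines = 20, nChromosomes = 2, chromLengths = c(80, 80),
                      nLoci = 40, monoFraction = 0.1, poolSize = 8)
  panel <- synthAncestral(spec, seed = 17, calibrate = FALSE)$panel
  repl <- runReplication(panel, "FC", P = 4, N = 60, generations = 2,
                         seed = 18)
  expect_named(repl$dh, c("G1-DH", "G2-DH"))
  expect_equal(nrow(scores(repl$dh[["G1-DH"]])), 60)
  expect_true(all(vapply(repl$dh, function(x) all(scores(x) %in% c(0, 2)),
                         TRUE)))
  ## seeded determinism: identical seed -> identical generation set
  repl2 <- runReplication(panel, "FC", P = 4, N = 60, generations = 2,
                          seed = 18)
  expect_identical(lapply(repl$dh, scores), lapply(repl2$dh, scores))
  ## P = 2: loci fixed in both parents stay fixed in every DH line
  repl3 <- runReplication(panel, "DC", P = 2, N = 50, generations = 1,
                          seed = 19)
  par <- scores(panel)[match(repl3$parents, rownames(scores(panel))), ]
  fixed <- which(par[1, ] == par[2, ])
  dhsc <- scores(repl3$dh[["G1-DH"]])
  expect_true(all(dhsc[, fixed] == rep(par[1, fixed], each = nrow(dhsc))))
  expect_error(runReplication(panel, "HC", P = 40, N = 10), "exceeds")
})

test_that("G1-DH genic variance matches the frequency bookkeeping oracle", {
  ## For a fixed parent set and plan, a DH line picks cross k uniformly and
  ## then an allele Bernoulli(p_k) per locus (p_k = mean parental dose).
  ## E[trace(V)] = sum_i 4 (pbar(1 - pbar) - (E_k[p_k(1-p_k)] + Var_k(p_k))/N)
  spec <- founderSpec(nLines = 30, nChromosomes = 2, chromLengths = c(70, 70),
                      nLoci = 100, monoFraction = 0, poolSize = 10)
  panel <- synthAncestral(spec, seed = 20, calibrate = FALSE)$panel
  parents <- sampleParents(panel, 4, seed = 21)
  founders <- founderPopulation(panel[match(parents, rownames(scores(panel))), ])
  plan <- designCrosses(parents, "FC", seed = 22)
  pk <- apply(plan@crosses, 1, function(cr) {
    (scores(panel)[cr["mother"], ] + scores(panel)[cr["father"], ]) / 4
  })  # L x K matrix of per-cross DH allele frequencies
  N <- 1000
  pbar <- rowMeans(pk)
  within <- rowMeans(pk * (1 - pk))
  between <- rowMeans(sweep(pk, 1, pbar)^2)
  expectedTrace <- sum(4 * (pbar * (1 - pbar) - (within + between) / N))
  set.seed(23)
  tr <- replicate(30, {
    dh <- asGenotypeMatrix(makeDH(sampleProgeny(founders, plan, N)))
    sum(diag(gpdV(gpdDecompose(dh))))
  })
  expect_lt(abs(mean(tr) - expectedTrace), 3 * sd(tr) / sqrt(length(tr)))
})
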