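## Fixtures are built in code; no data files.

## evenly spaced map: `lociPerChrom` loci per chromosome, spacing `step` cM
evenMap <- function(nChrom = 1, lociPerChrom = 2, step = 10) {
  chrom <- rep(as.character(seq_len(nChrom)), each = lociPerChrom)
  pos <- rep(seq(0, by = step, length.out = lociPerChrom), nChrom)
  geneticMap(paste0("m", seq_along(chrom)), chrom, pos)
}

## two perfectly coupled lines: D = [[1, 1], [1, 1]]
couplingPanel <- function(map = evenMap(1, 2)) {
  genotypeMatrix(rbind(c(2, 2), c(0, 0)), map)
}

## two perfectly repulsed lines: D = [[1, -1], [-1, 1]]
repulsionPanel <- function(map = evenMap(1, 2)) {
  genotypeMatrix(rbind(c(2, 0), c(0, 2)), map)
}

## random homozygous panel over a multi-chromosome map
randomPanel <- function(seed, nLines = 30, nChrom = 2, lociPerChrom = 10,
                        step = 8) {
  set.seed(seed)
  map <- evenMap(nChrom, lociPerChrom, step)
  L <- nChrom * lociPerChrom
  p <- stats::runif(L, 0.1, 0.9)
  sc <- 2 * (matrix(stats::runif(nLines * L), nLines) <
               matrix(p, nLines, L, byrow = TRUE))
  genotypeMatrix(sc, map)
}

randomDecomposition <- function(seed, ...) gpdDecompose(randomPanel(seed, ...))

## two homozygous parents differing at all loci, as a Population
biparentalFounders <- function(map) {
  L <- nrow(loci(map))
  panel <- genotypeMatrix(rbind(rep(2, L), rep(0, L)), map, c("A", "B"))
  founderPopulation(panel)
}

## fixture where b_w > 1 is attainable and therefore b_b can drop below -1:
## three perfectly coupled loci on chromosome 1, one perfectly repulsed locus
## on chromosome 2 (two line types only)
coupledRepulsedPanel <- function() {
  map <- geneticMap(paste0("m", 1:4), c("1", "1", "1", "2"),
                    c(0, 5, 10, 0))
  genotypeMatrix(rbind(c(2, 2, 2, 0), c(0, 0, 0, 2),
                       c(2, 2, 2, 0), c(0, 0, 0, 2)), map)
}

## exact two-sided binomial range [lo, hi] covering prob `conf`
binomRange <- function(n, p, conf = 0.99) {
  a <- (1 - conf) / 2
  c(stats::qbinom(a, n, p), stats::qbinom(1 - a, n, p))
}
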