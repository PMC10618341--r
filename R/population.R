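#' Founder population from a panel of homozygous lines
#'
#' Turns a 0/2 [GenotypeMatrix] into a phased [Population]: both haplotypes of
#' each founder are identical (fully inbred material).
#'
#' @param x a [GenotypeMatrix].
#' @param generation label for the pedigree (default \code{"founder"}).
#' @return a [Population].
#' @export
founderPopulation <- function(x, generation = "founder") {
  hap <- x@scores / 2
  storage.mode(hap) <- "integer"
  ids <- rownames(x@scores)
  new("Population", hapA = hap, hapB = hap, map = x@map,
      pedigree = data.frame(id = ids, mother = NA_character_,
                            father = NA_character_),
      generation = generation)
}

#' @rdname founderPopulation
#' @param pop a Population
#' @export
nIndividuals <- function(pop) nrow(pop@hapA)

#' @rdname founderPopulation
#' @export
pedigree <- function(pop) pop@pedigree

#' @rdname founderPopulation
#' @export
isDH <- function(pop) all(pop@hapA == pop@hapB)

#' @export
setMethod("show", "Population", function(object) {
  cat(sprintf("Population '%s': %d individuals x %d loci%s\n",
              object@generation, nrow(object@hapA), ncol(object@hapA),
              if (isDH(object)) " (fully homozygous)" else ""))
})

#' Genotypic scores of a fully homozygous population
#'
#' @param pop a [Population] with identical haplotype pairs (DH or inbred).
#' @return a [GenotypeMatrix] with 0/2 scores at all mapped loci.
#' @export
asGenotypeMatrix <- function(pop) {
  if (!isDH(pop))
    stop("population is not fully homozygous; derive DH lines first")
  genotypeMatrix(2 * pop@hapA, pop@map, pop@pedigree$id)
}

## Meiosis engine.  Gametes are generated chromosome-by-chromosome as a
## Markov walk over the ordered loci: the walk starts on a random parental
## haplotype and switches haplotypes between adjacent loci with the Haldane
## probability r = (1 - exp(-2d/100))/2.  With no interference this
## per-interval chain is exactly equivalent to a Poisson crossover process,
## and chromosomes assort independently because chromosome-first loci switch
## with probability 1/2.  `parentIdx` may repeat; one gamete per entry.
.gametes <- function(pop, parentIdx) {
  M <- length(parentIdx)
  L <- ncol(pop@hapA)
  rvec <- .recombVector(pop@map)
  A <- pop@hapA[parentIdx, , drop = FALSE]
  B <- pop@hapB[parentIdx, , drop = FALSE]
  switch_ <- matrix(stats::runif(M * L), M, L) <
    matrix(rvec, M, L, byrow = TRUE)
  ## cumulative parity of switches = which haplotype the walk sits on
  G <- matrix(0L, M, L)
  state <- integer(M)
  for (l in seq_len(L)) {
    state <- (state + switch_[, l]) %% 2L
    col <- A[, l]
    onB <- state == 1L
    col[onB] <- B[onB, l]
    G[, l] <- col
  }
  G
}

#' Simulate meiosis gametes
#'
#' One recombinant gamete per requested parent, under Haldane's mapping
#' function (no crossover interference); chromosomes assort independently.
#'
#' @param pop a [Population].
#' @param parents integer indices (repetition allowed) or character ids of
#'   the parents; one gamete is produced per entry.
#' @param seed optional integer seed.
#' @return integer matrix (one row per gamete) of 0/1 reference-allele codes.
#' @export
meiosis <- function(pop, parents, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(parents)) {
    idx <- match(parents, pop@pedigree$id)
    if (anyNA(idx)) stop("unknown parent id(s)")
    parents <- idx
  }
  stopifnot(all(parents >= 1 & parents <= nrow(pop@hapA)))
  .gametes(pop, as.integer(parents))
}

#' Derive doubled-haploid lines
#'
#' Takes exactly one meiosis gamete from each individual and doubles it into a
#' fully homozygous individual, yielding the DH generation of the population.
#'
#' @param pop a [Population] of N individuals.
#' @param seed optional integer seed.
#' @return a [Population] of N DH individuals labelled
#'   \code{"<generation>-DH"}.
#' @export
makeDH <- function(pop, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- .gametes(pop, seq_len(nrow(pop@hapA)))
  ids <- paste0(pop@pedigree$id, "_DH")
  new("Population", hapA = g, hapB = g, map = pop@map,
      pedigree = data.frame(id = ids, mother = pop@pedigree$id,
                            father = pop@pedigree$id),
      generation = paste0(pop@generation, "-DH"))
}

#' Build the cross list of a mating design
#'
#' \describe{
#'   \item{DC}{disjoint crosses: the parents are put in random order and
#'     crossed consecutively, giving P/2 crosses with every parent used once.}
#'   \item{FC}{factorial: the parents are randomly split into two equal sets
#'     and all (P/2)^2 between-set crosses are made.}
#'   \item{HC}{half-diallel: all P(P-1)/2 unordered pairs, no selfs.}
#' }
#' P = 2 gives the single biparental cross under every design.
#'
#' @param parentIds character vector of parent ids (P >= 2; P even for DC and
#'   FC).
#' @param design \code{"DC"}, \code{"FC"} or \code{"HC"}.
#' @param seed optional integer seed (randomizes the DC ordering / FC split).
#' @return a [CrossPlan].
#' @examples
#' nrow(designCrosses(letters[1:4], "HC")@crosses)  # 6
#' @export
designCrosses <- function(parentIds, design = c("DC", "FC", "HC"),
                          seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)
  P <- length(parentIds)
  if (P < 2) stop("at least two parents are required")
  if (design %in% c("DC", "FC") && P %% 2 != 0)
    stop(design, " design requires an even number of parents")
  crosses <- switch(design,
    DC = {
      ord <- sample(parentIds)
      data.frame(mother = ord[seq(1, P, by = 2)],
                 father = ord[seq(2, P, by = 2)])
    },
    FC = {
      ord <- sample(parentIds)
      s1 <- ord[seq_len(P / 2)]
      s2 <- ord[-seq_len(P / 2)]
      expand.grid(mother = s1, father = s2, stringsAsFactors = FALSE,
                  KEEP.OUT.ATTRS = FALSE)
    },
    HC = {
      idx <- utils::combn(P, 2)
      data.frame(mother = parentIds[idx[1L, ]], father = parentIds[idx[2L, ]])
    })
  new("CrossPlan", design = design, parents = as.character(parentIds),
      crosses = crosses)
}

#' Sample the F1 generation G1 from a cross plan
#'
#' Each of the N progenies independently draws its cross uniformly at random
#' with replacement from the plan, then receives one meiosis gamete from each
#' parent of that cross.  For fully homozygous parents every F1 of a cross is
#' the same fixed heterozygote, so with P = 2 generation G1 consists of N
#' genetically identical F1 genotypes.
#'
#' @param pop a [Population] containing (at least) the plan's parents.
#' @param plan a [CrossPlan].
#' @param N number of progenies.
#' @param seed optional integer seed.
#' @return a [Population] labelled \code{"G1"}.
#' @export
sampleProgeny <- function(pop, plan, N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (N < 1) stop("N must be at least 1")
  if (nrow(plan@crosses) == 0) stop("empty cross plan")
  k <- sample.int(nrow(plan@crosses), N, replace = TRUE)
  mother <- plan@crosses$mother[k]
  father <- plan@crosses$father[k]
  mi <- match(mother, pop@pedigree$id)
  fi <- match(father, pop@pedigree$id)
  if (anyNA(mi) || anyNA(fi))
    stop("cross plan refers to parents absent from the population")
  gm <- .gametes(pop, mi)
  gf <- .gametes(pop, fi)
  new("Population", hapA = gm, hapB = gf, map = pop@map,
      pedigree = data.frame(id = sprintf("G1_%d", seq_len(N)),
                            mother = mother, father = father),
      generation = "G1")
}

#' One generation of random mating (no selfing)
#'
#' Each of the N offspring independently draws an unordered pair of two
#' distinct parents uniformly at random (monoecious model without selfing)
#' and receives one meiosis gamete from each.
#'
#' @param pop a [Population] of size >= 2.
#' @param N number of offspring (default: size of \code{pop}).
#' @param seed optional integer seed.
#' @param generation label for the offspring (default increments a trailing
#'   \code{G<k>} in the parent label).
#' @return a [Population].
#' @export
randomMate <- function(pop, N = nIndividuals(pop), seed = NULL,
                       generation = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n0 <- nrow(pop@hapA)
  if (n0 < 2) stop("random mating requires at least 2 individuals")
  first <- sample.int(n0, N, replace = TRUE)
  second <- sample.int(n0 - 1L, N, replace = TRUE)
  second <- second + (second >= first)   # uniform over distinct pairs
  gm <- .gametes(pop, first)
  gf <- .gametes(pop, second)
  if (is.null(generation)) {
    k <- suppressWarnings(as.integer(sub("^G(\\d+).*$", "\\1",
                                         pop@generation)))
    generation <- if (is.na(k)) paste0(pop@generation, "+1")
                  else paste0("G", k + 1L)
  }
  new("Population", hapA = gm, hapB = gf, map = pop@map,
      pedigree = data.frame(id = sprintf("%s_%d", generation, seq_len(N)),
                            mother = pop@pedigree$id[first],
                            father = pop@pedigree$id[second]),
      generation = generation)
}

#' Run one replication of the breeding scheme
#'
#' Samples P parents without replacement from the founder panel, crosses them
#' according to the mating design to produce generation G1 of size N, chains
#' random mating to G2..G<generations>, and derives one DH line from each of
#' the N individuals of every generation (G1-DH..G<generations>-DH).
#'
#' @param panel founder [GenotypeMatrix] (fully homozygous lines).
#' @param design \code{"DC"}, \code{"FC"} or \code{"HC"}.
#' @param P number of parents to sample from the panel.
#' @param N population size of G1 and of every intermating generation.
#' @param generations number of generations (>= 1); generation k is Gk.
#' @param seed optional integer seed for the whole replication.
#' @return list with elements \code{parents} (ids), \code{plan}
#'   ([CrossPlan]), \code{generations} (list of [Population] G1..Gk) and
#'   \code{dh} (named list of 0/2 [GenotypeMatrix], one per DH generation).
#' @export
runReplication <- function(panel, design, P, N, generations = 4,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (P > nrow(panel@scores))
    stop("P exceeds the number of founder lines")
  parents <- sample(rownames(panel@scores), P)
  founders <- founderPopulation(panel[match(parents, rownames(panel@scores)), ])
  plan <- designCrosses(parents, design)
  gens <- vector("list", generations)
  gens[[1L]] <- sampleProgeny(founders, plan, N)
  if (generations > 1)
    for (k in 2:generations) gens[[k]] <- randomMate(gens[[k - 1L]], N)
  names(gens) <- paste0("G", seq_len(generations))
  dh <- lapply(gens, function(g) asGenotypeMatrix(makeDH(g)))
  names(dh) <- paste0(names(gens), "-DH")
  list(parents = parents, plan = plan, generations = gens, dh = dh)
}
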