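#' @import methods
NULL

#' GeneticMap: chromosome lengths and locus positions in centimorgan
#'
#' A \code{GeneticMap} ties an ordered set of loci to chromosomes with genetic
#' lengths in centimorgan (cM).  Positions are continuous floating-point cM
#' coordinates; no physical (base-pair) coordinates are used anywhere in the
#' package.
#'
#' @slot chromosomes data.frame with columns \code{chrom} (character, unique)
#'   and \code{length} (cM, positive).
#' @slot loci data.frame with columns \code{marker} (character, unique),
#'   \code{chrom} (character, present in \code{chromosomes}) and \code{pos}
#'   (cM in \code{[0, length]}), sorted by (chromosome, position).
#'
#' @seealso [geneticMap()] for the user-facing constructor,
#'   [readGeneticMap()] for TSV input.
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(chromosomes = "data.frame", loci = "data.frame"))

setValidity("GeneticMap", function(object) {
  ch <- object@chromosomes
  lo <- object@loci
  msg <- character()
  if (!all(c("chrom", "length") %in% names(ch)))
    msg <- c(msg, "chromosomes must have columns 'chrom' and 'length'")
  if (!all(c("marker", "chrom", "pos") %in% names(lo)))
    msg <- c(msg, "loci must have columns 'marker', 'chrom' and 'pos'")
  if (length(msg)) return(msg)
  if (anyDuplicated(ch$chrom))
    msg <- c(msg, "chromosome ids must be unique")
  if (any(ch$length <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (anyDuplicated(lo$marker))
    msg <- c(msg, "marker ids must be unique")
  if (!all(lo$chrom %in% ch$chrom))
    msg <- c(msg, "every locus chromosome must appear in the chromosome table")
  len <- ch$length[match(lo$chrom, ch$chrom)]
  if (any(lo$pos < 0 | lo$pos > len, na.rm = TRUE))
    msg <- c(msg, "locus positions must lie in [0, chromosome length]")
  ## sorted by (chromosome in table order, position)
  ord <- order(match(lo$chrom, ch$chrom), lo$pos)
  if (is.unsorted(ord))
    msg <- c(msg, "loci must be sorted by (chromosome, position)")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: homozygous genotypic scores tied to a genetic map
#'
#' N x L matrix of genotypic scores of fully homozygous material (inbred or
#' doubled-haploid lines): entry 2 if the line is homozygous for the reference
#' allele at the locus, 0 otherwise.  Heterozygous material is not supported.
#' Columns are aligned to the loci of a [GeneticMap].
#'
#' @slot scores numeric N x L matrix with entries in \{0, 2\}; rownames are
#'   individual ids, colnames the marker ids of the map.
#' @slot map the [GeneticMap] the columns refer to.
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(scores = "matrix", map = "GeneticMap"))

setValidity("GenotypeMatrix", function(object) {
  sc <- object@scores
  msg <- character()
  if (!is.numeric(sc))
    return("scores must be a numeric matrix")
  if (ncol(sc) != nrow(object@map@loci))
    msg <- c(msg, sprintf("scores has %d columns but the map has %d loci",
                          ncol(sc), nrow(object@map@loci)))
  bad <- which(!(sc == 0 | sc == 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1L, ]
    msg <- c(msg, sprintf(
      "homozygous coding violated: entry [%s, %s] is %s, expected 0 or 2",
      rownames(sc)[b[1L]] %||% b[1L],
      colnames(sc)[b[2L]] %||% b[2L], sc[b[1L], b[2L]]))
  }
  if (!is.null(colnames(sc)) &&
      !identical(colnames(sc), object@map@loci$marker))
    msg <- c(msg, "column names must equal the map's marker ids")
  if (length(msg)) msg else TRUE
})

#' GpdDecomposition: D = V + W + B partition of the genotypic covariance
#'
#' Variance-covariance matrix \eqn{D = Z'Z/N} of centered genotypic scores,
#' partitioned entrywise into its diagonal \eqn{V} (single-locus variances
#' \eqn{d_{ii} = 4 p_i (1 - p_i)}), the within-chromosome off-diagonal part
#' \eqn{W}, and the between-chromosome part \eqn{B}.  Off-diagonal entries
#' \eqn{d_{ij} = 4 (f_{ij} - p_i p_j)} carry the gametic phase disequilibrium
#' (GPD) between loci i and j.  Monomorphic loci are retained as zero
#' rows/columns so locus indexing is stable across generations.
#'
#' @slot D,V,W,B symmetric L x L matrices with \code{D == V + W + B};
#'   \code{V} diagonal, \code{W} and \code{B} zero-diagonal.
#' @slot p length-L vector of reference-allele frequencies.
#' @slot map the [GeneticMap] used for the within/between partition.
#'
#' @exportClass GpdDecomposition
setClass("GpdDecomposition",
  representation(D = "matrix", V = "matrix", W = "matrix", B = "matrix",
                 p = "numeric", map = "GeneticMap"))

setValidity("GpdDecomposition", function(object) {
  L <- length(object@p)
  msg <- character()
  for (nm in c("D", "V", "W", "B")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(L, L)))
      msg <- c(msg, sprintf("%s must be %d x %d", nm, L, L))
  }
  if (length(msg)) return(msg)
  tol <- 1e-8 * max(1, sum(diag(object@D)))
  if (max(abs(object@D - t(object@D))) > tol)
    msg <- c(msg, "D must be symmetric")
  if (max(abs(object@D - (object@V + object@W + object@B))) > tol)
    msg <- c(msg, "D must equal V + W + B entrywise")
  if (any(object@V[row(object@V) != col(object@V)] != 0))
    msg <- c(msg, "V must be diagonal")
  if (any(diag(object@W) != 0) || any(diag(object@B) != 0))
    msg <- c(msg, "W and B must have zero diagonals")
  if (max(abs(diag(object@D) - 4 * object@p * (1 - object@p))) > tol)
    msg <- c(msg, "diag(D) must equal 4 p (1 - p)")
  if (length(msg)) msg else TRUE
})

#' CrossPlan: parent pairs of a mating design
#'
#' @slot design one of \code{"DC"} (disjoint crosses), \code{"FC"} (factorial)
#'   or \code{"HC"} (half-diallel).
#' @slot parents character vector of parent ids entering the design.
#' @slot crosses data.frame with columns \code{mother} and \code{father}.
#'
#' @exportClass CrossPlan
setClass("CrossPlan",
  representation(design = "character", parents = "character",
                 crosses = "data.frame"))

setValidity("CrossPlan", function(object) {
  P <- length(object@parents)
  K <- nrow(object@crosses)
  msg <- character()
  if (!object@design %in% c("DC", "FC", "HC"))
    msg <- c(msg, "design must be one of 'DC', 'FC', 'HC'")
  if (!all(c("mother", "father") %in% names(object@crosses)))
    msg <- c(msg, "crosses must have columns 'mother' and 'father'")
  else {
    if (any(object@crosses$mother == object@crosses$father))
      msg <- c(msg, "selfs are not allowed in any design")
    expected <- switch(object@design,
      DC = P / 2, FC = if (P == 2) 1 else (P / 2)^2, HC = P * (P - 1) / 2)
    if (length(expected) && K != expected)
      msg <- c(msg, sprintf("%s design with %d parents must have %g crosses, got %d",
                            object@design, P, expected, K))
  }
  if (length(msg)) msg else TRUE
})

#' Population: phased diploid individuals aligned to a genetic map
#'
#' Working container of the breeding simulator.  Each individual carries two
#' haplotypes over the mapped loci, coded 1 for the reference allele and 0 for
#' the alternate.  Doubled-haploid (DH) individuals have identical haplotype
#' pairs.
#'
#' @slot hapA,hapB integer N x L matrices in \{0, 1\}.
#' @slot map the [GeneticMap].
#' @slot pedigree data.frame with columns \code{id}, \code{mother},
#'   \code{father} (NA for founders).
#' @slot generation label such as \code{"G1"} or \code{"G2-DH"}.
#'
#' @exportClass Population
setClass("Population",
  representation(hapA = "matrix", hapB = "matrix", map = "GeneticMap",
                 pedigree = "data.frame", generation = "character"))

setValidity("Population", function(object) {
  msg <- character()
  if (!identical(dim(object@hapA), dim(object@hapB)))
    msg <- c(msg, "hapA and hapB must have identical dimensions")
  if (ncol(object@hapA) != nrow(object@map@loci))
    msg <- c(msg, "haplotype columns must match the map's loci")
  if (!all(object@hapA %in% c(0L, 1L)) || !all(object@hapB %in% c(0L, 1L)))
    msg <- c(msg, "haplotype entries must be 0 or 1")
  if (nrow(object@pedigree) != nrow(object@hapA))
    msg <- c(msg, "pedigree must have one row per individual")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
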