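#' Genotypic variance-covariance matrix D
#'
#' \eqn{D = Z'Z / N} with divisor N (the population formulation, which makes
#' \eqn{E[V_A | X] = trace(D)} exact).  Diagonal entries are
#' \eqn{d_{ii} = 4 p_i (1 - p_i)} and off-diagonals
#' \eqn{d_{ij} = 4 (f_{ij} - p_i p_j)}, four times the gametic phase
#' disequilibrium for fully homozygous material.
#'
#' @param z centered score matrix from [centerScores()].
#' @param n number of lines the centering was computed from (default
#'   \code{nrow(z)}).
#' @return symmetric L x L numeric matrix.
#' @export
gpdMatrix <- function(z, n = nrow(z)) {
  if (n < 1) stop("n must be positive")
  crossprod(z) / n
}

#' Partition D into diagonal, within- and between-chromosome parts
#'
#' Splits \code{D} entrywise into \eqn{V = diag(D)}, \eqn{W} (off-diagonal
#' entries of same-chromosome locus pairs) and \eqn{B} (different-chromosome
#' pairs).  W and B are kept as full symmetric matrices, so sums over "pairs"
#' count (i,j) and (j,i) separately and the quadratic form \eqn{a'Wa} carries
#' the factor 2 of the covariance component automatically.
#'
#' @param D symmetric L x L matrix from [gpdMatrix()].
#' @param map a [GeneticMap] with exactly L loci assigning each locus to one
#'   chromosome.
#' @param p allele frequencies consistent with \code{diag(D)}.
#' @return a [GpdDecomposition].
#' @export
gpdPartition <- function(D, map, p) {
  L <- nrow(map@loci)
  if (!all(dim(D) == L))
    stop(sprintf("D is %d x %d but the map has %d loci", nrow(D), ncol(D), L))
  ci <- .chromIndex(map)
  V <- diag(diag(D), nrow = L)
  same <- outer(ci, ci, `==`)
  W <- ifelse(same, D, 0)
  diag(W) <- 0
  B <- ifelse(same, 0, D)
  dimnames(V) <- dimnames(W) <- dimnames(B) <- dimnames(D)
  new("GpdDecomposition", D = D, V = V, W = W, B = B, p = as.numeric(p),
      map = map)
}

#' Disequilibrium decomposition of a genotype matrix
#'
#' Convenience wrapper: allele frequencies, centering, \eqn{D = Z'Z/N} and the
#' within/between-chromosome partition in one step.
#'
#' @param x a [GenotypeMatrix].
#' @return a [GpdDecomposition].
#' @examples
#' gm <- geneticMap(c("m1", "m2"), c("1", "1"), c(0, 10))
#' x <- genotypeMatrix(rbind(c(2, 2), c(0, 0)), gm)
#' gpdDecompose(x)  # perfect coupling: D = [[1, 1], [1, 1]]
#' @export
gpdDecompose <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  p <- alleleFrequencies(x)
  z <- centerScores(x, p)
  gpdPartition(gpdMatrix(z, nrow(z)), x@map, p)
}

#' @rdname gpdDecompose
#' @param dec a GpdDecomposition
#' @export
gpdD <- function(dec) dec@D
#' @rdname gpdDecompose
#' @export
gpdV <- function(dec) dec@V
#' @rdname gpdDecompose
#' @export
gpdW <- function(dec) dec@W
#' @rdname gpdDecompose
#' @export
gpdB <- function(dec) dec@B

#' @export
setMethod("show", "GpdDecomposition", function(object) {
  cat(sprintf("GpdDecomposition: %d loci on %d chromosome(s)\n",
              length(object@p), nrow(object@map@chromosomes)))
  cat(sprintf("  trace(V) = %.4g, 2 trace(W^2) = %.4g, 2 trace(B^2) = %.4g\n",
              sum(diag(object@V)), 2 * sum(object@W^2), 2 * sum(object@B^2)))
})

#' Pairwise within-chromosome linkage disequilibrium r^2
#'
#' \eqn{r^2_{ij} = d_{ij}^2 / (d_{ii} d_{jj})} for all pairs of polymorphic
#' loci on the same chromosome.  On fully homozygous lines this equals the
#' haplotype-based r^2.  Pairs involving a monomorphic locus are skipped; the
#' number skipped is attached as attribute \code{"n_skipped"}.
#'
#' @param x a [GenotypeMatrix].
#' @return data.frame with columns \code{locus1}, \code{locus2}, \code{chrom},
#'   \code{dist} (cM) and \code{r2}.
#' @export
pairwiseR2 <- function(x) {
  dec <- gpdDecompose(x)
  ci <- .chromIndex(x@map)
  pos <- x@map@loci$pos
  mk <- x@map@loci$marker
  dii <- diag(dec@D)
  poly <- dii > 0
  out <- vector("list", nrow(x@map@chromosomes))
  nSkipped <- 0L
  for (cc in seq_along(out)) {
    idxAll <- which(ci == cc)
    idx <- idxAll[poly[idxAll]]
    nSkipped <- nSkipped +
      (length(idxAll) * (length(idxAll) - 1L) -
         length(idx) * (length(idx) - 1L)) / 2L
    if (length(idx) < 2) next
    Dc <- dec@D[idx, idx, drop = FALSE]
    dc <- dii[idx]
    r2 <- Dc^2 / outer(dc, dc)
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    out[[cc]] <- data.frame(
      locus1 = mk[idx[ut[, 1L]]], locus2 = mk[idx[ut[, 2L]]],
      chrom = x@map@chromosomes$chrom[cc],
      dist = abs(pos[idx[ut[, 2L]]] - pos[idx[ut[, 1L]]]),
      r2 = r2[ut])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(locus1 = character(), locus2 = character(),
                      chrom = character(), dist = numeric(), r2 = numeric())
  attr(res, "n_skipped") <- as.integer(nSkipped)
  res
}

#' LD decay distance from binned mean r^2
#'
#' Bins pairwise r^2 records by map distance and returns the midpoint of the
#' first bin whose mean r^2 falls below the threshold.  Used to calibrate
#' synthetic founder panels; the binned-threshold rule (default 1 cM bins) is
#' a documented package choice.
#'
#' @param r2records data.frame from [pairwiseR2()].
#' @param threshold r^2 threshold in (0, 1), default 0.1.
#' @param binWidth bin width in cM.
#' @return decay distance in cM (bin midpoint), or \code{Inf} if mean r^2
#'   never falls below the threshold ("beyond map").
#' @export
ldDecayDistance <- function(r2records, threshold = 0.1, binWidth = 1) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (nrow(r2records) == 0) stop("no r2 records")
  bin <- floor(r2records$dist / binWidth)
  means <- tapply(r2records$r2, bin, mean)
  bins <- as.numeric(names(means))
  ## scan bins in distance order; empty bins are simply absent
  ord <- order(bins)
  below <- means[ord] < threshold
  if (!any(below)) return(Inf)
  (bins[ord][which(below)[1L]] + 0.5) * binWidth
}
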