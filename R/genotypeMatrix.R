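#' Construct a genotype matrix of fully homozygous lines
#'
#' @param scores numeric N x L matrix with entries in \{0, 2\}: 2 = homozygous
#'   for the reference allele, 0 = homozygous alternate.
#' @param map a [GeneticMap] whose loci correspond to the columns.
#' @param ids optional individual ids (default \code{L1..LN}).
#' @return a [GenotypeMatrix].
#' @export
genotypeMatrix <- function(scores, map, ids = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0 || ncol(scores) == 0)
    stop("genotype matrix must be nonempty")
  storage.mode(scores) <- "double"
  rownames(scores) <- ids %||% rownames(scores) %||%
    paste0("L", seq_len(nrow(scores)))
  colnames(scores) <- map@loci$marker
  new("GenotypeMatrix", scores = scores, map = map)
}

#' @rdname genotypeMatrix
#' @param x a GenotypeMatrix
#' @export
scores <- function(x) {
  stopifnot(is(x, "GenotypeMatrix"))
  x@scores
}

#' Subset lines and/or loci of a GenotypeMatrix
#'
#' @param x a [GenotypeMatrix].
#' @param i line (row) index.
#' @param j locus (column) index, kept in map order.
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypeMatrix.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@scores))
  if (missing(j)) j <- seq_len(ncol(x@scores))
  map <- subsetMap(x@map, j)
  sc <- x@scores[i, match(map@loci$marker, colnames(x@scores)), drop = FALSE]
  new("GenotypeMatrix", scores = sc, map = map)
})

#' @export
setMethod("show", "GenotypeMatrix", function(object) {
  p <- alleleFrequencies(object)
  cat(sprintf("GenotypeMatrix: %d homozygous lines x %d loci (%d chromosome(s))\n",
              nrow(object@scores), ncol(object@scores),
              nrow(object@map@chromosomes)))
  cat(sprintf("  monomorphic loci: %d (%.1f%%)\n",
              sum(p == 0 | p == 1), 100 * mean(p == 0 | p == 1)))
})

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@scores))

#' Reference-allele frequencies of a population sample
#'
#' \eqn{p_i = \sum_n x_{ni} / (2N)}, the frequency of the reference allele at
#' each locus, computed exactly from the 0/2 scores.
#'
#' @param x a [GenotypeMatrix] (or bare numeric matrix with entries in
#'   \{0, 2\}).
#' @return named numeric vector of length L with values in \code{[0, 1]}.
#' @examples
#' gm <- geneticMap("m1", "1", 0)
#' alleleFrequencies(genotypeMatrix(rbind(2, 0), gm))  # 0.5
#' @export
alleleFrequencies <- function(x) {
  sc <- if (is(x, "GenotypeMatrix")) x@scores else as.matrix(x)
  if (nrow(sc) == 0 || ncol(sc) == 0)
    stop("cannot compute allele frequencies of an empty matrix")
  bad <- which(!(sc == 0 | sc == 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("score [%s, %s] = %s is not a homozygous 0/2 code",
                 bad[1, 1], bad[1, 2], sc[bad[1, 1], bad[1, 2]]))
  colSums(sc) / (2 * nrow(sc))
}

#' Center genotypic scores with allele frequencies
#'
#' \eqn{Z = X - 2 \mathbf{1} p}.  When \code{p} was computed from \code{x},
#' every column of Z sums to zero and monomorphic loci give zero columns.
#'
#' @param x a [GenotypeMatrix] or numeric matrix.
#' @param p allele frequencies (default: computed from \code{x}).
#' @return numeric N x L matrix of centered scores.
#' @export
centerScores <- function(x, p = alleleFrequencies(x)) {
  sc <- if (is(x, "GenotypeMatrix")) x@scores else as.matrix(x)
  if (length(p) != ncol(sc))
    stop(sprintf("length(p) = %d does not match %d loci", length(p), ncol(sc)))
  sweep(sc, 2L, 2 * p, `-`)
}

#' Read a 0/2 genotype matrix from TSV
#'
#' Format: header row of marker ids, first column the individual id, entries
#' 0 or 2.  Every marker must be present in \code{map}; columns are reordered
#' to map order.
#'
#' @param path file path (plain or gzip).
#' @param map a [GeneticMap] covering all markers in the file.
#' @return a [GenotypeMatrix].
#' @export
readGenotypeMatrix <- function(path, map) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1L]])
  sc <- as.matrix(tab[, -1L, drop = FALSE])
  markers <- colnames(sc)
  idx <- match(markers, map@loci$marker)
  if (anyNA(idx))
    stop("marker(s) absent from the map: ",
         paste(utils::head(markers[is.na(idx)], 5), collapse = ", "))
  sub <- subsetMap(map, sort(idx))
  genotypeMatrix(sc[, match(sub@loci$marker, markers), drop = FALSE], sub, ids)
}

#' Write a genotype matrix to TSV
#'
#' @param x a [GenotypeMatrix].
#' @param path output path; a \code{.gz} suffix writes a gzip stream (the
#'   portable compressed container used between modules).
#' @export
writeGenotypeMatrix <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  tab <- data.frame(id = rownames(x@scores), x@scores, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read homozygous genotypes from a VCF file
#'
#' Only fully homozygous calls are accepted: \code{0/0} (or \code{0|0}) is
#' scored 2 (reference) and \code{1/1} is scored 0.  A heterozygous or missing
#' call is an error naming the locus and line.  The VCF ID column supplies the
#' marker ids matched against the map.
#'
#' @param path VCF path (vcfR handles plain and bgzipped files).
#' @param map a [GeneticMap] covering all VCF markers.
#' @return a [GenotypeMatrix].
#' @export
readGenotypeVCF <- function(path, map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  sc <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
               dimnames = list(colnames(gt), rownames(gt)))
  sc[] <- t(ifelse(gt == "0/0", 2, ifelse(gt == "1/1", 0, NA)))
  if (anyNA(sc)) {
    bad <- which(is.na(sc), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-homozygous or missing call at locus '%s', line '%s'",
                 colnames(sc)[bad[2L]], rownames(sc)[bad[1L]]))
  }
  idx <- match(colnames(sc), map@loci$marker)
  if (anyNA(idx))
    stop("VCF marker(s) absent from the map: ",
         paste(utils::head(colnames(sc)[is.na(idx)], 5), collapse = ", "))
  sub <- subsetMap(map, sort(idx))
  genotypeMatrix(sc[, match(sub@loci$marker, colnames(sc)), drop = FALSE],
                 sub, rownames(sc))
}
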