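#' Construct a genetic map
#'
#' @param marker character vector of marker ids.
#' @param chrom chromosome id per marker.
#' @param pos genetic position per marker in cM.
#' @param chromLengths optional named vector of chromosome lengths in cM; if
#'   missing, each chromosome's length is the maximum observed position.
#' @return a [GeneticMap] with loci sorted by (chromosome, position).
#' @examples
#' gm <- geneticMap(c("m1", "m2", "m3"), c("1", "1", "2"), c(10, 55, 5))
#' @export
geneticMap <- function(marker, chrom, pos, chromLengths = NULL) {
  chrom <- as.character(chrom)
  marker <- as.character(marker)
  stopifnot(length(marker) == length(chrom), length(chrom) == length(pos))
  chromIds <- unique(chrom)
  if (is.null(chromLengths)) {
    ## inferred length: last mapped position, floored at 1 cM so chromosomes
    ## carrying a single locus at 0 keep a positive length
    chromLengths <- vapply(chromIds,
                           function(cc) max(pos[chrom == cc], 1), 0)
  } else {
    if (is.null(names(chromLengths))) names(chromLengths) <- chromIds
    missing <- setdiff(chromIds, names(chromLengths))
    if (length(missing))
      stop("no length given for chromosome(s): ", paste(missing, collapse = ", "))
    chromLengths <- chromLengths[chromIds]
  }
  ord <- order(match(chrom, chromIds), pos)
  new("GeneticMap",
      chromosomes = data.frame(chrom = chromIds,
                               length = unname(as.numeric(chromLengths))),
      loci = data.frame(marker = marker[ord], chrom = chrom[ord],
                        pos = as.numeric(pos[ord])))
}

#' @describeIn geneticMap number of mapped loci
#' @param x,object a GeneticMap
#' @export
nLoci <- function(x) {
  if (is(x, "GeneticMap")) nrow(x@loci)
  else if (is(x, "GenotypeMatrix")) nrow(x@map@loci)
  else if (is(x, "Population")) ncol(x@hapA)
  else stop("no loci for class ", class(x))
}

#' @rdname geneticMap
#' @export
chromosomes <- function(x) {
  if (is(x, "GeneticMap")) x@chromosomes else geneticMapOf(x)@chromosomes
}

#' @rdname geneticMap
#' @export
loci <- function(x) {
  if (is(x, "GeneticMap")) x@loci else geneticMapOf(x)@loci
}

#' @rdname geneticMap
#' @export
geneticMapOf <- function(x) {
  if (is(x, "GeneticMap")) x
  else if (is(x, "GenotypeMatrix") || is(x, "Population") ||
           is(x, "GpdDecomposition")) x@map
  else stop("no genetic map for class ", class(x))
}

## integer chromosome index per locus, in map order
.chromIndex <- function(map) {
  match(map@loci$chrom, map@chromosomes$chrom)
}

## per-locus Haldane recombination probability with the previous locus;
## chromosome-first loci get 0.5 so chromosomes assort independently and the
## starting parental haplotype is uniform.
.recombVector <- function(map) {
  ci <- .chromIndex(map)
  pos <- map@loci$pos
  d <- c(Inf, diff(pos))
  d[c(TRUE, diff(ci) != 0)] <- Inf
  ifelse(is.infinite(d), 0.5, haldane(d))
}

#' Haldane's mapping function
#'
#' Recombination fraction between two loci at map distance \code{d} cM under
#' no crossover interference: \eqn{r = (1 - e^{-2d/100}) / 2}.
#'
#' @param d map distance in cM (vectorized).
#' @return recombination fraction in \code{[0, 0.5)}.
#' @examples
#' haldane(50)   # ~0.3161
#' @export
haldane <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * (1 - exp(-2 * d / 100))
}

#' Subset a genetic map to a set of loci
#'
#' @param map a [GeneticMap].
#' @param i integer or logical index, or character marker ids, in map order.
#' @return the subset [GeneticMap]; the chromosome table is kept intact.
#' @export
subsetMap <- function(map, i) {
  lo <- map@loci
  if (is.character(i)) i <- match(i, lo$marker)
  if (is.logical(i)) i <- which(i)
  if (anyNA(i) || any(i < 1 | i > nrow(lo)))
    stop("locus index out of range or marker missing from map")
  i <- sort(unique(as.integer(i)))
  keep <- unique(lo$chrom[i])
  new("GeneticMap",
      chromosomes = map@chromosomes[map@chromosomes$chrom %in% keep, ,
                                    drop = FALSE],
      loci = lo[i, , drop = FALSE])
}

#' Read a genetic map from TSV
#'
#' Expects a header with columns \code{marker_id}, \code{chromosome},
#' \code{position_cM}.
#'
#' @param path file path.
#' @param chromLengths optional named lengths in cM (defaults to max position
#'   per chromosome).
#' @return a [GeneticMap].
#' @export
readGeneticMap <- function(path, chromLengths = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric"))
  need <- c("marker_id", "chromosome", "position_cM")
  if (!all(need %in% names(tab)))
    stop("map file must have header columns: ", paste(need, collapse = ", "))
  geneticMap(tab$marker_id, tab$chromosome, tab$position_cM, chromLengths)
}

#' Write a genetic map to TSV
#'
#' @param map a [GeneticMap].
#' @param path output path; a \code{.gz} suffix writes a gzip stream.
#' @export
writeGeneticMap <- function(map, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  tab <- data.frame(marker_id = map@loci$marker, chromosome = map@loci$chrom,
                    position_cM = map@loci$pos)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d loci on %d chromosome(s), %.1f cM total\n",
              nrow(object@loci), nrow(object@chromosomes),
              sum(object@chromosomes$length)))
})
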