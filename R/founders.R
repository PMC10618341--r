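#' Specification of a synthetic ancestral panel
#'
#' Describes the statistical structure of a panel of fully homozygous founder
#' lines: panel size, chromosome structure, allele-frequency spectrum,
#' monomorphic-in-panel fraction, and the target LD decay distance (the
#' distance at which binned mean r^2 first falls below 0.1).  These are the
#' properties that drive everything downstream; individual marker identities
#' of any real panel are deliberately not reproduced.
#'
#' @param nLines number of inbred lines (default 115).
#' @param nChromosomes number of chromosomes (default 10).
#' @param chromLengths chromosome lengths in cM; default a maize-like
#'   decreasing profile scaled to 1442 cM total.
#' @param nLoci total number of loci (apportioned to chromosomes by length).
#' @param freqRange range of the uniform allele-frequency spectrum for
#'   polymorphic loci (default \code{c(0.02, 0.98)}).
#' @param monoFraction fraction of loci monomorphic in the panel.
#' @param targetDecay target LD decay distance in cM at r^2 = 0.1.
#' @param poolSize number of founder haplotypes in the ancestral pool;
#'   controls background relatedness (small pools give coarse frequency
#'   spectra and long-range background LD).
#' @param segmentLength mean length (cM) of the exponential donor segments of
#'   the line mosaics; default twice the target decay distance.
#' @return object of class \code{FounderSpec}.
#' @seealso [presetFounderSpec()] for the named elite-like / landrace-like
#'   presets, [synthAncestral()] for the generator.
#' @export
founderSpec <- function(nLines = 115, nChromosomes = 10, chromLengths = NULL,
                        nLoci = 2500, freqRange = c(0.02, 0.98),
                        monoFraction = 0.05, targetDecay = 21,
                        poolSize = 24, segmentLength = NULL) {
  if (is.null(chromLengths)) {
    w <- seq(1.35, 0.75, length.out = nChromosomes)
    chromLengths <- 1442 * w / sum(w)
  }
  stopifnot(length(chromLengths) == nChromosomes, all(chromLengths > 0),
            monoFraction >= 0, monoFraction <= 1, nLines >= 2,
            poolSize >= 2, targetDecay > 0, nLoci >= nChromosomes)
  spec <- list(nLines = nLines, nChromosomes = nChromosomes,
               chromLengths = as.numeric(chromLengths), nLoci = nLoci,
               freqRange = freqRange, monoFraction = monoFraction,
               targetDecay = targetDecay, poolSize = poolSize,
               segmentLength = segmentLength %||% 2 * targetDecay)
  class(spec) <- "FounderSpec"
  spec
}

#' @rdname founderSpec
#' @param name \code{"elite"} (monomorphic fraction 0.049, decay 22.2 cM) or
#'   \code{"landrace"} (0.163, 21.3 cM).
#' @param ... overrides passed on to [founderSpec()].
#' @export
presetFounderSpec <- function(name = c("elite", "landrace"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    elite = list(monoFraction = 0.049, targetDecay = 22.2),
    landrace = list(monoFraction = 0.163, targetDecay = 21.3))
  do.call(founderSpec, utils::modifyList(args, list(...)))
}

#' @export
print.FounderSpec <- function(x, ...) {
  cat(sprintf(paste0("FounderSpec: %d lines, %d chromosomes (%.0f cM), ",
                     "%d loci\n  monomorphic fraction %.3f, ",
                     "target decay %.1f cM, pool size %d\n"),
              x$nLines, x$nChromosomes, sum(x$chromLengths), x$nLoci,
              x$monoFraction, x$targetDecay, x$poolSize))
  invisible(x)
}

## largest-remainder apportionment of `total` items by weight
.apportion <- function(weights, total) {
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## map with loci placed uniformly on each chromosome, counts by length
.randomMap <- function(spec) {
  counts <- .apportion(spec$chromLengths, spec$nLoci)
  chrom <- rep(as.character(seq_len(spec$nChromosomes)), counts)
  pos <- unlist(lapply(seq_len(spec$nChromosomes), function(cc)
    sort(stats::runif(counts[cc], 0, spec$chromLengths[cc]))))
  geneticMap(paste0("s", seq_along(chrom)), chrom, pos,
             stats::setNames(spec$chromLengths,
                             as.character(seq_len(spec$nChromosomes))))
}

## Pool haplotypes: per chromosome an AR(1) latent Gaussian with correlation
## exp(-d/rho) between adjacent loci, thresholded at qnorm(q) so the marginal
## allele frequency at locus i is q_i while alleles decay in association with
## map distance.  Loci intended polymorphic but fixed in the realized pool get
## one haplotype flipped (minimal distortion of the spectrum).
.genPool <- function(map, q, rho, H) {
  L <- length(q)
  ci <- .chromIndex(map)
  phi <- exp(-pmax(c(Inf, diff(map@loci$pos)), 0) / rho)
  phi[c(TRUE, diff(ci) != 0)] <- 0
  G <- matrix(0, H, L)
  state <- stats::rnorm(H)
  for (l in seq_len(L)) {
    state <- phi[l] * state + sqrt(1 - phi[l]^2) * stats::rnorm(H)
    G[, l] <- state
  }
  pool <- (G < matrix(stats::qnorm(q), H, L, byrow = TRUE)) + 0L
  intendedPoly <- q > 0 & q < 1
  fixed <- which(intendedPoly & (colSums(pool) %in% c(0L, H)))
  if (length(fixed)) {
    flip <- sample.int(H, length(fixed), replace = TRUE)
    pool[cbind(flip, fixed)] <- 1L - pool[cbind(flip, fixed)]
  }
  pool
}

## Lines as recombinant mosaics of the pool haplotypes: donor identity is a
## Markov chain along each chromosome with exponential segment lengths (mean
## segLen cM); at a boundary the new donor is uniform over the pool.
.genMosaic <- function(map, pool, segLen, nLines) {
  L <- ncol(pool)
  H <- nrow(pool)
  ci <- .chromIndex(map)
  pSwitch <- 1 - exp(-pmax(c(Inf, diff(map@loci$pos)), 0) / segLen)
  pSwitch[c(TRUE, diff(ci) != 0)] <- 1
  sc <- matrix(0, nLines, L)
  donor <- sample.int(H, nLines, replace = TRUE)
  for (l in seq_len(L)) {
    sw <- stats::runif(nLines) < pSwitch[l]
    if (any(sw)) donor[sw] <- sample.int(H, sum(sw), replace = TRUE)
    sc[, l] <- pool[donor, l]
  }
  2 * sc
}

.realizedDecay <- function(panel, binWidth = 1) {
  ldDecayDistance(pairwiseR2(panel), threshold = 0.1, binWidth = binWidth)
}

#' Generate a synthetic ancestral panel
#'
#' Builds a panel of fully homozygous founder lines whose statistical
#' structure follows a [founderSpec()]: a small pool of ancestral haplotypes
#' carries distance-decaying allelic association (latent AR(1) Gaussian
#' copula with scale \code{rho}), each line is a recombinant mosaic of pool
#' haplotypes with exponential segment lengths, and \code{rho} is calibrated
#' by bisection so the realized LD decay distance (binned r^2 rule,
#' [ldDecayDistance()]) approximates `spec$targetDecay`.  This generator is a
#' synthetic stand-in: it matches panel size, chromosome structure, frequency
#' spectrum, monomorphic fraction and LD scale, nothing marker-specific.
#'
#' @param spec a [founderSpec()].
#' @param seed optional integer seed.
#' @param calibrate logical; skip the bisection and use \code{rho =
#'   targetDecay} when \code{FALSE} (faster, coarser).
#' @return list with elements \code{panel} (a [GenotypeMatrix]), \code{map},
#'   and \code{calibration} (rho, realized decay distance, realized
#'   monomorphic fraction, target).
#' @export
synthAncestral <- function(spec, seed = NULL, calibrate = TRUE) {
  stopifnot(inherits(spec, "FounderSpec"))
  if (!is.null(seed)) set.seed(seed)
  if (spec$targetDecay >= max(spec$chromLengths)) {
    warning("target decay distance exceeds the longest chromosome; ",
            "best-effort calibration")
    calibrate <- FALSE
  }
  map <- .randomMap(spec)
  q <- .drawFrequencies(spec)
  rho <- spec$targetDecay
  if (calibrate) {
    calSeed <- sample.int(2^30, 1)
    sub <- if (spec$nLoci > 600)
      sort(sample.int(spec$nLoci, 600)) else seq_len(spec$nLoci)
    subMap <- subsetMap(map, sub)
    ## bisect on the mean r^2 in a +-3 cM window around the target distance:
    ## the binned decay distance crosses the 0.1 threshold there when the
    ## window mean equals the threshold, but the window mean is a much
    ## smoother function of rho (common random numbers across evaluations)
    evalR2 <- function(r) {
      set.seed(calSeed)
      pool <- .genPool(subMap, q[sub], r, spec$poolSize)
      sc <- .genMosaic(subMap, pool, spec$segmentLength, spec$nLines)
      rec <- pairwiseR2(genotypeMatrix(sc, subMap))
      win <- abs(rec$dist - spec$targetDecay) <= 3
      if (!any(win)) NA_real_ else mean(rec$r2[win])
    }
    lo <- 1; hi <- 400
    if (isTRUE(evalR2(hi) < 0.1)) {
      warning("target decay distance not reachable; using maximal rho")
      rho <- hi
    } else if (isTRUE(evalR2(lo) > 0.1)) {
      rho <- lo
    } else {
      for (it in 1:10) {
        mid <- exp((log(lo) + log(hi)) / 2)
        if (isTRUE(evalR2(mid) < 0.1)) lo <- mid else hi <- mid
      }
      rho <- exp((log(lo) + log(hi)) / 2)
    }
    set.seed(calSeed + 1L)
  }
  pool <- .genPool(map, q, rho, spec$poolSize)
  sc <- .genMosaic(map, pool, spec$segmentLength, spec$nLines)
  panel <- genotypeMatrix(sc, map, paste0("F", seq_len(spec$nLines)))
  p <- alleleFrequencies(panel)
  list(panel = panel, map = map,
       calibration = list(rho = rho,
                          realizedDecay = .realizedDecay(panel),
                          realizedMonoFraction = mean(p == 0 | p == 1),
                          targetDecay = spec$targetDecay))
}

.drawFrequencies <- function(spec) {
  L <- spec$nLoci
  mono <- stats::runif(L) < spec$monoFraction
  q <- stats::runif(L, spec$freqRange[1L], spec$freqRange[2L])
  q[mono] <- sample(c(0, 1), sum(mono), replace = TRUE)
  q
}

#' Sample QTL positions proportional to chromosome length
#'
#' Apportions L QTL to chromosomes proportionally to their genetic length
#' (largest-remainder rounding) and samples uniformly without replacement
#' from the candidate pool within each chromosome.
#'
#' @param map a [GeneticMap].
#' @param L number of QTL.
#' @param pool candidate locus indices (default: all mapped loci).
#' @param seed optional integer seed.
#' @return sorted integer vector of L locus indices; per-chromosome counts
#'   are attached as attribute \code{"perChrom"}.
#' @export
sampleQtl <- function(map, L, pool = seq_len(nrow(map@loci)), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(pool) < L) stop("candidate pool smaller than L")
  counts <- .apportion(map@chromosomes$length, L)
  ci <- .chromIndex(map)
  picked <- integer(0)
  for (cc in seq_along(counts)) {
    cand <- pool[ci[pool] == cc]
    if (length(cand) < counts[cc])
      stop(sprintf("chromosome %s: pool has %d candidate loci, %d required",
                   map@chromosomes$chrom[cc], length(cand), counts[cc]))
    picked <- c(picked, if (counts[cc] > 0)
      cand[sample.int(length(cand), counts[cc])] else integer(0))
  }
  out <- sort(picked)
  attr(out, "perChrom") <- stats::setNames(counts, map@chromosomes$chrom)
  out
}

#' Sample parental lines from a panel
#'
#' Uniform sample without replacement of P line ids.
#'
#' @param panel a [GenotypeMatrix].
#' @param P number of parents.
#' @param seed optional integer seed.
#' @return character vector of P distinct line ids.
#' @export
sampleParents <- function(panel, P, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(panel@scores)
  if (P > length(ids)) stop("P exceeds the panel size")
  sample(ids, P)
}
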