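#' Realized variance components for one effect vector
#'
#' Quadratic forms of the QTL substitution effects against the disequilibrium
#' decomposition: \eqn{V_A = a'Da}, \eqn{V_g = a'Va}, \eqn{C_w = a'Wa},
#' \eqn{C_b = a'Ba}, with \eqn{V_A = V_g + C_w + C_b} holding to machine
#' precision.  The standardized ratios \eqn{b_w = C_w / V_g},
#' \eqn{b_b = C_b / V_g}, \eqn{b = b_w + b_b} are returned as \code{NA} with
#' \code{ratiosDefined = FALSE} when \eqn{V_g = 0} (all sampled QTL
#' monomorphic), so aggregation across replications can skip them.
#'
#' @param dec a [GpdDecomposition].
#' @param a numeric effect vector of length L.
#' @return named list with elements \code{VA}, \code{Vg}, \code{Cw},
#'   \code{Cb}, \code{C}, \code{bw}, \code{bb}, \code{b},
#'   \code{ratiosDefined}.
#' @examples
#' gm <- geneticMap(c("m1", "m2"), c("1", "1"), c(0, 10))
#' dec <- gpdDecompose(genotypeMatrix(rbind(c(2, 2), c(0, 0)), gm))
#' realizedComponents(dec, c(1, 1))   # VA = 4, Vg = 2, b = 1
#' realizedComponents(dec, c(1, -1))  # VA = 0, b = -1 (bound attained)
#' @export
realizedComponents <- function(dec, a) {
  if (length(a) != length(dec@p))
    stop(sprintf("effect vector has length %d, expected %d",
                 length(a), length(dec@p)))
  if (!all(is.finite(a))) stop("effect vector must be finite")
  Vg <- sum(diag(dec@V) * a^2)
  Cw <- drop(crossprod(a, dec@W %*% a))
  Cb <- drop(crossprod(a, dec@B %*% a))
  VA <- Vg + Cw + Cb
  defined <- Vg > 0
  list(VA = VA, Vg = Vg, Cw = Cw, Cb = Cb, C = Cw + Cb,
       bw = if (defined) Cw / Vg else NA_real_,
       bb = if (defined) Cb / Vg else NA_real_,
       b = if (defined) (Cw + Cb) / Vg else NA_real_,
       ratiosDefined = defined)
}

## realized components for many effect vectors at once; A is nDraws x L.
## Cw is accumulated chromosome-block-wise to avoid forming A %*% W.
.componentsMany <- function(dec, A) {
  dii <- diag(dec@V)
  ci <- .chromIndex(dec@map)
  Vg <- drop(A^2 %*% dii)
  VA <- rowSums((A %*% dec@D) * A)
  within <- numeric(nrow(A))
  for (cc in unique(ci)) {
    idx <- which(ci == cc)
    Ac <- A[, idx, drop = FALSE]
    within <- within + rowSums((Ac %*% dec@D[idx, idx, drop = FALSE]) * Ac)
  }
  Cw <- within - Vg
  Cb <- VA - within
  data.frame(VA = VA, Vg = Vg, Cw = Cw, Cb = Cb, C = Cw + Cb,
             bw = ifelse(Vg > 0, Cw / Vg, NA_real_),
             bb = ifelse(Vg > 0, Cb / Vg, NA_real_),
             b = ifelse(Vg > 0, (Cw + Cb) / Vg, NA_real_))
}

#' Conditional moments of the variance components given X
#'
#' For QTL effects \eqn{a \sim N(0, I)}, the components are Gaussian quadratic
#' forms and their conditional moments are exact trace identities:
#' \deqn{E[V_g|X] = E[V_A|X] = trace(V), \quad E[C_w|X] = E[C_b|X] = 0}
#' \deqn{var[V_g|X] = 2 trace(V^2), \; var[C_w|X] = 2 trace(W^2), \;
#'       var[C_b|X] = 2 trace(B^2)}
#' \deqn{var[V_A|X] = 2 trace(D^2) = var[V_g|X] + var[C_w|X] + var[C_b|X]}
#' (the pairwise covariances vanish because \eqn{trace(VW) = trace(VB) =
#' trace(WB) = 0} in this partition).  The moments of the standardized ratios
#' are first-order (delta-method) approximations:
#' \deqn{E[b_w|X] \approx 0, \quad var[b_w|X] \approx 2 trace(W^2)/trace(V)^2}
#' and analogously for \eqn{b_b} and \eqn{b}.  When \eqn{trace(V) = 0} the
#' ratio moments are \code{NA}.
#'
#' @param x a [GpdDecomposition] or [GenotypeMatrix] (for a GenotypeMatrix a
#'   fast path avoids building the full W/B matrices).
#' @return named numeric vector with elements \code{E_Vg}, \code{E_Cw},
#'   \code{E_Cb}, \code{E_VA}, \code{var_Vg}, \code{var_Cw}, \code{var_Cb},
#'   \code{var_C}, \code{var_VA}, \code{E_bw}, \code{E_bb}, \code{E_b},
#'   \code{var_bw}, \code{var_bb}, \code{var_b}.
#' @export
setGeneric("conditionalMoments", function(x) standardGeneric("conditionalMoments"))

#' @rdname conditionalMoments
#' @export
setMethod("conditionalMoments", "GpdDecomposition", function(x) {
  .momentsFromTraces(trV = sum(diag(x@V)), trV2 = sum(diag(x@V)^2),
                     trW2 = sum(x@W^2), trB2 = sum(x@B^2))
})

#' @rdname conditionalMoments
#' @export
setMethod("conditionalMoments", "GenotypeMatrix", function(x) {
  p <- alleleFrequencies(x)
  z <- centerScores(x, p)
  D <- crossprod(z) / nrow(z)
  .tracesToMoments(D, .chromIndex(x@map))
})

## trace bookkeeping shared by both methods: trW2 via per-chromosome blocks,
## trB2 as the Frobenius remainder.
.tracesToMoments <- function(D, ci) {
  dii <- diag(D)
  trD2 <- sum(D^2)
  within <- 0
  for (cc in unique(ci)) {
    idx <- which(ci == cc)
    within <- within + sum(D[idx, idx]^2)
  }
  .momentsFromTraces(trV = sum(dii), trV2 = sum(dii^2),
                     trW2 = within - sum(dii^2), trB2 = trD2 - within)
}

.momentsFromTraces <- function(trV, trV2, trW2, trB2) {
  ratios <- if (trV > 0) {
    c(E_bw = 0, E_bb = 0, E_b = 0,
      var_bw = 2 * trW2 / trV^2, var_bb = 2 * trB2 / trV^2,
      var_b = 2 * (trW2 + trB2) / trV^2)
  } else {
    c(E_bw = NA_real_, E_bb = NA_real_, E_b = NA_real_,
      var_bw = NA_real_, var_bb = NA_real_, var_b = NA_real_)
  }
  c(E_Vg = trV, E_Cw = 0, E_Cb = 0, E_VA = trV,
    var_Vg = 2 * trV2, var_Cw = 2 * trW2, var_Cb = 2 * trB2,
    var_C = 2 * (trW2 + trB2), var_VA = 2 * (trV2 + trW2 + trB2),
    ratios)
}

#' Minimum attainable standardized disequilibrium ratio b
#'
#' The infimum over nonzero effect vectors of \eqn{b = a'(W + B)a / a'Va},
#' computed as the smallest eigenvalue of
#' \eqn{V^{-1/2} (D - V) V^{-1/2}} on the subspace of polymorphic loci.
#' Because D is positive semidefinite the bound is always \eqn{\ge -1};
#' equality holds iff D is singular on that subspace.
#'
#' @param dec a [GpdDecomposition].
#' @return the lower bound for b (a number in \code{[-1, 0]}).
#' @export
bLowerBound <- function(dec) {
  dii <- diag(dec@V)
  poly <- which(dii > 0)
  if (length(poly) == 0) stop("no polymorphic loci: bound undefined")
  s <- 1 / sqrt(dii[poly])
  M <- (dec@D - dec@V)[poly, poly, drop = FALSE] * outer(s, s)
  lam <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  ## floating-point guard: clip eigenvalues a hair below -1
  if (lam < -1 && lam > -1 - 1e-9) lam <- -1
  lam
}

#' Monte-Carlo moments of the realized components
#'
#' Draws \code{nSamples} effect vectors (default i.i.d. standard normal, the
#' distribution all theory in this package assumes), computes the realized
#' components for each, and summarizes their empirical mean, variance,
#' skewness and kurtosis.  Shape statistics are the standardized third and
#' fourth central moments without small-sample bias correction.
#'
#' @param dec a [GpdDecomposition].
#' @param nSamples number of effect vectors (>= 100).
#' @param seed optional integer seed for reproducibility.
#' @param sampler optional function \code{(nSamples, L)} returning the matrix
#'   of effect draws, for non-Gaussian extensions.
#' @return data.frame with one row per component (\code{VA}, \code{Vg},
#'   \code{Cw}, \code{Cb}, \code{C}, \code{bw}, \code{bb}, \code{b}) and
#'   columns \code{mean}, \code{var}, \code{skewness}, \code{kurtosis},
#'   \code{n}; the number of draws with undefined ratios is attached as
#'   attribute \code{"n_undefined"}.
#' @export
monteCarloMoments <- function(dec, nSamples = 10000, seed = NULL,
                              sampler = NULL) {
  if (nSamples < 100) stop("nSamples must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  L <- length(dec@p)
  A <- if (is.null(sampler)) matrix(stats::rnorm(nSamples * L), nSamples, L)
       else sampler(nSamples, L)
  comp <- .componentsMany(dec, A)
  stat <- function(v) {
    v <- v[!is.na(v)]
    m <- mean(v); s2 <- mean((v - m)^2)
    c(mean = m, var = s2 * length(v) / (length(v) - 1),
      skewness = if (s2 > 0) mean((v - m)^3) / s2^1.5 else NA_real_,
      kurtosis = if (s2 > 0) mean((v - m)^4) / s2^2 else NA_real_,
      n = length(v))
  }
  out <- as.data.frame(t(vapply(comp, stat, numeric(5))))
  attr(out, "n_undefined") <- sum(is.na(comp$b))
  attr(out, "seed") <- seed
  out
}

#' Probability that the disequilibrium component C is negative
#'
#' Monte-Carlo estimate of \eqn{P[C < 0 | X]} over \eqn{a \sim N(0, I)}.
#' With symmetric effect distributions this probability exceeds 0.5 whenever
#' many locus pairs are in positive (coupling) association, reflecting the
#' positive skewness of C given X.
#'
#' @param dec a [GpdDecomposition].
#' @param nSamples number of effect draws.
#' @param seed optional integer seed.
#' @return list with \code{prob}, binomial \code{se}, \code{nSamples} and
#'   \code{degenerate} (\code{TRUE} when all off-diagonal GPD is zero, so C
#'   is identically 0 and the probability is not meaningful).
#' @export
signAsymmetryProbability <- function(dec, nSamples = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  offd <- sum(dec@W^2) + sum(dec@B^2)
  if (offd == 0)
    return(list(prob = NA_real_, se = NA_real_, nSamples = nSamples,
                degenerate = TRUE))
  A <- matrix(stats::rnorm(nSamples * length(dec@p)), nSamples)
  C <- .componentsMany(dec, A)$C
  phat <- mean(C < 0)
  list(prob = phat, se = sqrt(phat * (1 - phat) / nSamples),
       nSamples = nSamples, degenerate = FALSE)
}
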