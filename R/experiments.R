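#' Aggregated conditional-moment estimates for one scenario
#'
#' A scenario is the combination of a founder panel, a mating design, P
#' parents, population size N and trait size L.  Each replication samples P
#' parents, simulates generations G1..G<generations> and their DH
#' populations, then draws \code{nQtlSets} sets of L QTL positions from the
#' candidate pool; for every realized QTL genotype matrix the conditional
#' moments are computed and averaged over all \code{nReps * nQtlSets}
#' realizations per generation.  Realizations with undefined ratios
#' (\eqn{trace(V) = 0}) are excluded from the ratio averages and counted.
#'
#' Per-replication seeds are derived as \code{seed + replication}, so two
#' scenario runs with the same master seed draw identical parent samples in
#' every replication: design arms are paired (common random numbers), which
#' sharpens between-design comparisons.
#'
#' @param panel founder [GenotypeMatrix].
#' @param design \code{"DC"}, \code{"FC"} or \code{"HC"}.
#' @param P,N,L parents, population size, number of QTL.
#' @param nReps replications (paper-scale default 500; desk-scale runs use
#'   fewer).
#' @param nQtlSets QTL position sets per replication (paper-scale 50).
#' @param generations number of intermated generations to simulate.
#' @param qtlPool candidate locus indices for QTL sampling (default: all
#'   polymorphic-or-not panel loci).
#' @param seed master seed; keep below 2^31 - nReps.
#' @return data.frame with columns \code{generation}, \code{statistic},
#'   \code{estimate} (mean over realizations), \code{se} (standard error
#'   across replications), \code{nRealizations}, \code{nUndefined}; scenario
#'   parameters are attached as attributes.
#' @export
runScenario <- function(panel, design, P, N, L, nReps = 50, nQtlSets = 10,
                        generations = 1, qtlPool = NULL, seed = 1) {
  stopifnot(nReps >= 1, nQtlSets >= 1, generations >= 1)
  map <- panel@map
  qtlPool <- qtlPool %||% seq_len(nrow(map@loci))
  genLabels <- paste0("G", seq_len(generations), "-DH")
  statNames <- names(.momentsFromTraces(1, 1, 0, 0))
  ## acc[[gen]]: nReps x nStats matrix of within-replication means
  acc <- lapply(genLabels, function(g)
    matrix(NA_real_, nReps, length(statNames),
           dimnames = list(NULL, statNames)))
  names(acc) <- genLabels
  nUndef <- stats::setNames(integer(length(genLabels)), genLabels)
  for (rep in seq_len(nReps)) {
    repl <- runReplication(panel, design, P, N, generations,
                           seed = seed + rep)
    qtlSets <- lapply(seq_len(nQtlSets), function(s)
      sampleQtl(map, L, pool = qtlPool))
    for (g in genLabels) {
      sets <- vapply(qtlSets, function(idx)
        conditionalMoments(repl$dh[[g]][, idx]), numeric(length(statNames)))
      nUndef[g] <- nUndef[g] + sum(is.na(sets["var_b", ]))
      acc[[g]][rep, ] <- rowMeans(sets, na.rm = TRUE)
    }
  }
  out <- do.call(rbind, lapply(genLabels, function(g) {
    m <- acc[[g]]
    data.frame(generation = g, statistic = statNames,
               estimate = colMeans(m, na.rm = TRUE),
               se = apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(nReps),
               nRealizations = nReps * nQtlSets,
               nUndefined = nUndef[g], row.names = NULL)
  }))
  structure(out, design = design, P = P, N = N, L = L, nReps = nReps,
            nQtlSets = nQtlSets, seed = seed)
}

#' Fit the finite-population decay model for var[b_b]
#'
#' With infinite population size the between-chromosome disequilibrium
#' variance is reduced by 1/4 per generation of random mating.  Sampling from
#' a finite population of size N regenerates disequilibrium each generation,
#' described by the recursion \eqn{v_0 = \theta + \omega}, \eqn{v_{r+1} =
#' v_r / 4 + \omega}, whose closed form is
#' \deqn{v_r = \theta / 4^r + \omega (4 - 4^{-r}) / 3.}
#' \eqn{\theta} is the infinite-N level at r = 0 and \eqn{\omega} the
#' finite-N deviation, sustaining a steady state of \eqn{(4/3)\omega} as r
#' grows.  The model is linear in \eqn{(\theta, \omega)}; the unbounded fit
#' is exact least squares, and when it yields \eqn{\omega < 0} (flagged) a
#' refit constrained to \eqn{\omega \ge 0} is reported.
#'
#' @param varbb numeric vector of var[b_b] estimates per generation.
#' @param r recombination-step index per element; G1-DH is r = 0 (default
#'   \code{0:(length(varbb) - 1)}).
#' @return object of class \code{DecayFit}: a list with \code{theta},
#'   \code{omega}, their standard errors, \code{rss},
#'   \code{steadyState} = (4/3) omega, \code{omegaNegative},
#'   \code{unbounded} (the diagnostic unconstrained estimates) and the data.
#' @examples
#' r <- 0:3
#' decayCurve(0.08 / 4^r + 0.03 * (4 - 4^(-r)) / 3)  # recovers (0.08, 0.03)
#' @export
decayCurve <- function(varbb, r = seq_along(varbb) - 1) {
  if (length(varbb) < 3)
    stop("at least 3 generations of estimates are required")
  if (length(varbb) != length(r)) stop("varbb and r lengths differ")
  x1 <- 4^(-r)
  x2 <- (4 - 4^(-r)) / 3
  fit <- stats::lm(varbb ~ 0 + x1 + x2)
  cf <- stats::coef(fit)
  ## noiseless series make summary.lm warn about a perfect fit; the zero SEs
  ## are exactly what we want to report there
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  theta <- unname(cf[1L]); omega <- unname(cf[2L])
  unbounded <- c(theta = theta, omega = omega)
  omegaNegative <- omega < 0
  if (omegaNegative || theta < 0) {
    cfit <- try(stats::nls(varbb ~ theta * x1 + omega * x2,
                           start = list(theta = max(theta, 1e-8),
                                        omega = max(omega, 1e-8)),
                           algorithm = "port", lower = c(0, 0)),
                silent = TRUE)
    if (inherits(cfit, "try-error"))
      stop("constrained decay fit did not converge: ",
           attr(cfit, "condition")$message)
    cf <- stats::coef(cfit)
    theta <- unname(cf["theta"]); omega <- unname(cf["omega"])
  }
  resid <- varbb - (theta * x1 + omega * x2)
  structure(list(theta = theta, omega = omega,
                 se = stats::setNames(unname(se), c("theta", "omega")),
                 rss = sum(resid^2), steadyState = 4 / 3 * omega,
                 omegaNegative = omegaNegative, unbounded = unbounded,
                 r = r, varbb = varbb),
            class = "DecayFit")
}

#' @export
print.DecayFit <- function(x, ...) {
  cat(sprintf(paste0("Decay fit over %d generations: theta = %.4g, ",
                     "omega = %.4g (steady state %.4g), rss = %.3g\n"),
              length(x$r), x$theta, x$omega, x$steadyState, x$rss))
  if (x$omegaNegative)
    cat("  note: unbounded omega was negative; constrained fit reported\n")
  invisible(x)
}

#' Write scenario results to disk
#'
#' One CSV row per generation x statistic, plus an optional decay-fit CSV and
#' a JSON metadata record (seeds, scenario parameters, timestamp) when
#' jsonlite is available.  An empty estimate set yields a header-only CSV
#' with a warning.
#'
#' @param estimates data.frame from [runScenario()] (possibly several,
#'   row-bound).
#' @param dir output directory (created if needed).
#' @param fit optional \code{DecayFit}.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
writeRunReport <- function(estimates, dir, fit = NULL, prefix = "scenario") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_estimates.csv"))
  if (nrow(estimates) == 0)
    warning("empty estimate set: writing header-only CSV")
  utils::write.csv(estimates, paths[1L], row.names = FALSE)
  if (!is.null(fit)) {
    p <- file.path(dir, paste0(prefix, "_decayfit.csv"))
    utils::write.csv(data.frame(r = fit$r, varbb = fit$varbb,
                                fitted = fit$theta / 4^fit$r +
                                  fit$omega * (4 - 4^(-fit$r)) / 3),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- attributes(estimates)
    meta <- meta[setdiff(names(meta), c("names", "row.names", "class"))]
    meta$package_version <- as.character(utils::packageVersion("gpdVA"))
    if (!is.null(fit))
      meta$decay <- list(theta = fit$theta, omega = fit$omega,
                         steadyState = fit$steadyState)
    p <- file.path(dir, paste0(prefix, "_metadata.json"))
    jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
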