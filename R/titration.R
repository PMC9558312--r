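## Deprotonated-fraction estimators, Henderson-Hasselbalch fitting and
## multi-pH titration campaigns.

#' Deprotonated fraction of a single-site lambda series
#'
#' Frames with lambda below the lower threshold count as protonated, frames
#' above the upper threshold as deprotonated; intermediate frames are
#' excluded from both counts.  `S = N_deprot / (N_prot + N_deprot)`.
#'
#' @param lambda numeric series of the deprotonation coordinate.
#' @param thresholds length-2 numeric `(lower, upper)`, default
#'   `c(0.2, 0.8)`.
#' @return list with `S`, `nProt`, `nDeprot`, `nExcluded`.
#' @examples
#' deprotFraction(c(rep(0.05, 30), rep(0.95, 10), rep(0.5, 5)))$S  # 0.25
#' @export
deprotFraction <- function(lambda, thresholds = c(0.2, 0.8)) {
  if (!length(lambda)) stop("empty lambda series")
  nProt <- sum(lambda < thresholds[1])
  nDeprot <- sum(lambda > thresholds[2])
  if (nProt + nDeprot == 0L)
    stop("no classified frames: deprotonated fraction undefined")
  list(S = nDeprot / (nProt + nDeprot), nProt = nProt, nDeprot = nDeprot,
       nExcluded = length(lambda) - nProt - nDeprot)
}

#' Macroscopic and microscopic deprotonated fractions of a multisite group
#'
#' Frames are classified by which state's coordinate exceeds the upper
#' threshold (under the simplex constraint at most one can).  With counts
#' `N_k` per state and `p` the fully protonated state, the macroscopic
#' fraction is `sum_{k != p} N_k / sum_k N_k` and the microscopic fraction of
#' deprotonated tautomer `k` conditions on frames in either the protonated
#' basin or basin `k`: `N_k / (N_p + N_k)`.
#'
#' @param lambdas matrix `[n_frames x n_states]` of the group's coordinates.
#' @param protonatedState column index of the fully protonated state.
#' @param thresholds classification thresholds; only the upper one is used.
#' @param stateNames optional state labels for the output.
#' @return list with `Smacro`, `Smicro` (named, one per deprotonated state),
#'   `counts`, `nExcluded`.
#' @examples
#' ## counts (50, 30, 20) in the HSP / HSD / HSE basins
#' m <- matrix(0.05, 100, 3); m[1:50, 1] <- m[51:80, 2] <- m[81:100, 3] <- 0.9
#' deprotFractionMultisite(m, stateNames = c("HSP", "HSD", "HSE"))
#' @export
deprotFractionMultisite <- function(lambdas, protonatedState = 1L,
                                    thresholds = c(0.2, 0.8),
                                    stateNames = colnames(lambdas)) {
  lambdas <- as.matrix(lambdas)
  ns <- ncol(lambdas)
  if (is.null(stateNames)) stateNames <- paste0("state", seq_len(ns))
  inBasin <- lambdas > thresholds[2]
  if (any(rowSums(inBasin) > 1L))
    stop("two coordinates above the upper threshold in one frame: ",
         "impossible under the simplex constraint")
  counts <- colSums(inBasin)
  names(counts) <- stateNames
  tot <- sum(counts)
  if (tot == 0L)
    stop("no classified frames: deprotonated fraction undefined")
  p <- protonatedState
  sMicro <- vapply(setdiff(seq_len(ns), p), function(k) {
    den <- counts[p] + counts[k]
    if (den == 0L) NA_real_ else unname(counts[k] / den)
  }, numeric(1))
  names(sMicro) <- stateNames[setdiff(seq_len(ns), p)]
  list(Smacro = sum(counts[-p]) / tot, Smicro = sMicro, counts = counts,
       nExcluded = nrow(lambdas) - tot)
}

#' Henderson-Hasselbalch fit of a titration curve
#'
#' Nonlinear least-squares fit of `S(pH) = 1 / (1 + 10^(pKa - pH))` with the
#' pKa as the sole free parameter.  The standard error comes from the
#' linearized fit covariance and the 95 percent confidence half-width from
#' the t distribution with `n - 1` degrees of freedom.  Optional
#' inverse-variance weighting by the per-point standard errors.
#'
#' @param pH numeric pH values (at least 3, spanning both sides of the
#'   transition).
#' @param S deprotonated fractions in `[0, 1]`.
#' @param sErr optional per-point standard errors used as
#'   inverse-variance weights (points with zero or missing error get the
#'   median weight).
#' @return list with `pKa`, `se`, `ci95`, `fitted`, `nPoints`, `rss`.
#' @examples
#' pH <- seq(1, 7, 0.5)
#' fitHH(pH, 1 / (1 + 10^(4 - pH)))$pKa   # 4
#' @export
fitHH <- function(pH, S, sErr = NULL) {
  keep <- is.finite(pH) & is.finite(S)
  pH <- pH[keep]; S <- S[keep]
  if (length(pH) < 3L)
    stop("need at least 3 pH points for a Henderson-Hasselbalch fit")
  w <- rep(1, length(pH))
  if (!is.null(sErr)) {
    sErr <- sErr[keep]
    ok <- is.finite(sErr) & sErr > 0
    if (any(ok)) {
      w[ok] <- 1 / sErr[ok]^2
      w[!ok] <- stats::median(w[ok])
    }
  }
  if (all(S < 0.5) || all(S > 0.5))
    stop("titration curve does not cross S = 0.5: pKa not identifiable")
  hh <- function(p) 1 / (1 + 10^(p - pH))
  rssf <- function(p) sum(w * (S - hh(p))^2)
  opt <- stats::optimize(rssf, lower = min(pH) - 10, upper = max(pH) + 10,
                         tol = 1e-10)
  pKa <- opt$minimum
  f <- hh(pKa)
  J <- -log(10) * f * (1 - f)
  n <- length(pH)
  sigma2 <- opt$objective / (n - 1)
  se <- sqrt(sigma2 / sum(w * J^2))
  list(pKa = pKa, se = se, ci95 = stats::qt(0.975, n - 1) * se,
       fitted = f, nPoints = n, rss = opt$objective)
}

## Per-run fraction extraction shared by the frozen and mobile campaign
## paths.  lamMat: [frames x nCoords] for one run.
.runFractions <- function(lamMat, group, layout, thresholds) {
  cols <- which(layout$groupIndex == 1L)
  if (length(group@lambda) == 2L) {
    d <- cols[setdiff(1:2, group@protonatedState)]
    fr <- deprotFraction(lamMat[, d], thresholds)
    data.frame(species = "site", S = fr$S,
               framesUsed = fr$nProt + fr$nDeprot,
               framesExcluded = fr$nExcluded)
  } else {
    fr <- deprotFractionMultisite(lamMat[, cols, drop = FALSE],
                                  group@protonatedState, thresholds,
                                  stateNames = group@stateNames)
    used <- sum(fr$counts)
    data.frame(
      species = c("macro", paste0("micro:", names(fr$Smicro))),
      S = c(fr$Smacro, unname(fr$Smicro)),
      framesUsed = used, framesExcluded = fr$nExcluded)
  }
}

#' Run a multi-pH titration campaign
#'
#' Runs `nReplicas` independent lambda-dynamics trajectories at every pH
#' value, classifies the recorded frames into protonation basins after
#' discarding a burn-in prefix, averages the deprotonated fractions over
#' replicas, and fits the Henderson-Hasselbalch equation to every reportable
#' species (the site itself for a two-state group; the macroscopic fraction
#' and the per-tautomer microscopic fractions for a multisite group).
#' Fully reproducible from the seed.  Frozen-atom systems are sampled with
#' the vectorized lockstep engine; mobile systems fall back to sequential
#' [runDynamics()] calls.
#'
#' @param system a [TitratableSystem-class] with exactly one lambda-group.
#' @param pH numeric vector of pH values.
#' @param nReplicas replicas per pH value (default 5).
#' @param nSteps lambda-steps per replica.  The default protocol,
#'   `2e6` steps of 0.01 ps, gives the conventional 20 ns per replica;
#'   because the pH step is flat inside both classification basins, the
#'   leapfrog discretization bias cancels out of the basin-population
#'   ratio, so the larger lambda-only step is safe.
#' @param dt integration step, ps.
#' @param lambdaMass fictitious lambda mass, amu.
#' @param lambdaT,lambdaTau lambda thermostat temperature (defaults to the
#'   system temperature) and coupling time, ps.
#' @param settings a [LambdaPotentialSettings-class].
#' @param vmm optional [VmmPolynomial-class] correction for the group.
#' @param thresholds classification thresholds.
#' @param burnIn fraction of frames discarded from the start of every
#'   trajectory.
#' @param outputInterval frame spacing, ps.
#' @param seed RNG seed for the whole campaign.
#' @param returnTrajectories also return every trajectory as a
#'   [LambdaTrajectory-class] (memory permitting).
#' @return a [TitrationResult-class]; with `returnTrajectories = TRUE`, a
#'   list with elements `result` and `trajectories`.
#' @seealso [fitHH()], [quadratureOracle()]
#' @export
titrationCampaign <- function(system, pH, nReplicas = 5L, nSteps = 2000000L,
                              dt = 0.01, lambdaMass = 5,
                              lambdaT = system@temperature, lambdaTau = 2.0,
                              settings = LambdaPotentialSettings(),
                              vmm = NULL, thresholds = c(0.2, 0.8),
                              burnIn = 0.1, outputInterval = 1.0,
                              seed = 1L, returnTrajectories = FALSE) {
  if (length(system@groups) != 1L)
    stop("titrationCampaign expects a system with exactly one lambda-group")
  group <- system@groups[[1]]
  layout <- .coordLayout(system)
  nRuns <- length(pH) * nReplicas
  runPH <- rep(pH, each = nReplicas)
  runRep <- rep(seq_len(nReplicas), times = length(pH))
  outputEvery <- max(1L, round(outputInterval / dt))
  ## start every run at the simplex midpoint (no basin preference; the
  ## burn-in removes the relaxation transient)
  ns <- length(group@lambda)
  init <- unname(lambdaValues(system))
  init[seq_len(ns)] <- 1 / ns
  trajList <- if (returnTrajectories) vector("list", nRuns) else NULL
  perRun <- vector("list", nRuns)
  if (system@frozen) {
    set.seed(seed)
    ens <- .sampleEnsemble(system, runPH, nSteps, dt, lambdaMass, lambdaT,
                           lambdaTau, settings, vmm, outputEvery, init)
    nFrames <- dim(ens$frames)[1]
    drop0 <- floor(burnIn * nFrames)
    keep <- seq.int(drop0 + 1L, nFrames)
    for (r in seq_len(nRuns)) {
      lamMat <- ens$frames[, , r, drop = FALSE]
      dim(lamMat) <- dim(ens$frames)[1:2]
      perRun[[r]] <- tryCatch(
        .runFractions(lamMat[keep, , drop = FALSE], group, layout,
                      thresholds),
        error = function(e) NULL)
      if (returnTrajectories) {
        colnames(lamMat) <- ens$coordNames
        trajList[[r]] <- new("LambdaTrajectory", time = ens$time,
                             lambdas = lamMat,
                             coordinateNames = ens$coordNames,
                             pH = runPH[r], seed = as.integer(seed),
                             replica = runRep[r],
                             energies = data.frame(
                               time = numeric(), potential = numeric(),
                               kineticAtoms = numeric(),
                               kineticLambda = numeric()))
      }
    }
  } else {
    for (r in seq_len(nRuns)) {
      sys <- system
      lambdaValues(sys) <- init
      spec <- IntegratorSpec(nSteps = nSteps, dt = dt,
                             lambdaT = lambdaT, lambdaTau = lambdaTau,
                             lambdaMass = lambdaMass,
                             outputInterval = outputInterval,
                             seed = seed + r - 1L)
      tr <- runDynamics(sys, spec, runPH[r], settings, vmm)
      nFrames <- length(tr@time)
      keep <- seq.int(floor(burnIn * nFrames) + 1L, nFrames)
      perRun[[r]] <- tryCatch(
        .runFractions(tr@lambdas[keep, , drop = FALSE], group, layout,
                      thresholds),
        error = function(e) NULL)
      if (returnTrajectories) trajList[[r]] <- tr
    }
  }
  ## aggregate replicas
  rows <- list()
  for (iPH in seq_along(pH)) {
    runs <- which(runPH == pH[iPH])
    tabs <- perRun[runs]
    bad <- vapply(tabs, is.null, TRUE)
    if (any(bad)) {
      warning(sprintf(
        "pH %.2f: %d replica(s) with no classified frames; point flagged",
        pH[iPH], sum(bad)))
      rows[[iPH]] <- data.frame(pH = pH[iPH], species = NA_character_,
                                S = NA_real_, sem = NA_real_,
                                framesUsed = 0L, framesExcluded = 0L,
                                nReplicas = 0L)
      next
    }
    tab <- do.call(rbind, tabs)
    agg <- lapply(split(tab, tab$species), function(d) {
      data.frame(pH = pH[iPH], species = d$species[1], S = mean(d$S),
                 sem = stats::sd(d$S) / sqrt(nrow(d)),
                 framesUsed = sum(d$framesUsed),
                 framesExcluded = sum(d$framesExcluded),
                 nReplicas = nrow(d))
    })
    rows[[iPH]] <- do.call(rbind, agg)
  }
  fractions <- do.call(rbind, rows)
  rownames(fractions) <- NULL
  ok <- !is.na(fractions$species)
  if (!any(ok))
    stop("no pH point produced classified frames")
  fits <- do.call(rbind, lapply(
    split(fractions[ok, ], fractions$species[ok]), function(d) {
      ft <- tryCatch(fitHH(d$pH, d$S), error = function(e) {
        warning("Henderson-Hasselbalch fit failed for species '",
                d$species[1], "': ", conditionMessage(e))
        NULL
      })
      if (is.null(ft))
        data.frame(species = d$species[1], pKa = NA_real_,
                   ci95 = NA_real_, se = NA_real_, nPoints = nrow(d))
      else
        data.frame(species = d$species[1], pKa = ft$pKa, ci95 = ft$ci95,
                   se = ft$se, nPoints = ft$nPoints)
    }))
  rownames(fits) <- NULL
  res <- new("TitrationResult", fractions = fractions, fits = fits,
             thresholds = thresholds, nReplicas = as.integer(nReplicas),
             pHValues = as.numeric(pH))
  if (returnTrajectories) list(result = res, trajectories = trajList)
  else res
}

#' @describeIn pKaEstimates fitted pKas of a campaign.
#' @export
setMethod("pKaEstimates", "TitrationResult", function(object) object@fits)

#' @describeIn deprotonatedFractions per-pH fractions of a campaign.
#' @export
setMethod("deprotonatedFractions", "TitrationResult",
          function(object) object@fractions)
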