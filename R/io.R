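## Configuration parsing, trajectory / summary writers and readers, and the
## programmatic surface behind the command-line subcommands
## (calibrate / titrate / analyze / validate).

.configDefaults <- function() {
  list(
    mode = "titrate",
    seed = 1L,
    output = "lambdacph_out",
    system = list(),
    integrator = list(dt = 0.002, nSteps = 200000L, lambdaT = 300,
                      lambdaTau = 2.0, atomT = 300, atomTau = 0.5,
                      lambdaMass = 5, outputInterval = 1.0),
    potentials = list(barrier = 5.0, k1 = 50, x0 = 0.1),
    titration = list(pH = seq(1, 7, by = 0.5), replicas = 5L,
                     thresholds = c(0.2, 0.8), burnIn = 0.1),
    calibration = list(gridMin = -0.1, gridMax = 1.1, gridStep = 0.05,
                       order = 5L, nStepsPerPoint = 2000L))
}

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key '", where, bad[1], "'")
}

.mergeSection <- function(user, def, where) {
  if (is.null(user)) return(def)
  .checkKeys(user, names(def), where)
  for (k in names(user)) def[[k]] <- user[[k]]
  def
}

#' Parse and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys (naming the
#' offender), fills in the engine defaults (lambda mass 5 amu, T 300 K,
#' lambda thermostat 2.0 ps, bias barrier 5.0 kJ/mol, thresholds 0.2/0.8,
#' TI grid -0.1 to 1.1 in steps of 0.05) and checks the value ranges.  A run
#' is reproducible from its configuration and seed alone.
#'
#' @param path path to a YAML file, or a raw YAML string.
#' @return a validated configuration (class `cphmdConfig`).
#' @seealso [serializeConfig()], [runConfig()]
#' @export
parseConfig <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  if (!is.list(raw)) stop("configuration must be a YAML mapping")
  def <- .configDefaults()
  .checkKeys(raw, names(def), "")
  cfg <- def
  for (k in c("mode", "seed", "output"))
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  cfg$system <- .validateSystemConfig(raw$system)
  cfg$integrator <- .mergeSection(raw$integrator, def$integrator,
                                  "integrator.")
  cfg$potentials <- .mergeSection(raw$potentials, def$potentials,
                                  "potentials.")
  cfg$titration <- .mergeSection(raw$titration, def$titration, "titration.")
  cfg$calibration <- .mergeSection(raw$calibration, def$calibration,
                                   "calibration.")
  if (!cfg$mode %in% c("calibrate", "titrate", "analyze", "validate"))
    stop("mode must be one of calibrate/titrate/analyze/validate")
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$potentials$barrier < 0)
    stop("potentials.barrier must be >= 0")
  if (cfg$potentials$x0 <= 0 || cfg$potentials$x0 >= 0.5)
    stop("potentials.x0 must lie in (0, 0.5)")
  if (cfg$integrator$dt <= 0) stop("integrator.dt must be positive")
  if (cfg$titration$burnIn < 0 || cfg$titration$burnIn >= 1)
    stop("titration.burnIn must lie in [0, 1)")
  th <- cfg$titration$thresholds
  if (length(th) != 2L || th[1] >= th[2])
    stop("titration.thresholds must be an increasing pair")
  structure(cfg, class = "cphmdConfig")
}

## YAML 1.1 parses a bare `y` key as the boolean TRUE; restore coordinate
## field names on atom-like records.
.fixCoordNames <- function(a) {
  names(a)[names(a) %in% c("TRUE", "yes")] <- "y"
  names(a)[names(a) %in% c("FALSE", "no")] <- "n"
  a
}

.validateSystemConfig <- function(sys) {
  if (is.null(sys) || !length(sys)) return(list())
  .checkKeys(sys, c("fixture", "atoms", "groups", "buffers", "scheme",
                    "cutoff", "epsilonR", "box", "temperature",
                    "totalChargeTarget", "frozen", "restraintK"), "system.")
  if (!is.null(sys$fixture))
    .checkKeys(sys$fixture,
               c("kind", "pKaRefs", "environmentCharges", "temperature",
                 "nBuffers", "base", "frozen", "restraintK", "scheme",
                 "cutoff", "epsilonR"), "system.fixture.")
  sys
}

#' Serialize a configuration back to YAML
#'
#' @param config a `cphmdConfig` from [parseConfig()].
#' @param path optional output file; with `NULL` the YAML text is returned.
#' @return the YAML string (invisibly when written to a file).
#' @export
serializeConfig <- function(config, path = NULL) {
  txt <- yaml::as.yaml(unclass(config), precision = 15L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Build a titratable system from a configuration
#'
#' The `system` section either names a fixture
#' (`system: fixture: {kind: ideal_site, pKaRefs: [3.65], ...}`) or defines
#' the system inline: a list of atoms (`x`, `y`, `z`, `mass`, `charge`),
#' lambda-groups (`atoms`, `stateCharges` as one charge row per member atom,
#' `pKaRefs`, optional `protonatedState`, `stateNames`, `name`), an optional
#' buffer block (`atoms`, `qMin`, `qMax`, `collectiveLambda`), and the
#' electrostatics / temperature settings.
#'
#' @param config a `cphmdConfig`.
#' @return a [TitratableSystem-class].
#' @export
systemFromConfig <- function(config) {
  sys <- config$system
  if (!length(sys)) stop("configuration has no system section")
  if (!is.null(sys$fixture)) {
    fx <- sys$fixture
    args <- fx
    if (!is.null(fx$pKaRefs)) args$pKaRefs <- as.numeric(fx$pKaRefs)
    if (!is.null(fx$environmentCharges))
      args$environmentCharges <-
        do.call(rbind, lapply(fx$environmentCharges, function(a)
          as.data.frame(.fixCoordNames(a))))
    return(do.call(makeFixture, args))
  }
  if (is.null(sys$atoms)) stop("system needs a fixture or an atoms list")
  atoms <- do.call(rbind, lapply(sys$atoms, function(a) {
    a <- .fixCoordNames(a)
    data.frame(x = a$x, y = a$y, z = a$z,
               mass = if (is.null(a$mass)) 12 else a$mass,
               charge = if (is.null(a$charge)) 0 else a$charge)
  }))
  groups <- lapply(sys$groups, function(g) {
    sc <- do.call(rbind, lapply(g$stateCharges, as.numeric))
    LambdaGroup(as.integer(g$atoms), sc, as.numeric(g$pKaRefs),
                protonatedState = if (is.null(g$protonatedState)) 1L
                                  else as.integer(g$protonatedState),
                stateNames = g$stateNames,
                name = if (is.null(g$name)) "site" else g$name)
  })
  buffers <- NULL
  if (!is.null(sys$buffers)) {
    b <- sys$buffers
    buffers <- BufferSet(as.integer(b$atoms),
                         qMin = if (is.null(b$qMin)) -0.5 else b$qMin,
                         qMax = if (is.null(b$qMax)) 0.5 else b$qMax,
                         collectiveLambda = if (is.null(b$collectiveLambda))
                           0.5 else b$collectiveLambda)
  }
  TitratableSystem(
    atoms, groups, buffers = buffers,
    scheme = if (is.null(sys$scheme)) "plain" else sys$scheme,
    cutoff = if (is.null(sys$cutoff)) Inf else sys$cutoff,
    epsilonR = if (is.null(sys$epsilonR)) 1 else sys$epsilonR,
    box = if (is.null(sys$box)) NULL else as.numeric(sys$box),
    temperature = if (is.null(sys$temperature)) 300 else sys$temperature,
    totalChargeTarget = if (is.null(sys$totalChargeTarget)) 0
                        else sys$totalChargeTarget,
    frozen = if (is.null(sys$frozen)) TRUE else sys$frozen,
    restraintK = if (is.null(sys$restraintK)) 0 else sys$restraintK)
}

#' Write / read a lambda trajectory text file
#'
#' Whitespace-delimited text, one row per output interval: time in ps, then
#' every lambda-coordinate in group-major order, then the collective buffer
#' coordinate when present.  Header comments record the coordinate names,
#' pH, replica, seed and the protonated-state column, so the file is
#' self-describing for re-analysis.  Values are written in full precision:
#' re-reading reproduces the analysis bit-for-bit.
#'
#' @param traj a [LambdaTrajectory-class].
#' @param path output file.
#' @param protonatedState index of the protonated-state coordinate among the
#'   group columns (written to the header for re-analysis).
#' @return the path, invisibly.
#' @export
writeLambdaTrajectory <- function(traj, path, protonatedState = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# lambda trajectory",
    sprintf("# pH %.10g replica %d seed %d", traj@pH, traj@replica,
            traj@seed),
    sprintf("# protonatedState %d", protonatedState),
    paste("# time_ps", paste(traj@coordinateNames, collapse = " "))), con)
  if (length(traj@time)) {
    rows <- cbind(traj@time, traj@lambdas)
    writeLines(apply(rows, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname writeLambdaTrajectory
#' @export
readLambdaTrajectory <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  meta <- header[grepl("^# pH ", header)]
  mv <- strsplit(sub("^# ", "", meta[1]), " ")[[1]]
  pH <- as.numeric(mv[2]); replica <- as.integer(mv[4])
  seed <- as.integer(mv[6])
  names <- strsplit(sub("^# time_ps ?", "",
                        header[grepl("^# time_ps", header)]), " ")[[1]]
  names <- names[nzchar(names)]
  if (length(body)) {
    m <- do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"), as.numeric))
  } else {
    m <- matrix(numeric(), 0L, length(names) + 1L)
  }
  lam <- m[, -1, drop = FALSE]
  colnames(lam) <- names
  new("LambdaTrajectory", time = as.numeric(m[, 1]), lambdas = lam,
      coordinateNames = names, pH = pH, seed = seed, replica = replica,
      energies = data.frame(time = numeric(), potential = numeric(),
                            kineticAtoms = numeric(),
                            kineticLambda = numeric()))
}

#' Write run outputs to a directory
#'
#' Writes the titration summary CSV (`titration.csv`: pH, species, mean and
#' standard error of the deprotonated fraction, frame counts), the fit
#' sidecar (`fits.yaml`), per-run lambda-trajectory files
#' (`lambda_pH<value>_rep<index>.dat`) and a run log with seed and package
#' version.
#'
#' @param result a [TitrationResult-class].
#' @param outdir output directory (created if needed).
#' @param trajectories optional list of [LambdaTrajectory-class] objects.
#' @param config optional `cphmdConfig` echoed into the run log.
#' @param protonatedState protonated-state column index for the trajectory
#'   headers.
#' @return `outdir`, invisibly.
#' @export
writeOutputs <- function(result, outdir, trajectories = NULL, config = NULL,
                         protonatedState = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result@fractions, file.path(outdir, "titration.csv"),
                   row.names = FALSE)
  yaml::write_yaml(
    list(fits = apply(result@fits, 1, as.list, simplify = FALSE),
         thresholds = result@thresholds,
         nReplicas = result@nReplicas),
    file.path(outdir, "fits.yaml"), precision = 15L)
  for (tr in trajectories) {
    f <- sprintf("lambda_pH%.10g_rep%d.dat", tr@pH, tr@replica)
    writeLambdaTrajectory(tr, file.path(outdir, f), protonatedState)
  }
  log <- c(sprintf("lambdaCPH %s",
                   as.character(utils::packageVersion("lambdaCPH"))),
           if (!is.null(config)) c("", "configuration:",
                                   serializeConfig(config)))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Re-analyze written lambda trajectories
#'
#' Reads every `lambda_pH*_rep*.dat` file in a directory, discards the
#' burn-in prefix, recomputes the deprotonated fractions and refits the
#' Henderson-Hasselbalch equation.  Applied to the files written by a run,
#' this reproduces the in-memory result exactly.
#'
#' @param outdir directory containing trajectory files.
#' @param thresholds classification thresholds.
#' @param burnIn discarded prefix fraction.
#' @return a [TitrationResult-class].
#' @export
analyzeOutputs <- function(outdir, thresholds = c(0.2, 0.8), burnIn = 0.1) {
  files <- list.files(outdir, pattern = "^lambda_pH.*_rep[0-9]+\\.dat$",
                      full.names = TRUE)
  if (!length(files)) stop("no lambda trajectory files in ", outdir)
  trajs <- lapply(files, readLambdaTrajectory)
  pState <- as.integer(sub("^# protonatedState ", "",
    grep("^# protonatedState", readLines(files[1], n = 5L), value = TRUE)))
  ## group columns = all non-buffer coordinates
  cn <- trajs[[1]]@coordinateNames
  gcols <- which(cn != "buffer")
  perRun <- lapply(trajs, function(tr) {
    nFrames <- length(tr@time)
    keep <- seq.int(floor(burnIn * nFrames) + 1L, nFrames)
    lam <- tr@lambdas[keep, gcols, drop = FALSE]
    tab <- if (length(gcols) == 2L) {
      d <- setdiff(1:2, pState)
      fr <- deprotFraction(lam[, d], thresholds)
      data.frame(species = "site", S = fr$S,
                 framesUsed = fr$nProt + fr$nDeprot,
                 framesExcluded = fr$nExcluded)
    } else {
      fr <- deprotFractionMultisite(lam, pState, thresholds,
                                    stateNames = sub("^[^.]*\\.", "",
                                                     cn[gcols]))
      data.frame(species = c("macro", paste0("micro:", names(fr$Smicro))),
                 S = c(fr$Smacro, unname(fr$Smicro)),
                 framesUsed = sum(fr$counts), framesExcluded = fr$nExcluded)
    }
    tab$pH <- tr@pH
    tab
  })
  tab <- do.call(rbind, perRun)
  agg <- do.call(rbind, lapply(split(tab, list(tab$pH, tab$species)),
    function(d) data.frame(pH = d$pH[1], species = d$species[1],
                           S = mean(d$S),
                           sem = stats::sd(d$S) / sqrt(nrow(d)),
                           framesUsed = sum(d$framesUsed),
                           framesExcluded = sum(d$framesExcluded),
                           nReplicas = nrow(d))))
  agg <- agg[order(agg$species, agg$pH), ]
  rownames(agg) <- NULL
  fits <- do.call(rbind, lapply(split(agg, agg$species), function(d) {
    ft <- fitHH(d$pH, d$S)
    data.frame(species = d$species[1], pKa = ft$pKa, ci95 = ft$ci95,
               se = ft$se, nPoints = ft$nPoints)
  }))
  rownames(fits) <- NULL
  new("TitrationResult", fractions = agg, fits = fits,
      thresholds = thresholds, nReplicas = max(agg$nReplicas),
      pHValues = sort(unique(agg$pH)))
}

#' Engine self-validation
#'
#' Runs a set of fast equivalence and contract checks (pH-potential
#' end-state contract, end-state charge identity, charge- vs
#' potential-interpolation agreement on a random system, constraint
#' conservation with buffers, oracle symmetry at pH = pKa) and prints a
#' pass/fail report.
#'
#' @param verbose print per-check lines.
#' @return `TRUE` if every check passed, invisibly.
#' @export
validateEngine <- function(verbose = TRUE) {
  checks <- list()
  ## pH-potential end-state contract
  ok <- TRUE
  for (pKa in c(3.65, 7.2)) for (pH in c(2, 7.4)) for (Tt in c(280, 310)) {
    d <- phPotential(1, pKa, pH, Tt)$energy - phPotential(0, pKa, pH, Tt)$energy
    ok <- ok && abs(d - log(10) * .kB * Tt * (pKa - pH)) < 1e-12
  }
  checks[["pH end-state contract"]] <- ok
  ## end-state charge identity
  sys <- makeFixture("ideal_site", pKaRefs = 4)
  lambdaValues(sys) <- c(0, 1)
  ok <- interpolatedCharges(sys) == -1
  lambdaValues(sys) <- c(1, 0)
  checks[["end-state charges"]] <- ok && interpolatedCharges(sys) == 0
  ## scheme equivalence on a random small system
  set.seed(7)
  rsys <- .randomUncoupledSystem(3L, 12L)
  pi <- potentialInterpOracle(rsys)
  ci <- .ciComponents(rsys)
  checks[["scheme equivalence"]] <-
    abs(pi$components$groupEnv - ci$groupEnv) < 1e-8 &&
    abs(pi$components$interGroup - ci$interGroup) < 1e-8 &&
    pi$nEvaluations == 6L
  ## constraint conservation with buffers
  bsys <- makeFixture("buffer_bath", pKaRefs = 4)
  tr <- runDynamics(bsys, IntegratorSpec(nSteps = 2000L,
                                         outputInterval = 0.1), pH = 4)
  qs <- apply(tr@lambdas, 1, function(l) {
    lambdaValues(bsys) <- l
    totalCharge(bsys)
  })
  sums <- rowSums(tr@lambdas[, 1:2, drop = FALSE])
  checks[["constraint conservation"]] <-
    max(abs(qs)) < 1e-9 && max(abs(sums - 1)) < 1e-9
  ## oracle symmetry at pH = pKa
  o <- quadratureOracle(makeFixture("ideal_site", pKaRefs = 4), pH = 4)
  checks[["oracle symmetry"]] <- abs(o$S - 0.5) < 1e-9
  if (verbose)
    for (nm in names(checks))
      cat(sprintf("%-28s %s\n", nm, if (checks[[nm]]) "PASS" else "FAIL"))
  invisible(all(unlist(checks)))
}

## Random uncoupled (two-state) multi-site system used by the validation and
## equivalence suites.
.randomUncoupledSystem <- function(nSitesWanted, nAtoms,
                                   atomsPerGroup = 2L) {
  repeat {
    P <- matrix(stats::runif(3L * nAtoms, 0, 3), ncol = 3)
    d <- as.matrix(stats::dist(P))
    diag(d) <- Inf
    if (min(d) > 0.2) break
  }
  atoms <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3], mass = 12,
                      charge = round(stats::runif(nAtoms, -0.5, 0.5), 3))
  groups <- lapply(seq_len(nSitesWanted), function(s) {
    ids <- (s - 1L) * atomsPerGroup + seq_len(atomsPerGroup)
    LambdaGroup(ids,
                cbind(round(stats::runif(atomsPerGroup, -1, 1), 3),
                      round(stats::runif(atomsPerGroup, -1, 1), 3)),
                pKaRefs = 4, name = paste0("s", s),
                lambda = c(1 - 0.3 * s / nSitesWanted,
                           0.3 * s / nSitesWanted))
  })
  TitratableSystem(atoms, groups)
}

#' Run one configured campaign
#'
#' Dispatches on the configuration `mode`: `titrate` runs a titration
#' campaign and writes all outputs; `calibrate` runs a
#' thermodynamic-integration scan, fits V^MM and writes the calibration
#' file; `analyze` re-analyzes the trajectory files in the output
#' directory; `validate` runs the engine self-checks.
#'
#' @param config a `cphmdConfig` (see [parseConfig()]).
#' @param outdir optional override of the configured output directory.
#' @return mode-dependent: a [TitrationResult-class] (`titrate`,
#'   `analyze`), the [fitVmm()] list (`calibrate`), or a logical
#'   (`validate`), invisibly.
#' @export
runConfig <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "cphmdConfig"))
  if (is.null(outdir)) outdir <- config$output
  if (config$mode == "validate") return(validateEngine())
  if (config$mode == "analyze")
    return(invisible(analyzeOutputs(outdir,
                                    config$titration$thresholds,
                                    config$titration$burnIn)))
  system <- systemFromConfig(config)
  pot <- LambdaPotentialSettings(config$potentials$barrier,
                                 config$potentials$k1, config$potentials$x0)
  if (config$mode == "calibrate") {
    cal <- config$calibration
    scan <- tiScan(system, gridMin = cal$gridMin, gridMax = cal$gridMax,
                   gridStep = cal$gridStep,
                   nStepsPerPoint = cal$nStepsPerPoint,
                   dt = config$integrator$dt,
                   atomT = config$integrator$atomT,
                   atomTau = config$integrator$atomTau,
                   seed = config$seed, settings = pot)
    fit <- fitVmm(scan, order = cal$order)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeCalibration(file.path(outdir, "calibration.yaml"), scan, fit)
    return(invisible(fit))
  }
  ## titrate
  tt <- config$titration
  it <- config$integrator
  out <- titrationCampaign(system, pH = as.numeric(tt$pH),
                           nReplicas = tt$replicas, nSteps = it$nSteps,
                           dt = it$dt, lambdaMass = it$lambdaMass,
                           lambdaT = it$lambdaT, lambdaTau = it$lambdaTau,
                           settings = pot, thresholds = tt$thresholds,
                           burnIn = tt$burnIn,
                           outputInterval = it$outputInterval,
                           seed = config$seed, returnTrajectories = TRUE)
  pState <- system@groups[[1]]@protonatedState
  writeOutputs(out$result, outdir, out$trajectories, config, pState)
  invisible(out$result)
}

#' @rdname runConfig
#' @param path path to a YAML configuration file.
#' @export
runConfigFile <- function(path, outdir = NULL) {
  runConfig(parseConfig(path), outdir)
}
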