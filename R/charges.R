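#' @describeIn interpolatedCharges charge interpolation over groups and
#'   buffers of a system.
#' @export
setMethod("interpolatedCharges", "TitratableSystem", function(x) {
  q <- x@atoms$charge
  for (g in x@groups) {
    if (any(g@atomIds > length(q)))
      stop("group '", g@name, "' refers to atoms outside the system")
    q[g@atomIds] <- drop(g@stateCharges %*% g@lambda)
  }
  if (!is.null(x@buffers)) {
    b <- x@buffers
    q[b@atomIds] <- b@qMin + b@collectiveLambda * (b@qMax - b@qMin)
  }
  q
})

#' @describeIn totalCharge sum of interpolated charges over all atoms,
#'   buffers included.
#' @export
setMethod("totalCharge", "TitratableSystem", function(x) {
  sum(interpolatedCharges(x))
})

#' @describeIn nSites number of lambda-groups.
#' @export
setMethod("nSites", "TitratableSystem", function(x) length(x@groups))

.coordNames <- function(x) {
  nm <- unlist(lapply(x@groups, function(g) paste(g@name, g@stateNames, sep = ".")))
  if (!is.null(x@buffers)) nm <- c(nm, "buffer")
  if (is.null(nm)) character() else nm
}

#' @describeIn coordinateNames stacked coordinate labels.
#' @export
setMethod("coordinateNames", "TitratableSystem", .coordNames)

#' @describeIn lambdaValues stacked coordinate values.
#' @export
setMethod("lambdaValues", "TitratableSystem", function(x) {
  v <- unlist(lapply(x@groups, function(g) g@lambda))
  if (is.null(v)) v <- numeric()
  if (!is.null(x@buffers)) v <- c(v, x@buffers@collectiveLambda)
  names(v) <- .coordNames(x)
  v
})

#' @describeIn lambdaValues replace the stacked coordinate values.
#' @export
setMethod("lambdaValues<-", "TitratableSystem", function(x, value) {
  nc <- sum(vapply(x@groups, function(g) length(g@lambda), 1L)) +
    (!is.null(x@buffers))
  if (length(value) != nc)
    stop("expected ", nc, " coordinate values, got ", length(value))
  off <- 0L
  for (i in seq_along(x@groups)) {
    ns <- length(x@groups[[i]]@lambda)
    x@groups[[i]]@lambda <- as.numeric(value[off + seq_len(ns)])
    off <- off + ns
  }
  if (!is.null(x@buffers))
    x@buffers@collectiveLambda <- as.numeric(value[off + 1L])
  validObject(x)
  x
})

setMethod("show", "TitratableSystem", function(object) {
  cat("TitratableSystem:", nrow(object@atoms), "atoms,",
      length(object@groups), "lambda-group(s)")
  if (!is.null(object@buffers))
    cat(",", length(object@buffers@atomIds), "buffers")
  cat("\n  electrostatics:", object@scheme,
      if (is.finite(object@cutoff)) sprintf("(cutoff %.2f nm)", object@cutoff)
      else "(no cutoff)",
      sprintf("epsR = %g;", object@epsilonR),
      if (is.null(object@box)) "open boundaries" else
        sprintf("periodic box %.2f x %.2f x %.2f nm", object@box[1],
                object@box[2], object@box[3]), "\n")
  cat(sprintf("  T = %g K; atoms %s; total charge %.6g e\n",
              object@temperature,
              if (object@frozen) "frozen" else "mobile",
              totalCharge(object)))
  for (g in object@groups)
    cat(sprintf("  group '%s': %d atom(s), states %s; lambda = %s\n",
                g@name, length(g@atomIds),
                paste(g@stateNames, collapse = "/"),
                paste(signif(g@lambda, 4), collapse = ", ")))
  invisible(object)
})

setMethod("show", "LambdaGroup", function(object) {
  cat(sprintf("LambdaGroup '%s': %d atom(s), %d states (%s)\n", object@name,
              length(object@atomIds), ncol(object@stateCharges),
              paste(object@stateNames, collapse = "/")))
  cat("  reference pKas:", paste(signif(object@pKaRefs, 4), collapse = ", "),
      "\n  lambda:", paste(signif(object@lambda, 4), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "TitrationResult", function(object) {
  cat("TitrationResult:", length(object@pHValues), "pH values,",
      object@nReplicas, "replica(s)\n")
  f <- object@fits
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-12s pKa = %.3f +/- %.3f (95%% CI)\n",
                f$species[i], f$pKa[i], f$ci95[i]))
  invisible(object)
})

setMethod("show", "TiScanResult", function(object) {
  cat(sprintf("TiScanResult: %d grid point(s), arity %d, %d sample(s)/point\n",
              nrow(object@grid), ncol(object@grid), object@nSamples[1]))
  cat(sprintf("  grid range [%.2f, %.2f]; max |<dV/dx>| = %.3f kJ/mol\n",
              min(object@grid), max(object@grid),
              max(abs(object@meanGradients))))
  invisible(object)
})

setMethod("show", "LambdaTrajectory", function(object) {
  cat(sprintf("LambdaTrajectory: %d frames, %d coordinate(s), pH %.2f\n",
              length(object@time), ncol(object@lambdas), object@pH))
  invisible(object)
})
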