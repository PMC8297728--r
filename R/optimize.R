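.noTransfer <- function(msg) {
  stop(errorCondition(msg,
    class = c("lprosyNoTransfer", "error", "condition")))
}

## |cross| as a function of tau for a single-mixing experiment
.convObjective <- function(system, pair, experiment, clampWater = FALSE) {
  if (experiment == "noesy") {
    ops <- .noesyOps(system, clampWater)
    function(tau)
      unname(abs(.lprosyAccumulate(ops, pair[1], tau, 1L)[1L, pair[2]]))
  } else {
    liou <- buildLiouvillian(system, pair)
    function(tau) unname(abs(.tocsyAccumulate(liou, tau, 1L)[1L, "cross"]))
  }
}

#' Optimize the mixing time of a conventional experiment
#'
#' Maximizes the absolute cross amplitude for one (source, destination) pair
#' over the mixing time: a bracketing grid scan followed by golden-section
#' refinement.  The search is capped at `tauMax` (default 0.4 s); under fast
#' labile exchange the optimum collapses to much shorter mixings on its own.
#'
#' @param system a [SpinSystem-class].
#' @param pair `c(source, destination)`; the source must be labile.
#' @param experiment `"noesy"` or `"tocsy"`.
#' @param tauMax upper bound of the mixing-time search (s).
#' @param gridN coarse-grid size.
#' @param clampWater see [runConventionalNoesy()].
#' @return list with elements `tau` (s), `amplitude` (signed |max| with the
#'   display convention of the underlying run) and `objective`.
#' @examples
#' sys <- sugarSpinSystem(kex = 0, J = 5)
#' optimizeConventionalMixing(sys, c("OH", "CH"), "tocsy")$tau  # ~ 1/(2J)
#' @export
optimizeConventionalMixing <- function(system, pair,
                                       experiment = c("noesy", "tocsy"),
                                       tauMax = 0.4, gridN = 80L,
                                       clampWater = FALSE) {
  experiment <- match.arg(experiment)
  f <- .convObjective(system, pair, experiment, clampWater)
  taus <- seq(tauMax / gridN, tauMax, length.out = gridN)
  vals <- vapply(taus, f, numeric(1))
  if (max(vals) < 1e-15)
    .noTransfer("no transfer: cross amplitude is zero over the whole grid")
  i <- which.max(vals)
  lo <- if (i == 1L) 0 else taus[i - 1L]
  hi <- if (i == gridN) tauMax else taus[i + 1L]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-7)
  if (opt$objective >= vals[i])
    list(tau = opt$maximum, amplitude = opt$objective,
         objective = opt$objective)
  else
    list(tau = taus[i], amplitude = vals[i], objective = vals[i])
}

## accumulated |cross| over loops for a given per-loop mixing
.loopCurve <- function(system, pair, experiment, tau, maxLoops,
                       clampWater = FALSE, liou = NULL, ops = NULL) {
  if (experiment == "noesy") {
    if (is.null(ops)) ops <- .noesyOps(system, clampWater)
    unname(abs(.lprosyAccumulate(ops, pair[1], tau, maxLoops)[, pair[2]]))
  } else {
    if (is.null(liou)) liou <- buildLiouvillian(system, pair)
    unname(abs(.tocsyAccumulate(liou, tau, maxLoops)[, "cross"]))
  }
}

#' Jointly optimize an L-PROSY schedule
#'
#' Grid search over the loop count l1 (1..`maxLoops`) and the per-loop
#' mixing time (default 5-100 ms in 5 ms steps, refined ten-fold around the
#' coarse optimum), maximizing the accumulated cross amplitude.  All
#' optimizers in the package are deterministic given their grids.
#'
#' @inheritParams optimizeConventionalMixing
#' @param maxLoops largest loop count searched (default 30).
#' @param tauGrid per-loop mixing-time grid (s).
#' @param refine logical: refine the mixing grid ten-fold around the
#'   optimum.
#' @return list with `loops`, `tau` (s) and `amplitude`.
#' @export
optimizeLprosySchedule <- function(system, pair,
                                   experiment = c("noesy", "tocsy"),
                                   maxLoops = 30L,
                                   tauGrid = seq(0.005, 0.1, by = 0.005),
                                   refine = TRUE, clampWater = FALSE) {
  experiment <- match.arg(experiment)
  if (maxLoops < 1L) stop("maxLoops must be >= 1", call. = FALSE)
  liou <- if (experiment == "tocsy") buildLiouvillian(system, pair)
  ops <- if (experiment == "noesy") .noesyOps(system, clampWater)
  best <- list(loops = NA_integer_, tau = NA_real_, amplitude = -Inf)
  scan <- function(taus) {
    for (tau in taus) {
      curve <- .loopCurve(system, pair, experiment, tau, maxLoops,
                          clampWater, liou = liou, ops = ops)
      l <- which.max(curve)
      if (curve[l] > best$amplitude)
        best <<- list(loops = as.integer(l), tau = tau,
                      amplitude = curve[l])
    }
  }
  scan(tauGrid)
  if (!is.finite(best$amplitude) || best$amplitude < 1e-15)
    .noTransfer("no transfer: accumulated cross amplitude is zero")
  if (refine) {
    step <- if (length(tauGrid) > 1) min(diff(sort(tauGrid))) else
      best$tau / 2
    fine <- seq(best$tau - step, best$tau + step, by = step / 10)
    scan(fine[fine > 0])
  }
  best
}

#' Map L-PROSY enhancement over parameter grids
#'
#' For every (exchange rate, coupling) grid cell the conventional mixing and
#' the L-PROSY schedule are optimized independently and the fold enhancement
#' |L-PROSY| / |conventional| of the pair's cross-peak is recorded.  For
#' `experiment = "noesy"` the coupling axis is the cross-relaxation rate
#' sigma (s^-1); for `"tocsy"` it is J (Hz).  Cells without transfer are
#' returned as `NA` (undefined), never as zeros.
#'
#' @inheritParams optimizeLprosySchedule
#' @param kexGrid exchange rates (s^-1) for the labile source.
#' @param couplingGrid sigma values (s^-1, NOESY) or J values (Hz, TOCSY).
#' @return numeric matrix `length(kexGrid) x length(couplingGrid)` of fold
#'   factors, dimnames carrying the grid values.
#' @examples
#' sys <- sugarSpinSystem()
#' enhancementMap(sys, kexGrid = c(100, 1000), couplingGrid = c(2, 8),
#'                experiment = "tocsy", maxLoops = 10L)
#' @export
enhancementMap <- function(system, kexGrid, couplingGrid,
                           experiment = c("noesy", "tocsy"),
                           pair = c("OH", "CH"), maxLoops = 30L,
                           tauGrid = seq(0.005, 0.1, by = 0.005),
                           tauMax = 0.4) {
  experiment <- match.arg(experiment)
  if (!length(kexGrid) || !length(couplingGrid))
    stop("grids must be non-empty", call. = FALSE)
  p <- pools(system)
  wat <- p$name[p$kind == "water"][1]
  if (is.na(wat)) stop("system template needs a water pool", call. = FALSE)
  out <- matrix(NA_real_, length(kexGrid), length(couplingGrid),
                dimnames = list(signif(kexGrid, 6), signif(couplingGrid, 6)))
  for (i in seq_along(kexGrid)) {
    si <- setExchangeRate(system, pair[1], wat, kexGrid[i])
    for (j in seq_along(couplingGrid)) {
      sij <- if (experiment == "noesy")
        setCrossRelaxation(si, pair[1], pair[2], couplingGrid[j])
      else
        setJCoupling(si, pair[1], pair[2], couplingGrid[j])
      out[i, j] <- tryCatch({
        conv <- optimizeConventionalMixing(sij, pair, experiment,
                                           tauMax = tauMax)
        lp <- optimizeLprosySchedule(sij, pair, experiment,
                                     maxLoops = maxLoops, tauGrid = tauGrid)
        lp$amplitude / conv$amplitude
      }, lprosyNoTransfer = function(e) NA_real_)
    }
  }
  out
}
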