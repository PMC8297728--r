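.matexp <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
}

## exact affine propagator: returns function(M) for step tau under
## dM/dt = A M + b
.affineStep <- function(A, b, tau) {
  n <- nrow(A)
  P <- .matexp(rbind(cbind(A, b), 0) * tau)
  function(M) as.numeric(P %*% c(M, 1))[seq_len(n)]
}

#' Propagate longitudinal magnetization
#'
#' Exact affine matrix-exponential solution of dM/dt = A M + b for a time
#' `t >= 0`.  As `t` grows the solution relaxes to the thermal-equilibrium
#' fixed point of the generator.
#'
#' @param M0 magnetization vector at time zero (pool order of the generator).
#' @param gen a [LongitudinalGenerator-class].
#' @param t evolution time (s).
#' @return magnetization vector at time `t` (named by pool).
#' @examples
#' sys <- spinSystem(list(spinPool("A", "labile"), spinPool("B", "nonlabile")),
#'                   sigma = data.frame(a = "A", b = "B", value = -0.05))
#' gen <- buildGenerator(sys)
#' propagateLongitudinal(c(0, 1), gen, 0.5)
#' @export
propagateLongitudinal <- function(M0, gen, t) {
  stopifnot(is(gen, "LongitudinalGenerator"))
  if (length(t) != 1 || !is.finite(t) || t < 0)
    stop("evolution time must be a single non-negative number", call. = FALSE)
  if (length(M0) != nrow(gen@matrix))
    stop("M0 length does not match the generator", call. = FALSE)
  out <- if (t == 0) as.numeric(M0)
         else .affineStep(gen@matrix, gen@recovery, t)(M0)
  stats::setNames(out, gen@poolNames)
}

#' Construct a sequence schedule
#'
#' @param experiment `"conventional"` or `"lprosy"`.
#' @param targets labile pools addressed by the selective pulses.
#' @param mixingTime mixing time in seconds (per loop for L-PROSY).
#' @param loops L-PROSY loop count l1 (ignored, forced to 1, for
#'   conventional).
#' @param t1Max,t1Points indirect-dimension grid.
#' @return a [SequenceSchedule-class].
#' @examples
#' sequenceSchedule("lprosy", targets = "OH", mixingTime = 0.04, loops = 10)
#' @export
sequenceSchedule <- function(experiment = c("conventional", "lprosy"),
                             targets = character(), mixingTime = 0.1,
                             loops = 1L, t1Max = 0.05, t1Points = 128L) {
  experiment <- match.arg(experiment)
  if (experiment == "conventional") loops <- 1L
  new("SequenceSchedule", experiment = experiment,
      mixingTime = as.numeric(mixingTime), loops = as.integer(loops),
      t1Max = as.numeric(t1Max), t1Points = as.integer(t1Points),
      targets = as.character(targets))
}

setMethod("show", "SequenceSchedule", function(object) {
  cat(sprintf("SequenceSchedule: %s | mixing %.4g s x %d loop(s) | targets: %s\n",
              object@experiment, object@mixingTime, object@loops,
              paste(object@targets, collapse = ", ")))
})

.checkTargets <- function(system, targets) {
  p <- pools(system)
  if (!length(targets))
    stop("schedule declares no selective targets", call. = FALSE)
  bad <- setdiff(targets, p$name)
  if (length(bad))
    stop("unknown target pool '", bad[1], "'", call. = FALSE)
  notLabile <- targets[p$kind[match(targets, p$name)] != "labile"]
  if (length(notLabile))
    stop("selective targets must be labile pools; '", notLabile[1],
         "' is not", call. = FALSE)
  invisible(targets)
}

## Operators for the longitudinal engine.  clampWater freezes the water
## pool(s) exactly at equilibrium (ideal infinite reservoir).
.noesyOps <- function(system, clampWater = FALSE) {
  gen <- buildGenerator(system)
  A <- gen@matrix
  b <- gen@recovery
  p <- pools(system)
  wat <- which(p$kind == "water")
  if (clampWater && length(wat)) {
    A[wat, ] <- 0
    b[wat] <- 0
  }
  list(A = A, b = b, pools = p, water = wat, Meq = p$M0,
       kout = rowSums(system@kex))
}

## Core L-PROSY/conventional longitudinal accumulation for one source pool.
## Tracks (a) the physical magnetization M under the full affine flow,
## (b) the first-harmonic label vector L under the homogeneous flow, and
## (c) the still-encoded source content, which between projections decays
## only through exchange out of the source.  The fresh label drawn at each
## loop is the source polarization delivered by exchange since the previous
## projection; at k_ex = 0 no fresh label exists after loop 1, which is what
## makes a single long mixing optimal without repolarization.
## Returns a loops x n matrix of labeled amplitudes (fractions of the source
## equilibrium).
.lprosyAccumulate <- function(ops, source, tau, maxLoops) {
  n <- nrow(ops$A)
  src <- match(source, ops$pools$name)
  Phi <- .matexp(ops$A * tau)
  Meq <- ops$Meq
  stepM <- function(M) Meq + as.numeric(Phi %*% (M - Meq))
  kout <- ops$kout[src]
  M <- Meq
  L <- numeric(n)
  ehat <- 0
  out <- matrix(0, maxLoops, n,
                dimnames = list(NULL, ops$pools$name))
  decay <- exp(-kout * tau)
  for (l in seq_len(maxLoops)) {
    L[src] <- max(0, M[src] - ehat)
    if (length(ops$water)) L[ops$water] <- 0
    ehat <- M[src] * decay
    L <- as.numeric(Phi %*% L)
    M <- stepM(M)
    out[l, ] <- L / Meq[src]
  }
  out
}

.peakAmplitudes <- function(system, schedule, perSource, displaySign) {
  p <- pools(system)
  keep <- p$name[p$kind != "water"]
  diag <- vapply(schedule@targets, function(s) perSource[[s]][s],
                 numeric(1))
  cross <- do.call(rbind, lapply(schedule@targets, function(s) {
    dst <- setdiff(keep, s)
    data.frame(source = s, destination = dst,
               amplitude = displaySign * unname(perSource[[s]][dst]),
               stringsAsFactors = FALSE)
  }))
  new("PeakAmplitudes", diagonal = diag, cross = cross, schedule = schedule)
}

#' Simulate a conventional NOESY mixing
#'
#' Ideal selective labeling of the target labile pools (Ramsey amplitude
#' encoding, evaluated at the first t1 increment) followed by a single
#' mixing period under the full Solomon + exchange generator.  Cross-peak
#' amplitudes are the labeled magnetization arriving at each destination
#' pool, as a fraction of the source equilibrium.
#'
#' @param system a [SpinSystem-class].
#' @param schedule a conventional [SequenceSchedule-class]; `mixingTime` is
#'   the mixing period tau_m.
#' @param clampWater hold water exactly at equilibrium (ideal infinite
#'   reservoir).  Default `FALSE`: finite-pool water dynamics.
#' @param displaySign global display-sign convention applied to cross
#'   peaks.  With the default (+1) a negative cross-relaxation rate (fast
#'   tumbling) yields cross-peaks of opposite sign to the diagonal.
#' @return a [PeakAmplitudes-class].
#' @seealso [runLprosyNoesy()], [enhancement()]
#' @export
runConventionalNoesy <- function(system, schedule, clampWater = FALSE,
                                 displaySign = 1) {
  stopifnot(is(schedule, "SequenceSchedule"))
  if (schedule@experiment != "conventional")
    stop("schedule is not conventional", call. = FALSE)
  .checkTargets(system, schedule@targets)
  ops <- .noesyOps(system, clampWater)
  perSource <- lapply(stats::setNames(nm = schedule@targets), function(s)
    .lprosyAccumulate(ops, s, schedule@mixingTime, 1L)[1L, ])
  .peakAmplitudes(system, schedule, perSource, displaySign)
}

#' Simulate an L-PROSY NOESY schedule
#'
#' Repeats `loops` blocks of (selective re-labeling of the labile targets,
#' mixing of `mixingTime` seconds).  At each loop start the labile source is
#' projected: its z-magnetization is freshly labeled while accumulated
#' nonlabile z-magnetization carries over (and keeps relaxing during later
#' loops).  Fresh label is drawn from the exchange-replenished part of the
#' source polarization, so without exchange looping cannot beat a single
#' optimized mixing; with fast exchange the cross-peak accumulates over
#' loops toward its thermodynamic limit.
#'
#' @inheritParams runConventionalNoesy
#' @param schedule an lprosy [SequenceSchedule-class]: `mixingTime` is the
#'   per-loop mixing, `loops` the loop count l1.
#' @return a [PeakAmplitudes-class] with amplitudes after the final loop.
#' @examples
#' sys <- sugarSpinSystem(kex = 1000)
#' lp <- runLprosyNoesy(sys, sequenceSchedule("lprosy", "OH",
#'                                            mixingTime = 0.04, loops = 10))
#' peakTable(lp)
#' @export
runLprosyNoesy <- function(system, schedule, clampWater = FALSE,
                           displaySign = 1) {
  stopifnot(is(schedule, "SequenceSchedule"))
  if (schedule@experiment != "lprosy")
    stop("schedule is not lprosy", call. = FALSE)
  if (schedule@loops < 1L) stop("l1 must be >= 1", call. = FALSE)
  .checkTargets(system, schedule@targets)
  ops <- .noesyOps(system, clampWater)
  perSource <- lapply(stats::setNames(nm = schedule@targets), function(s)
    .lprosyAccumulate(ops, s, schedule@mixingTime,
                      schedule@loops)[schedule@loops, ])
  .peakAmplitudes(system, schedule, perSource, displaySign)
}

## ---- PeakAmplitudes accessors -------------------------------------------

#' Query simulated peak amplitudes
#'
#' @param pa a [PeakAmplitudes-class].
#' @param from,to source and destination pool names.
#' @param pool pool name.
#' @return numeric amplitude (fraction of source equilibrium).
#' @export
crossAmplitude <- function(pa, from, to) {
  stopifnot(is(pa, "PeakAmplitudes"))
  hit <- pa@cross$source == from & pa@cross$destination == to
  if (!any(hit))
    stop("no cross amplitude for ", from, " -> ", to, call. = FALSE)
  pa@cross$amplitude[hit][1]
}

#' @rdname crossAmplitude
#' @export
diagonalAmplitude <- function(pa, pool) {
  stopifnot(is(pa, "PeakAmplitudes"))
  if (!pool %in% names(pa@diagonal))
    stop("no diagonal amplitude for ", pool, call. = FALSE)
  unname(pa@diagonal[pool])
}

#' @rdname crossAmplitude
#' @export
peakTable <- function(pa) {
  stopifnot(is(pa, "PeakAmplitudes"))
  s <- pa@schedule
  d <- data.frame(source = names(pa@diagonal),
                  destination = names(pa@diagonal),
                  amplitude = unname(pa@diagonal), stringsAsFactors = FALSE)
  out <- rbind(d, pa@cross)
  out$experiment <- s@experiment
  out$mixing <- s@mixingTime
  out$loops <- s@loops
  rownames(out) <- NULL
  out
}

setMethod("show", "PeakAmplitudes", function(object) {
  cat(sprintf("PeakAmplitudes (%s, %d loop(s) x %.4g s):\n",
              object@schedule@experiment, object@schedule@loops,
              object@schedule@mixingTime))
  print(utils::head(peakTable(object), 10))
})

#' Fold enhancement of a cross-peak
#'
#' Ratio |L-PROSY| / |conventional| of the cross amplitudes for one peak,
#' each amplitude usually taken from its own individually optimized
#' schedule.  A zero conventional amplitude makes the enhancement undefined
#' and raises a condition of class `"lprosyUndefinedEnhancement"` (distinct
#' from numeric overflow).
#'
#' @param lp,conv [PeakAmplitudes-class] objects from the L-PROSY and
#'   conventional runs.
#' @param from,to the peak.
#' @return fold factor (>= 0).
#' @export
enhancement <- function(lp, conv, from, to) {
  a <- crossAmplitude(lp, from, to)
  b <- crossAmplitude(conv, from, to)
  if (b == 0)
    stop(errorCondition(
      paste0("undefined enhancement: conventional amplitude for ", from,
             " -> ", to, " is zero"),
      class = c("lprosyUndefinedEnhancement", "error", "condition")))
  abs(a) / abs(b)
}
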