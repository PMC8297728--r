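## Orthonormal product-operator basis for two spins-1/2: all Kronecker
## products of {E, Ix, Iy, Iz}, scaled to unit Hilbert-Schmidt norm.  The
## z-operator coefficients then equal pool magnetizations directly (I1z
## coefficient 1 at equilibrium).
.productBasis <- function() {
  E <- diag(2) + 0i
  Px <- matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i
  Py <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  Pz <- diag(c(0.5, -0.5)) + 0i
  single <- list(E = E, x = Px, y = Py, z = Pz)
  norms <- c(E = 2, x = 0.5, y = 0.5, z = 0.5)  # Tr(P^2)
  ops <- list()
  labels <- character()
  for (a in names(single)) for (b in names(single)) {
    B <- kronecker(single[[a]], single[[b]]) / sqrt(norms[[a]] * norms[[b]])
    ops[[length(ops) + 1L]] <- B
    labels <- c(labels, if (a == "E" && b == "E") "E"
                else if (b == "E") paste0("I1", a)
                else if (a == "E") paste0("I2", b)
                else paste0("2I1", a, "I2", b))
  }
  fac <- expand.grid(b = names(single), a = names(single),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  list(ops = ops, labels = labels, factors = fac[, c("a", "b")])
}

.hsInner <- function(A, B) sum(Conj(A) * B)

#' Build the Liouville-space superoperator for a labile/nonlabile pair
#'
#' Assembles the affine superoperator governing a two-spin subsystem (the
#' labile source spin and a J-coupled nonlabile spin) plus a scalar water
#' reservoir.  The coherent part is the isotropic-mixing Hamiltonian
#' `2*pi*J (I1.I2)` (idealized DIPSI2) or, with `mixingMode = "free"`, weak
#' coupling plus chemical-shift offsets.  Relaxation enters as R1/R2 decay
#' per operator factor; chemical exchange follows a stochastic-jump model:
#' every operator with a labile-spin factor decays at `k_ex` (which is what
#' averages away the J-coupling at fast exchange) and replacement
#' magnetization enters only as z-polarization from the water reservoir.
#'
#' @param system a [SpinSystem-class] containing the pair and, when the
#'   labile spin exchanges, a water pool.
#' @param pair `c(labile, nonlabile)` pool names; `J(pair)` must be defined
#'   (possibly zero) in the system.
#' @param mixingMode `"isotropic"` (DIPSI2 idealization) or `"free"`.
#' @return a [Liouvillian-class] (17-dimensional: 16 product operators plus
#'   the water z-magnetization).
#' @examples
#' sys <- sugarSpinSystem(kex = 0, J = 10)
#' L <- buildLiouvillian(sys, c("OH", "CH"))
#' @export
buildLiouvillian <- function(system, pair,
                             mixingMode = c("isotropic", "free")) {
  mixingMode <- match.arg(mixingMode)
  p <- pools(system)
  for (x in pair) if (!x %in% p$name)
    stop("unknown pool '", x, "'", call. = FALSE)
  i1 <- match(pair[1], p$name); i2 <- match(pair[2], p$name)
  if (p$kind[i1] != "labile")
    stop("pair[1] must be a labile pool", call. = FALSE)
  if (p$kind[i2] != "nonlabile")
    stop("pair[2] must be a nonlabile pool", call. = FALSE)
  J <- system@J[i1, i2]
  if (is.na(J)) stop("J undefined for pair", call. = FALSE)
  kex <- sum(system@kex[i1, ])
  wat <- which(p$kind == "water")
  if (kex > 0 && !length(wat))
    stop("labile exchange requires a water pool", call. = FALSE)
  Weq <- if (length(wat)) p$M0[wat[1]] else 1
  R1w <- if (length(wat)) p$R1[wat[1]] else 0

  bs <- .productBasis()
  nb <- length(bs$ops)
  E <- diag(2) + 0i
  Px <- matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i
  Py <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  Pz <- diag(c(0.5, -0.5)) + 0i
  H <- if (mixingMode == "isotropic") {
    2 * pi * J * (kronecker(Px, Px) + kronecker(Py, Py) + kronecker(Pz, Pz))
  } else {
    2 * pi * (p$offset[i1] * kronecker(Pz, E) + p$offset[i2] *
              kronecker(E, Pz) + J * kronecker(Pz, Pz))
  }
  S <- matrix(0, nb + 1L, nb + 1L)
  for (n in seq_len(nb)) {
    X <- -1i * (H %*% bs$ops[[n]] - bs$ops[[n]] %*% H)
    for (m in seq_len(nb)) {
      v <- .hsInner(bs$ops[[m]], X)
      if (Mod(v) > 1e-14) S[m, n] <- Re(v)
    }
  }
  ## incoherent rates per operator factor
  rate1 <- c(E = 0, x = p$R2[i1], y = p$R2[i1], z = p$R1[i1])
  rate2 <- c(E = 0, x = p$R2[i2], y = p$R2[i2], z = p$R1[i2])
  fac <- bs$factors
  r <- unname(rate1[fac$a] + rate2[fac$b]) + kex * (fac$a != "E")
  d <- diag(S)
  d[seq_len(nb)] <- d[seq_len(nb)] - r
  diag(S) <- d
  iz1 <- match("I1z", bs$labels); iz2 <- match("I2z", bs$labels)
  iw <- nb + 1L
  ## exchange replacement: labile z refilled from water; conservation flux
  ## into the water reservoir
  if (kex > 0) {
    S[iz1, iw] <- S[iz1, iw] + kex / Weq
    S[iw, iz1] <- S[iw, iz1] + kex
    S[iw, iw] <- S[iw, iw] - (R1w + kex / Weq)
  } else {
    S[iw, iw] <- -R1w
  }
  b <- numeric(nb + 1L)
  b[iz1] <- p$R1[i1]
  b[iz2] <- p$R1[i2]
  b[iw] <- R1w * Weq
  eq <- numeric(nb + 1L)
  eq[match("E", bs$labels)] <- 0.5
  eq[iz1] <- 1
  eq[iz2] <- 1
  eq[iw] <- Weq
  labels <- c(bs$labels, "W")
  dimnames(S) <- list(labels, labels)
  new("Liouvillian", matrix = S, recovery = b, basis = labels,
      pair = as.character(pair), eq = eq, kex = kex)
}

setMethod("show", "Liouvillian", function(object) {
  cat(sprintf("Liouvillian for pair %s (labile) - %s | k_ex = %g s^-1 | dim %d\n",
              object@pair[1], object@pair[2], object@kex,
              nrow(object@matrix)))
})

## L-PROSY / conventional TOCSY accumulation, same label bookkeeping as the
## longitudinal engine but in Liouville space.  Projection at each loop start
## keeps only E, I1z, I2z and W (z-filter; labile transverse memory and
## multi-spin terms are destroyed), relabels the labile z from its
## exchange-replenished part, and carries the accumulated labeled
## destination z over.
.tocsyAccumulate <- function(liou, tau, maxLoops) {
  A <- liou@matrix
  n <- nrow(A)
  iz1 <- match("I1z", liou@basis)
  iz2 <- match("I2z", liou@basis)
  keep <- match(c("E", "I1z", "I2z", "W"), liou@basis)
  Phi <- .matexp(A * tau)
  stepP <- .affineStep(A, liou@recovery, tau)
  p <- liou@eq
  L <- numeric(n)
  ehat <- 0
  decay <- exp(-liou@kex * tau)
  out <- matrix(0, maxLoops, 2, dimnames = list(NULL, c("diagonal", "cross")))
  for (l in seq_len(maxLoops)) {
    p[-keep] <- 0
    Lnew <- numeric(n)
    Lnew[iz2] <- L[iz2]
    Lnew[iz1] <- max(0, p[iz1] - ehat)
    ehat <- p[iz1] * decay
    L <- as.numeric(Phi %*% Lnew)
    p <- stepP(p)
    out[l, ] <- c(L[iz1], L[iz2])
  }
  out
}

.tocsyPeaks <- function(liou, schedule, amps) {
  pairName <- liou@pair
  cross <- data.frame(source = pairName[1], destination = pairName[2],
                      amplitude = unname(amps["cross"]),
                      stringsAsFactors = FALSE)
  new("PeakAmplitudes",
      diagonal = stats::setNames(unname(amps["diagonal"]), pairName[1]),
      cross = cross, schedule = schedule)
}

#' Simulate a conventional TOCSY mixing for a labile/nonlabile pair
#'
#' Single isotropic mixing of the schedule's `mixingTime` applied to the
#' selectively labeled labile spin.  Without exchange or relaxation the
#' transferred fraction follows the isotropic-mixing closed form
#' `sin^2(pi J tau)`; chemical exchange beyond ~J quenches the transfer by
#' averaging the coupling.
#'
#' @param system a [SpinSystem-class].
#' @param pair `c(labile, nonlabile)` pool names.
#' @param schedule a conventional [SequenceSchedule-class].
#' @param mixingMode passed to [buildLiouvillian()].
#' @return a [PeakAmplitudes-class].
#' @export
runConventionalTocsy <- function(system, pair, schedule,
                                 mixingMode = "isotropic") {
  stopifnot(is(schedule, "SequenceSchedule"))
  if (schedule@experiment != "conventional")
    stop("schedule is not conventional", call. = FALSE)
  liou <- buildLiouvillian(system, pair, mixingMode)
  amps <- .tocsyAccumulate(liou, schedule@mixingTime, 1L)[1L, ]
  .tocsyPeaks(liou, schedule, amps)
}

#' Simulate an L-PROSY TOCSY schedule
#'
#' Per loop the labile spin is re-polarized from water through chemical
#' exchange, freshly labeled, and mixed isotropically for the per-loop
#' mixing time; labeled z-magnetization accumulated on the nonlabile
#' destination carries over (and keeps relaxing) between loops.
#'
#' @inheritParams runConventionalTocsy
#' @param schedule an lprosy [SequenceSchedule-class].
#' @return a [PeakAmplitudes-class] after `loops` loops.
#' @examples
#' sys <- sugarSpinSystem(kex = 500, J = 5)
#' sch <- sequenceSchedule("lprosy", "OH", mixingTime = 0.02, loops = 20)
#' peakTable(runLprosyTocsy(sys, c("OH", "CH"), sch))
#' @export
runLprosyTocsy <- function(system, pair, schedule,
                           mixingMode = "isotropic") {
  stopifnot(is(schedule, "SequenceSchedule"))
  if (schedule@experiment != "lprosy")
    stop("schedule is not lprosy", call. = FALSE)
  if (schedule@loops < 1L) stop("l1 must be >= 1", call. = FALSE)
  liou <- buildLiouvillian(system, pair, mixingMode)
  amps <- .tocsyAccumulate(liou, schedule@mixingTime,
                           schedule@loops)[schedule@loops, ]
  .tocsyPeaks(liou, schedule, amps)
}
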