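#' Karplus parameterization for vicinal proton couplings
#'
#' Coefficients of the three-bond coupling curve
#' `J(omega) = C + A cos^2(omega) + B cos(omega)` (Hz).  The defaults are
#' the H-C-C-H parameterization used for glycerol-chain torsions in
#' sialic-acid oligomers: C = 0.48, A = 10.18, B = -0.03 Hz.
#'
#' @param A coefficient of cos^2 (Hz).
#' @param B coefficient of cos (Hz).
#' @param C constant term (Hz).
#' @return list with class `"karplusParams"`.
#' @export
karplusParams <- function(A = 10.18, B = -0.03, C = 0.48) {
  structure(list(A = A, B = B, C = C), class = "karplusParams")
}

#' Evaluate the Karplus curve
#'
#' @param omega dihedral angle(s) in degrees (IUPAC signed convention).
#' @param params a [karplusParams()] set.
#' @return predicted 3J coupling(s) in Hz.  The curve is an even function
#'   of omega; at omega = +-90 degrees the default parameterization gives
#'   0.48 Hz, well under 2 Hz.
#' @examples
#' karplusJ(c(-90, 0, 90))
#' @export
karplusJ <- function(omega, params = karplusParams()) {
  stopifnot(all(is.finite(omega)))
  co <- cos(omega * pi / 180)
  params$C + params$A * co^2 + params$B * co
}

.wrapDeg <- function(x) ((x + 180) %% 360) - 180

#' Torsion angles consistent with an observed coupling
#'
#' Inverts the Karplus curve numerically: returns all omega in
#' [-180, 180) whose predicted coupling lies within `tolerance` of
#' `jObs`, merged into contiguous intervals (wrapping across the -180/180
#' boundary).  An observed value above the curve's maximum (or below its
#' minimum) returns an empty set.
#'
#' @param jObs observed 3J (Hz).
#' @param tolerance matching tolerance (Hz), > 0.
#' @param params a [karplusParams()] set.
#' @param gridStep scan resolution (degrees).
#' @return data.frame with columns `lower`, `upper` (degrees); zero rows if
#'   no torsion is compatible.
#' @examples
#' torsionCandidates(0.48, 0.01)   # intervals containing +-90 degrees
#' @export
torsionCandidates <- function(jObs, tolerance, params = karplusParams(),
                              gridStep = 0.01) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  om <- seq(-180, 180 - gridStep, by = gridStep)
  ok <- abs(karplusJ(om, params) - jObs) <= tolerance
  if (!any(ok)) return(data.frame(lower = numeric(), upper = numeric()))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  runs <- data.frame(lower = om[starts[r$values]], upper = om[ends[r$values]])
  ## merge a run touching -180 with one touching +180 (wrap-around)
  n <- nrow(runs)
  if (n > 1 && runs$lower[1] == -180 &&
      runs$upper[n] == om[length(om)]) {
    runs$lower[1] <- runs$lower[n]
    runs <- runs[-n, , drop = FALSE]
  }
  rownames(runs) <- NULL
  runs
}

#' Effective NOE distance from a conformer ensemble
#'
#' Computes the NOE-weighted ensemble average `(mean(r^-6))^(-1/6)` over
#' frames, the quantity a cross-relaxation-derived distance reports; it is
#' dominated by the shortest conformer distances and always lies between
#' the per-frame minimum and maximum (power-mean bounds).  When either
#' selection matches several protons (e.g. H3 axial/equatorial or the H9
#' pair), the shortest distance in each frame is used.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param atomsA,atomsB atom selections: integer indices or `elety` names
#'   (each may match several atoms).
#' @return effective distance in Angstrom.
#' @examples
#' ens <- generateSyntheticEnsemble(10, 6, mode = "single-well", noise = 0.1,
#'                                  seed = 1)
#' effectiveNoeDistance(ens, 1, 4)
#' @export
effectiveNoeDistance <- function(ensemble, atomsA, atomsB) {
  ia <- .resolveAtoms(ensemble, atomsA)
  ib <- .resolveAtoms(ensemble, atomsB)
  nf <- dim(ensemble@coords)[1]
  r <- vapply(seq_len(nf), function(f) {
    xa <- ensemble@coords[f, ia, , drop = FALSE]
    xb <- ensemble@coords[f, ib, , drop = FALSE]
    dmin <- Inf
    for (i in seq_along(ia)) for (j in seq_along(ib)) {
      d <- sqrt(sum((xa[1, i, ] - xb[1, j, ])^2))
      if (d < dmin) dmin <- d
    }
    dmin
  }, numeric(1))
  if (any(r == 0)) stop("zero interatomic distance in ensemble",
                        call. = FALSE)
  mean(r^-6)^(-1 / 6)
}

#' Geometric hydrogen-bond criteria
#'
#' Defaults follow the standard geometric definition used for MD
#' trajectories of glycans: donor-acceptor distance d_DA <= 3.0 Angstrom
#' and donor-hydrogen-acceptor angle theta >= 135 degrees (180 = linear).
#' Comparisons are inclusive at the boundary.
#'
#' @param d_DA_max maximum donor-acceptor distance (Angstrom).
#' @param theta_DHA_min minimum D-H...A angle (degrees).
#' @export
hBondCriteria <- function(d_DA_max = 3.0, theta_DHA_min = 135) {
  structure(list(d_DA_max = d_DA_max, theta_DHA_min = theta_DHA_min),
            class = "hBondCriteria")
}

#' Detect hydrogen bonds in a conformer ensemble
#'
#' A bond is recorded in a frame when `d_DA <= d_DA_max` AND
#' `theta_DHA >= theta_DHA_min` (both inclusive); occupancy is the fraction
#' of frames in which a donor/acceptor pair satisfies both.  The angle is
#' evaluated at the donor hydrogen between the H->D and H->A directions.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param donors data.frame with columns `donor` and `hydrogen` (indices or
#'   `elety` names resolving to single atoms).  A donor without an attached
#'   hydrogen is an error.
#' @param acceptors vector of acceptor atoms (indices or `elety` names).
#' @param criteria a [hBondCriteria()] set.
#' @return data.frame: `donor`, `hydrogen`, `acceptor`, `occupancy`,
#'   `meanDist`, `meanAngle` (means over all frames).
#' @export
detectHbonds <- function(ensemble, donors, acceptors,
                         criteria = hBondCriteria()) {
  if (!all(c("donor", "hydrogen") %in% names(donors)))
    stop("donors must have columns 'donor' and 'hydrogen'", call. = FALSE)
  if (any(is.na(donors$hydrogen)))
    stop("donor without attached hydrogen", call. = FALSE)
  nf <- dim(ensemble@coords)[1]
  rows <- list()
  for (di in seq_len(nrow(donors))) {
    id <- .resolveAtoms(ensemble, donors$donor[di], single = TRUE)
    ih <- .resolveAtoms(ensemble, donors$hydrogen[di], single = TRUE)
    for (acc in acceptors) {
      ia <- .resolveAtoms(ensemble, acc, single = TRUE)
      if (ia == id) next
      d <- ang <- numeric(nf)
      for (f in seq_len(nf)) {
        D <- ensemble@coords[f, id, ]
        H <- ensemble@coords[f, ih, ]
        A <- ensemble@coords[f, ia, ]
        d[f] <- sqrt(sum((D - A)^2))
        u <- D - H; v <- A - H
        ang[f] <- acos(pmin(1, pmax(-1, sum(u * v) /
                     sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      }
      hit <- d <= criteria$d_DA_max & ang >= criteria$theta_DHA_min
      rows[[length(rows) + 1L]] <- data.frame(
        donor = donors$donor[di], hydrogen = donors$hydrogen[di],
        acceptor = acc, occupancy = mean(hit), meanDist = mean(d),
        meanAngle = mean(ang), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Arrhenius scaling of an exchange rate
#'
#' Translates an exchange rate measured at a reference temperature to
#' another temperature through thermal activation:
#' `k(T) = k_ref * exp(-Ea/R * (1/T - 1/T_ref))`, the scaling used to carry
#' hydroxyl exchange rates determined at -10 degC to warmer conditions.
#'
#' @param kRef rate at the reference temperature (s^-1).
#' @param tRef,t reference and target temperatures (K, > 0).
#' @param ea activation energy (kJ/mol, >= 0); not determined by the
#'   experiments modeled here, so always an explicit input.
#' @return rate at `t` (s^-1).
#' @examples
#' arrheniusScale(100, 263.15, 278.15, ea = 20)
#' @export
arrheniusScale <- function(kRef, tRef, t, ea) {
  if (any(c(tRef, t) <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
  if (ea < 0) stop("activation energy must be >= 0", call. = FALSE)
  R <- 8.314462618e-3  # kJ/(mol K)
  kRef * exp(-ea / R * (1 / t - 1 / tRef))
}

#' Temperature coefficient of a chemical shift
#'
#' Least-squares slope of shift versus temperature in ppb/K (negative =
#' upfield with warming).  Small magnitudes for labile protons are a
#' classical indicator of hydrogen bonding.
#'
#' @param shifts chemical shifts (ppm).
#' @param temps temperatures (K), at least two distinct values.
#' @return list with `slope` (ppb/K), `se` (standard error, ppb/K; NA with
#'   only two points) and the underlying `fit`.
#' @examples
#' tempCoefficient(c(6.00, 5.95), c(278, 288))$slope   # -5 ppb/K
#' @export
tempCoefficient <- function(shifts, temps) {
  if (length(shifts) != length(temps) || length(shifts) < 2)
    stop("need >= 2 (shift, temperature) points", call. = FALSE)
  if (length(unique(temps)) < 2)
    stop("degenerate temperatures", call. = FALSE)
  fit <- stats::lm(I(shifts * 1000) ~ temps)
  ## noiseless input produces a perfect fit; the warning is uninformative
  s <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(s["temps", "Estimate"]),
       se = if (nrow(s) > 1 && length(shifts) > 2)
         unname(s["temps", "Std. Error"]) else NA_real_,
       fit = fit)
}

#' Fit a Stejskal-Tanner diffusion decay
#'
#' Nonlinear least-squares fit of the pulsed-field-gradient attenuation
#' `A(g) = A0 * exp(-D * gamma^2 g^2 delta^2 (Delta - delta/3))`, seeded by
#' the exact log-linear solution.  The ratio of two diffusion coefficients
#' equals the inverse ratio of hydrodynamic radii
#' (`D_ref / D_analyte = Rh_analyte / Rh_ref`), which is how a reference
#' such as DSS converts a fitted D into a relative molecular size.
#'
#' @param areas peak areas at each gradient strength.
#' @param gradients gradient strengths (G/cm), >= 3 points.
#' @param delta gradient pulse duration (s).
#' @param Delta diffusion delay (s).
#' @param gamma gyromagnetic ratio (rad s^-1 G^-1; default 1H).
#' @return list with `D` (cm^2/s), `se`, `A0` and the `fit` object.
#' @examples
#' g <- seq(2, 50, length.out = 8)
#' b <- (26752.218744)^2 * g^2 * 0.002^2 * (0.1 - 0.002 / 3)
#' a <- 10 * exp(-3e-6 * b)
#' stejskalTannerFit(a, g, delta = 0.002, Delta = 0.1)$D
#' @export
stejskalTannerFit <- function(areas, gradients, delta, Delta,
                              gamma = 26752.218744) {
  if (length(areas) != length(gradients) || length(gradients) < 3)
    stop("need >= 3 gradient points", call. = FALSE)
  if (any(areas <= 0)) stop("peak areas must be positive", call. = FALSE)
  b <- gamma^2 * gradients^2 * delta^2 * (Delta - delta / 3)
  lin <- stats::lm(log(areas) ~ b)
  Dstart <- -unname(stats::coef(lin)[2])
  if (Dstart <= 0)
    stop(errorCondition("non-decaying data: fitted attenuation is not positive",
      class = c("lprosyNonDecaying", "error", "condition")))
  A0start <- exp(unname(stats::coef(lin)[1]))
  fit <- minpack.lm::nlsLM(areas ~ A0 * exp(-D * b),
                           start = list(A0 = A0start, D = Dstart),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  list(D = cf["D", "Estimate"], se = cf["D", "Std. Error"],
       A0 = cf["A0", "Estimate"], fit = fit)
}

#' Ratio of hydrodynamic radii from a diffusion-coefficient ratio
#'
#' @param dRef,dAnalyte fitted diffusion coefficients of the reference and
#'   the analyte.
#' @return `Rh_analyte / Rh_ref = D_ref / D_analyte`.
#' @export
hydrodynamicRadiusRatio <- function(dRef, dAnalyte) dRef / dAnalyte

#' Build a restraint table for structure calculation
#'
#' NOE rows receive bounds of the calculated distance +-`distanceMargin`
#' (1 Angstrom default); torsion rows receive the target value
#' +-`torsionWindow` (30 degrees default), all angles wrapped to
#' [-180, 180).  Degenerate torsions (the +-90 degree solutions of a
#' symmetric Karplus reading, e.g. H6-C6-C7-H7) emit both branches as
#' separate rows when `degenerate` is TRUE.
#'
#' @param noe data.frame with columns `atomA`, `atomB`, `distance`
#'   (Angstrom, > 0) and optionally `source`.
#' @param torsions data.frame with columns `atoms`, `target` (degrees),
#'   optionally `degenerate` (logical) and `source`.
#' @param distanceMargin half-width of the distance bounds (Angstrom).
#' @param torsionWindow half-width of the torsion window (degrees).
#' @return a [RestraintTable-class].
#' @examples
#' rt <- buildRestraints(
#'   noe = data.frame(atomA = "IIOH7", atomB = "IIIH3", distance = 3.2),
#'   torsions = data.frame(atoms = "H6-C6-C7-H7", target = 90,
#'                         degenerate = TRUE))
#' rt@noe$lower   # 2.2
#' @export
buildRestraints <- function(noe = NULL, torsions = NULL,
                            distanceMargin = 1, torsionWindow = 30) {
  noeTab <- data.frame(atomA = character(), atomB = character(),
                       distance = numeric(), lower = numeric(),
                       upper = numeric(), source = character())
  if (!is.null(noe) && nrow(noe)) {
    if (any(noe$distance <= 0))
      stop("NOE distances must be > 0", call. = FALSE)
    noeTab <- data.frame(
      atomA = noe$atomA, atomB = noe$atomB, distance = noe$distance,
      lower = pmax(noe$distance - distanceMargin, 0),
      upper = noe$distance + distanceMargin,
      source = if ("source" %in% names(noe)) noe$source else "noe",
      stringsAsFactors = FALSE)
  }
  torTab <- data.frame(atoms = character(), target = numeric(),
                       lower = numeric(), upper = numeric(),
                       source = character())
  if (!is.null(torsions) && nrow(torsions)) {
    deg <- if ("degenerate" %in% names(torsions)) torsions$degenerate
           else rep(FALSE, nrow(torsions))
    rows <- list()
    for (r in seq_len(nrow(torsions))) {
      targets <- if (isTRUE(deg[r]))
        c(abs(torsions$target[r]), -abs(torsions$target[r]))
      else torsions$target[r]
      for (tg in targets)
        rows[[length(rows) + 1L]] <- data.frame(
          atoms = torsions$atoms[r], target = .wrapDeg(tg),
          lower = .wrapDeg(tg - torsionWindow),
          upper = .wrapDeg(tg + torsionWindow),
          source = if ("source" %in% names(torsions)) torsions$source[r]
                   else "torsion",
          stringsAsFactors = FALSE)
    }
    torTab <- do.call(rbind, rows)
  }
  new("RestraintTable", noe = noeTab, torsions = torTab)
}

setMethod("show", "RestraintTable", function(object) {
  cat("RestraintTable:", nrow(object@noe), "NOE distance rows,",
      nrow(object@torsions), "torsion rows\n")
})
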