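#' @import methods
NULL

.POOL_KINDS <- c("labile", "water", "nonlabile")

#' SpinSystem: an exchange-coupled network of longitudinal proton pools
#'
#' A `SpinSystem` collects the pools (labile, water and nonlabile proton
#' sites) together with the pairwise parameters that drive magnetization
#' transfer between them: chemical-exchange rates (s^-1), cross-relaxation
#' rates sigma (s^-1, signed) and scalar couplings J (Hz).  All rates are in
#' s^-1, couplings in Hz and times in seconds throughout the package; no unit
#' inference is performed.
#'
#' Exchange is only meaningful for pairs in which at least one partner is a
#' labile or water pool, and the stored rate matrix always satisfies detailed
#' balance, `k[a,b] * M0[a] == k[b,a] * M0[b]`.  Reverse rates omitted at
#' construction time are filled in from this relation.
#'
#' @slot pools data.frame with columns `name`, `kind` (one of `"labile"`,
#'   `"water"`, `"nonlabile"`), `M0` (equilibrium magnetization, proportional
#'   to pool population), `R1`, `R2` (s^-1) and `offset` (Hz).
#' @slot kex directed exchange-rate matrix, `kex[i, j]` = rate i -> j (s^-1).
#' @slot sigma symmetric cross-relaxation matrix (s^-1, signed).
#' @slot J symmetric scalar-coupling matrix (Hz), zero diagonal.
#'
#' @seealso [spinSystem()], [buildGenerator()], [thermalEquilibrium()]
#' @export
setClass("SpinSystem",
  representation(pools = "data.frame", kex = "matrix",
                 sigma = "matrix", J = "matrix"))

setValidity("SpinSystem", function(object) {
  p <- object@pools
  msg <- character()
  need <- c("name", "kind", "M0", "R1", "R2", "offset")
  if (!all(need %in% names(p)))
    return(paste("pools must have columns", paste(need, collapse = ", ")))
  n <- nrow(p)
  if (n < 1) msg <- c(msg, "at least one pool is required")
  if (anyDuplicated(p$name)) msg <- c(msg, "pool names must be unique")
  if (!all(p$kind %in% .POOL_KINDS))
    msg <- c(msg, "unknown pool kind")
  if (any(!is.finite(p$M0)) || any(p$M0 <= 0))
    msg <- c(msg, "equilibrium magnetization must be positive and finite")
  if (any(!is.finite(p$R1)) || any(p$R1 <= 0))
    msg <- c(msg, "R1 must be positive and finite")
  for (m in list(object@kex, object@sigma, object@J))
    if (!all(dim(m) == c(n, n)))
      msg <- c(msg, "rate matrices must be n x n")
  if (length(msg)) return(msg)
  if (any(object@kex < 0)) msg <- c(msg, "exchange rates must be >= 0")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-12)
    msg <- c(msg, "sigma must be symmetric")
  if (max(abs(object@J - t(object@J))) > 1e-12)
    msg <- c(msg, "J must be symmetric")
  if (any(abs(diag(object@J)) > 0)) msg <- c(msg, "J diagonal must be zero")
  ## exchange only between pairs involving a labile or water pool
  exch <- which(object@kex > 0, arr.ind = TRUE)
  if (nrow(exch)) {
    bad <- p$kind[exch[, 1]] == "nonlabile" & p$kind[exch[, 2]] == "nonlabile"
    if (any(bad))
      msg <- c(msg, "exchange declared between two nonlabile pools")
    ## detailed balance
    db <- abs(object@kex[exch] * p$M0[exch[, 1]] -
              object@kex[cbind(exch[, 2], exch[, 1])] * p$M0[exch[, 2]])
    scale <- pmax(object@kex[exch] * p$M0[exch[, 1]], 1)
    if (any(db / scale > 1e-9))
      msg <- c(msg, "exchange rates violate detailed balance")
  }
  if (length(msg)) msg else TRUE
})

#' LongitudinalGenerator: the affine evolution of z-magnetization
#'
#' Holds the rate matrix A and recovery vector b of the longitudinal
#' Bloch-McConnell/Solomon equations dM/dt = A M + b.  The recovery vector is
#' constructed so that the thermal-equilibrium magnetization is the unique
#' fixed point of the affine flow.
#'
#' @slot matrix n x n rate generator (s^-1).
#' @slot recovery inhomogeneous term restoring thermal equilibrium.
#' @slot poolNames pool labels, in matrix order.
#' @seealso [buildGenerator()], [propagateLongitudinal()]
#' @export
setClass("LongitudinalGenerator",
  representation(matrix = "matrix", recovery = "numeric",
                 poolNames = "character"))

#' SequenceSchedule: descriptor of a NOESY/TOCSY acquisition scheme
#'
#' @slot experiment `"conventional"` (one long mixing) or `"lprosy"`
#'   (`loops` repetitions of a selective excite-evolve-store block followed by
#'   `mixingTime` of mixing each).
#' @slot mixingTime mixing time in seconds; for L-PROSY this is the per-loop
#'   mixing time.
#' @slot loops number of L-PROSY loops l1 (1 for conventional).
#' @slot t1Max,t1Points indirect-dimension grid (Ramsey amplitude encoding).
#'   Peak amplitudes are reported at the first t1 increment.
#' @slot targets labile pools addressed by the selective pulses.
#' @export
setClass("SequenceSchedule",
  representation(experiment = "character", mixingTime = "numeric",
                 loops = "integer", t1Max = "numeric", t1Points = "integer",
                 targets = "character"))

setValidity("SequenceSchedule", function(object) {
  msg <- character()
  if (!object@experiment %in% c("conventional", "lprosy"))
    msg <- c(msg, "experiment must be 'conventional' or 'lprosy'")
  if (length(object@mixingTime) != 1 || !is.finite(object@mixingTime) ||
      object@mixingTime < 0)
    msg <- c(msg, "mixingTime must be a single non-negative number")
  if (object@loops < 1L) msg <- c(msg, "loop count l1 must be >= 1")
  if (object@t1Max < 0) msg <- c(msg, "t1Max must be >= 0")
  if (object@t1Points < 1L) msg <- c(msg, "t1Points must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PeakAmplitudes: diagonal and cross-peak amplitudes of a simulated run
#'
#' Amplitudes are dimensionless fractions of the source pool's equilibrium
#' magnetization, evaluated at the first t1 increment, so that |amplitude|
#' is bounded by 1 for a normalized system.
#'
#' @slot diagonal named numeric, diagonal amplitude per source pool.
#' @slot cross data.frame with columns `source`, `destination`, `amplitude`.
#' @slot schedule the [SequenceSchedule-class] that produced the amplitudes.
#' @seealso [runConventionalNoesy()], [runLprosyNoesy()], [enhancement()]
#' @export
setClass("PeakAmplitudes",
  representation(diagonal = "numeric", cross = "data.frame",
                 schedule = "SequenceSchedule"))

#' Liouvillian: product-operator superoperator for a labile/nonlabile pair
#'
#' Represents the longitudinal + coherence dynamics of a two-spin subsystem
#' (labile spin 1, nonlabile spin 2) coupled to a scalar water reservoir, in
#' the 16-member orthonormal product-operator basis augmented by the water
#' z-magnetization.  The coherent part is either the isotropic-mixing
#' Hamiltonian 2*pi*J (I1.I2) (idealized DIPSI2) or free evolution; exchange
#' follows a stochastic-jump model in which every labile-spin operator decays
#' at k_ex and replacement magnetization enters as z-polarization from water.
#'
#' @slot matrix homogeneous part of the affine superoperator (17 x 17).
#' @slot recovery inhomogeneous recovery vector.
#' @slot basis product-operator labels (plus `"W"`).
#' @slot pair `c(labile, nonlabile)` pool names.
#' @slot eq equilibrium coefficient vector.
#' @slot kex total exchange rate of the labile spin (s^-1).
#' @export
setClass("Liouvillian",
  representation(matrix = "matrix", recovery = "numeric", basis = "character",
                 pair = "character", eq = "numeric", kex = "numeric"))

#' ConformerEnsemble: frames x atoms x 3 coordinates with atom labels
#'
#' @slot coords numeric array `[frame, atom, xyz]` in Angstrom.
#' @slot atoms data.frame with columns `eleno`, `elety`, `resid`, `resno`,
#'   `chain`, `o`, `b` (occupancy and B-factor are carried through untouched).
#' @slot stridePs picoseconds per frame (NA when not applicable).
#' @seealso [conformerEnsemble()], [readEnsemblePDB()], [rmsd2dMap()]
#' @export
setClass("ConformerEnsemble",
  representation(coords = "array", atoms = "data.frame", stridePs = "numeric"))

setValidity("ConformerEnsemble", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3 || d[3] != 3)
    return("coords must be a frames x atoms x 3 array")
  if (d[1] < 1) msg <- c(msg, "at least one frame is required")
  if (nrow(object@atoms) != d[2])
    msg <- c(msg, "atom table does not match coordinate dimension")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' ClusterReport: cluster assignments and representatives for an ensemble
#'
#' @slot assignments integer cluster id per frame; NA marks frames assigned to
#'   no cluster ("exceptions").
#' @slot fractions named numeric, fraction of the trajectory per cluster
#'   (sums to <= 1 when frames are unassigned).
#' @slot representatives list of representative models: medoid frame indices
#'   (cutoff clustering) or averaged reference coordinate matrices
#'   ([representativeModels()]).
#' @slot method character description of the grouping rule.
#' @export
setClass("ClusterReport",
  representation(assignments = "integer", fractions = "numeric",
                 representatives = "list", method = "character"))

#' RestraintTable: NOE distance and torsion restraints for structure
#' calculation
#'
#' Distance rows carry the calculated effective distance with +-1 Angstrom
#' default bounds; torsion rows carry the target angle with a +-30 degree
#' default window (wrapped to [-180, 180)).  Degenerate +-90 degree torsions
#' emit one row per branch.
#'
#' @slot noe data.frame: `atomA`, `atomB`, `distance`, `lower`, `upper`,
#'   `source`.
#' @slot torsions data.frame: `atoms`, `target`, `lower`, `upper`, `source`.
#' @seealso [buildRestraints()]
#' @export
setClass("RestraintTable",
  representation(noe = "data.frame", torsions = "data.frame"))

setValidity("RestraintTable", function(object) {
  if (nrow(object@noe) &&
      (any(object@noe$lower > object@noe$distance) ||
       any(object@noe$distance > object@noe$upper)))
    return("NOE bounds must satisfy lower <= distance <= upper")
  TRUE
})
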