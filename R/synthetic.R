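## run expr under a temporary seed, restoring global RNG state afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Canonical hydroxyl / water / aliphatic three-pool system
#'
#' Deterministic convenience constructor for the OH-W-CH system used
#' throughout the package: a labile hydroxyl exchanging with a large water
#' pool and cross-relaxing / J-coupled to a nonlabile aliphatic proton.
#' Water is a finite but very large pool (default 1000 x the hydroxyl);
#' increasing `waterRatio` recovers the ideal infinite-reservoir limit.
#'
#' @param kex OH -> water exchange rate (s^-1).
#' @param sigma OH-CH cross-relaxation rate (s^-1; negative in the
#'   fast-tumbling regime).
#' @param J OH-CH scalar coupling (Hz).
#' @param R1,R1w longitudinal rates of the solute protons and of water
#'   (s^-1).
#' @param R2 transverse rate of the solute protons (s^-1; Liouville engine
#'   only).
#' @param waterRatio water pool size relative to the hydroxyl pool.
#' @return a [SpinSystem-class] with pools `OH`, `W`, `CH`.
#' @export
sugarSpinSystem <- function(kex = 200, sigma = -0.05, J = 5, R1 = 1,
                            R1w = 0.3, R2 = 10, waterRatio = 1000) {
  spinSystem(
    list(spinPool("OH", "labile", M0 = 1, R1 = R1, R2 = R2, offset = 500),
         spinPool("W", "water", M0 = waterRatio, R1 = R1w, R2 = R1w),
         spinPool("CH", "nonlabile", M0 = 1, R1 = R1, R2 = R2, offset = -800)),
    exchange = if (kex > 0) data.frame(from = "OH", to = "W", k = kex),
    sigma = data.frame(a = "OH", b = "CH", value = sigma),
    J = data.frame(a = "OH", b = "CH", value = J))
}

#' Generate a synthetic spin system
#'
#' Preset-driven random systems for simulation studies.  The `sugar-OH`
#' preset draws the hydroxyl exchange rate log-uniformly over the
#' room-temperature saccharide range 10-1000 s^-1; `amide` draws over the
#' slower 1-100 s^-1 range typical of backbone NH sites.  `custom` applies
#' overrides to the defaults without drawing anything.
#'
#' @param preset `"sugar-OH"`, `"amide"` or `"custom"`.
#' @param overrides named list overriding any [sugarSpinSystem()] argument
#'   (e.g. `list(kex = 0)` for a no-exchange control).
#' @param seed integer seed; the same seed reproduces the same system.
#' @return a [SpinSystem-class].
#' @examples
#' generateSyntheticSpinSystem("sugar-OH", seed = 1)
#' @export
generateSyntheticSpinSystem <- function(preset = c("sugar-OH", "amide",
                                                   "custom"),
                                        overrides = list(), seed = NULL) {
  preset <- match.arg(preset)
  args <- .withSeed(seed, switch(preset,
    "sugar-OH" = list(kex = 10^stats::runif(1, 1, 3), sigma = -0.05, J = 5,
                      R1 = 1, R2 = 30),
    "amide" = list(kex = 10^stats::runif(1, 0, 2), sigma = -0.1, J = 7,
                   R1 = 1.5, R2 = 15),
    "custom" = list()))
  args[names(overrides)] <- overrides
  do.call(sugarSpinSystem, args)
}

## rigid template: an irregular 3D helix-like chain, deterministic
.chainTemplate <- function(nAtoms) {
  i <- seq_len(nAtoms)
  cbind(5 * cos(0.9 * i) + 0.8 * i,
        5 * sin(0.9 * i),
        2.5 * i + 1.1 * sin(2.1 * i))
}

## rotate atoms `moving` about the axis p2->p3 by angle deg
.rotateAboutBond <- function(X, i2, i3, moving, deg) {
  ax <- X[i3, ] - X[i2, ]
  ax <- ax / sqrt(sum(ax^2))
  th <- deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  X[moving, ] <- sweep(sweep(X[moving, , drop = FALSE], 2, X[i3, ]) %*% t(R),
                       2, X[i3, ], FUN = "+")
  X
}

#' Generate a synthetic conformer ensemble
#'
#' Deterministic (under `seed`) coordinate ensembles for testing the
#' geometry analytics without any external trajectory:
#' \describe{
#'   \item{`single-well`}{one rigid template plus isotropic Gaussian
#'     coordinate noise.}
#'   \item{`two-state`}{two rigid templates (the second has its outer half
#'     rotated 120 degrees about an internal bond) drawn i.i.d. with
#'     mixture fraction `mixture`, plus noise.}
#'   \item{`uniform-torsion`}{the central dihedral of the chain drawn
#'     uniformly over [-180, 180) each frame, plus noise.}
#' }
#'
#' @param nFrames,nAtoms ensemble dimensions (`nAtoms >= 6`).
#' @param mode one of the modes above.
#' @param noise Gaussian coordinate noise s.d. (Angstrom).
#' @param mixture fraction of frames in state A (two-state mode).
#' @param seed integer seed.
#' @return a [ConformerEnsemble-class]; for `two-state` the drawn state per
#'   frame is in attribute `"state"` of the coords array... see Details.
#' @details The per-frame state labels of the `two-state` mode are returned
#'   in the `stridePs`-independent attribute `state` attached to the
#'   ensemble object (`attr(ens, "state")`).
#' @examples
#' ens <- generateSyntheticEnsemble(100, 8, mode = "two-state", noise = 0.2,
#'                                  mixture = 0.7, seed = 7)
#' table(attr(ens, "state"))
#' @export
generateSyntheticEnsemble <- function(nFrames, nAtoms = 12,
                                      mode = c("single-well", "two-state",
                                               "uniform-torsion"),
                                      noise = 0.1, mixture = 0.7,
                                      seed = NULL) {
  mode <- match.arg(mode)
  if (nFrames < 1) stop("nFrames must be >= 1", call. = FALSE)
  if (nAtoms < 6) stop("nAtoms must be >= 6", call. = FALSE)
  tplA <- .chainTemplate(nAtoms)
  half <- ceiling(nAtoms / 2)
  tplB <- .rotateAboutBond(tplA, half - 1L, half, (half + 1L):nAtoms, 120)
  mid <- c(half - 2L, half - 1L, half, half + 1L)
  state <- NULL
  coords <- .withSeed(seed, {
    arr <- array(0, c(nFrames, nAtoms, 3))
    if (mode == "two-state")
      state <- stats::rbinom(nFrames, 1, 1 - mixture) + 1L  # 1 = A, 2 = B
    for (f in seq_len(nFrames)) {
      X <- switch(mode,
        "single-well" = tplA,
        "two-state" = if (state[f] == 1L) tplA else tplB,
        "uniform-torsion" = .rotateAboutBond(
          tplA, mid[2], mid[3], (mid[3] + 1L):nAtoms,
          stats::runif(1, -180, 180)))
      arr[f, , ] <- X + matrix(stats::rnorm(nAtoms * 3, sd = noise),
                               nAtoms, 3)
    }
    arr
  })
  ens <- conformerEnsemble(coords)
  if (!is.null(state)) attr(ens, "state") <- state
  ens
}
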