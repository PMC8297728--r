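#' Construct a conformer ensemble
#'
#' @param coords numeric array `[frame, atom, 3]` (Angstrom) or a list of
#'   per-frame `atoms x 3` matrices with a constant atom count.
#' @param atoms optional atom table (`eleno`, `elety`, `resid`, `resno`,
#'   `chain`, `o`, `b`); generated when missing.
#' @param stridePs picoseconds between frames (NA if not applicable).
#' @return a [ConformerEnsemble-class].
#' @export
conformerEnsemble <- function(coords, atoms = NULL, stridePs = NA_real_) {
  if (is.list(coords)) {
    na <- unique(vapply(coords, nrow, integer(1)))
    if (length(na) != 1)
      stop("frames have differing atom counts", call. = FALSE)
    arr <- array(0, c(length(coords), na, 3))
    for (f in seq_along(coords)) arr[f, , ] <- as.matrix(coords[[f]])
    coords <- arr
  }
  na <- dim(coords)[2]
  if (is.null(atoms))
    atoms <- data.frame(eleno = seq_len(na),
                        elety = paste0("A", seq_len(na)),
                        resid = "UNK", resno = 1L, chain = "A",
                        o = 1, b = 0, stringsAsFactors = FALSE)
  new("ConformerEnsemble", coords = coords, atoms = atoms,
      stridePs = as.numeric(stridePs))
}

#' @rdname lprosy-accessors
#' @export
setMethod("nFrames", "ConformerEnsemble",
          function(object) dim(object@coords)[1])

#' @rdname lprosy-accessors
#' @export
setMethod("nAtoms", "ConformerEnsemble",
          function(object) dim(object@coords)[2])

#' @rdname lprosy-accessors
#' @export
setMethod("atomTable", "ConformerEnsemble", function(object) object@atoms)

#' @rdname lprosy-accessors
#' @param frame frame index.
#' @export
setMethod("frameCoords", "ConformerEnsemble", function(object, frame = 1L) {
  m <- object@coords[frame, , ]
  dim(m) <- c(dim(object@coords)[2], 3)
  colnames(m) <- c("x", "y", "z")
  m
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble: %d frames x %d atoms%s\n",
              nFrames(object), nAtoms(object),
              if (is.na(object@stridePs)) ""
              else sprintf(" (%g ps/frame)", object@stridePs)))
})

## resolve atom selections given as indices or elety names
.resolveAtoms <- function(ensemble, sel, single = FALSE) {
  idx <- if (is.numeric(sel)) as.integer(sel)
         else which(ensemble@atoms$elety %in% sel)
  if (!length(idx) || any(idx < 1L | idx > nAtoms(ensemble)))
    stop("atom selection '", paste(sel, collapse = ","),
         "' matches no atom", call. = FALSE)
  if (single && length(idx) != 1L)
    stop("atom selection '", paste(sel, collapse = ","),
         "' must resolve to a single atom", call. = FALSE)
  idx
}

#' Select atoms of an ensemble
#'
#' Index helper mirroring the analysis subsets used for glycan rings: e.g.
#' `selectAtoms(ens, pattern = "^C[1-6]$|^O6$")` for the ring-carbon +
#' O6 subset, optionally restricted to residues.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param pattern regular expression on atom names (`elety`).
#' @param resno residue numbers to keep (optional).
#' @return integer atom indices.
#' @export
selectAtoms <- function(ensemble, pattern = NULL, resno = NULL) {
  a <- ensemble@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(pattern)) keep <- keep & grepl(pattern, a$elety)
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  which(keep)
}

## ---- superposition -------------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `B` onto `A` over an atom subset via the
#' SVD of the cross-covariance matrix, with the determinant correction that
#' excludes reflections.  Degenerate (collinear or < 3 atom) subsets are an
#' error.
#'
#' @param A,B `atoms x 3` coordinate matrices.
#' @param subset atom indices used for the fit (default all).
#' @return list with `rmsd` (Angstrom, over the subset), `rotation` (3 x 3),
#'   `translation` (length 3) and `Bfit` (all of B moved onto A:
#'   `B %*% rotation + translation`).
#' @examples
#' A <- matrix(rnorm(30), 10, 3)
#' th <- 0.7; R <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0),
#'                       c(0, 0, 1))
#' kabschSuperpose(A, A %*% R + 2)$rmsd   # ~ 0
#' @export
kabschSuperpose <- function(A, B, subset = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (is.null(subset)) subset <- seq_len(nrow(A))
  if (length(subset) < 3) stop("subset must contain >= 3 atoms",
                               call. = FALSE)
  As <- A[subset, , drop = FALSE]
  Bs <- B[subset, , drop = FALSE]
  sd <- svd(scale(As, scale = FALSE))$d
  if (sd[2] < 1e-10 * max(sd[1], 1e-300))
    stop("degenerate (collinear) reference geometry", call. = FALSE)
  ca <- colMeans(As); cb <- colMeans(Bs)
  Ac <- sweep(As, 2, ca); Bc <- sweep(Bs, 2, cb)
  sv <- svd(crossprod(Bc, Ac))           # 3x3
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- ca - as.numeric(cb %*% R)
  Bfit <- B %*% R + matrix(trans, nrow(B), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Bfit[subset, , drop = FALSE] - As)^2)))
  list(rmsd = rmsd, rotation = R, translation = trans, Bfit = Bfit)
}

## fast pairwise superposition RMSD from pre-centered subset coordinates
.pairRmsd <- function(Ac, Bc, ssa, ssb, n) {
  sv <- svd(crossprod(Ac, Bc))
  s <- sum(sv$d[1:2]) + sv$d[3] * sign(det(sv$u) * det(sv$v))
  sqrt(max(0, (ssa + ssb - 2 * s)) / n)
}

#' All-versus-all 2D-RMSD map
#'
#' Pairwise optimal-superposition RMSD between every pair of (strided)
#' frames over an atom subset: a symmetric matrix with zero diagonal, the
#' map used to spot interconverting conformational clusters along a
#' trajectory.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param subset atom indices (default all atoms).
#' @param stride keep every `stride`-th frame.
#' @return symmetric numeric matrix (Angstrom); attribute `"frames"` holds
#'   the original frame indices.
#' @export
rmsd2dMap <- function(ensemble, subset = NULL, stride = 1L) {
  if (is.null(subset)) subset <- seq_len(nAtoms(ensemble))
  if (!length(subset)) stop("empty atom selection", call. = FALSE)
  frames <- seq(1L, nFrames(ensemble), by = as.integer(stride))
  nf <- length(frames)
  if (nf < 2) stop("need >= 2 frames after striding", call. = FALSE)
  n <- length(subset)
  cen <- vector("list", nf)
  ss <- numeric(nf)
  for (i in seq_len(nf)) {
    x <- ensemble@coords[frames[i], subset, ]
    dim(x) <- c(n, 3)
    x <- sweep(x, 2, colMeans(x))
    cen[[i]] <- x
    ss[i] <- sum(x^2)
  }
  M <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf)
    M[i, j] <- M[j, i] <- .pairRmsd(cen[[i]], cen[[j]], ss[i], ss[j], n)
  attr(M, "frames") <- frames
  M
}

## ---- clustering ----------------------------------------------------------

#' Cutoff clustering of a 2D-RMSD map
#'
#' Single-linkage grouping: frames are connected whenever their pairwise
#' RMSD is within the cutoff, and connected components form clusters (a
#' deterministic stand-in for the visual inspection of the map).  Clusters
#' smaller than `minSize` are reported as unassigned exceptions.  The
#' medoid frame (smallest mean intra-cluster RMSD) represents each cluster.
#'
#' @param map symmetric RMSD matrix (e.g. from [rmsd2dMap()]).
#' @param cutoff linkage cutoff (Angstrom, > 0); 2 Angstrom is the usual
#'   choice for whole-oligosaccharide ring-atom subsets.
#' @param minSize smallest cluster size that counts as assigned.
#' @return a [ClusterReport-class].
#' @export
clusterByCutoff <- function(map, cutoff, minSize = 1L) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (!isSymmetric(unname(map), tol = 1e-8))
    stop("map must be a square symmetric matrix", call. = FALSE)
  n <- nrow(map)
  hc <- stats::hclust(stats::as.dist(map), method = "single")
  raw <- stats::cutree(hc, h = cutoff)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= minSize])
  ## relabel clusters by decreasing size
  ord <- keep[order(-sizes[as.character(keep)])]
  assignments <- rep(NA_integer_, n)
  for (k in seq_along(ord)) assignments[raw == ord[k]] <- k
  fractions <- vapply(seq_along(ord),
                      function(k) sum(assignments == k, na.rm = TRUE) / n,
                      numeric(1))
  names(fractions) <- paste0("cluster", seq_along(ord))
  reps <- lapply(seq_along(ord), function(k) {
    memb <- which(assignments == k)
    if (length(memb) == 1L) return(memb)
    memb[which.min(rowMeans(map[memb, memb, drop = FALSE]))]
  })
  new("ClusterReport", assignments = assignments, fractions = fractions,
      representatives = reps,
      method = sprintf("single-linkage, cutoff %g A", cutoff))
}

setMethod("show", "ClusterReport", function(object) {
  cat("ClusterReport (", object@method, "):\n", sep = "")
  cat("  fractions:", paste(sprintf("%s=%.3f", names(object@fractions),
                                    object@fractions), collapse = ", "),
      "\n  unassigned:", sum(is.na(object@assignments)), "frames\n")
})

#' Averaged reference models and trajectory fractions
#'
#' For each anchor frame, the frames in a centered window (default 11
#' frames, the anchor +-5) are superposed onto the anchor over the subset
#' and averaged to give a reference model (superpose-then-average, so
#' rotational scatter does not smear the mean).  Every frame of the
#' ensemble is then assigned to the reference with the smallest
#' superposition RMSD, provided it is below `cutoff`; the fraction of the
#' trajectory represented by each reference is reported.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param anchors anchor frame indices, one per putative cluster.
#' @param window odd window length (frames).
#' @param subset atom indices used for fitting and averaging.
#' @param cutoff assignment cutoff (Angstrom).
#' @return a [ClusterReport-class]; `representatives` holds the averaged
#'   `subset x 3` reference coordinates.
#' @export
representativeModels <- function(ensemble, anchors, window = 11L,
                                 subset = NULL, cutoff = 2) {
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  if (is.null(subset)) subset <- seq_len(nAtoms(ensemble))
  half <- (window - 1L) %/% 2L
  nf <- nFrames(ensemble)
  if (any(anchors - half < 1L | anchors + half > nf))
    stop("window out of trajectory bounds", call. = FALSE)
  n <- length(subset)
  getSub <- function(f) {
    x <- ensemble@coords[f, subset, ]
    dim(x) <- c(n, 3)
    x
  }
  refs <- lapply(anchors, function(a) {
    anchor <- getSub(a)
    acc <- matrix(0, n, 3)
    for (f in (a - half):(a + half)) {
      fit <- kabschSuperpose(anchor, getSub(f))
      acc <- acc + fit$Bfit
    }
    acc / window
  })
  assignments <- rep(NA_integer_, nf)
  best <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    x <- getSub(f)
    r <- vapply(refs, function(ref) kabschSuperpose(ref, x)$rmsd,
                numeric(1))
    k <- which.min(r)
    if (r[k] <= cutoff) {
      assignments[f] <- k
      best[f] <- r[k]
    }
  }
  fractions <- vapply(seq_along(refs),
                      function(k) sum(assignments == k, na.rm = TRUE) / nf,
                      numeric(1))
  names(fractions) <- paste0("model", seq_along(refs))
  new("ClusterReport", assignments = assignments, fractions = fractions,
      representatives = refs,
      method = sprintf("averaged %d-frame references, cutoff %g A",
                       window, cutoff))
}

## ---- torsions ------------------------------------------------------------

## signed IUPAC dihedral (degrees) for one frame
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Torsion angle trajectory
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param atoms4 four atom indices (or single-match `elety` names) defining
#'   the dihedral, IUPAC signed convention, range [-180, 180).
#' @return numeric vector, one angle (degrees) per frame.
#' @export
torsionTrajectory <- function(ensemble, atoms4) {
  idx <- vapply(atoms4, function(a) .resolveAtoms(ensemble, a, single = TRUE),
                integer(1))
  if (length(idx) != 4) stop("need exactly 4 atoms", call. = FALSE)
  vapply(seq_len(nFrames(ensemble)), function(f) {
    x <- frameCoords(ensemble, f)
    .wrapDeg(.dihedral(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ]))
  }, numeric(1))
}

#' Joint torsion population map
#'
#' Normalized joint and marginal histograms of two torsion angles over
#' [-180, 180) with a fixed bin width (default 5 degrees, 72 marginal
#' bins), optionally converted to a -ln(p) free-energy surface.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param torsionA,torsionB four-atom definitions as in
#'   [torsionTrajectory()].
#' @param bin bin width in degrees; must divide 360.
#' @param freeEnergy also return `-log(p)` of the joint map (Inf for empty
#'   bins).
#' @return list with `joint` (matrix of fractions, rows = torsionA bins),
#'   `marginalA`, `marginalB` (named fraction vectors summing to 1),
#'   `breaks`, and optionally `freeEnergy`.
#' @export
torsionPopulationMap <- function(ensemble, torsionA, torsionB, bin = 5,
                                 freeEnergy = FALSE) {
  if (bin <= 0 || 360 %% bin != 0)
    stop("bin width must divide 360", call. = FALSE)
  ta <- torsionTrajectory(ensemble, torsionA)
  tb <- torsionTrajectory(ensemble, torsionB)
  breaks <- seq(-180, 180, by = bin)
  ca <- cut(ta, breaks, right = FALSE, include.lowest = TRUE)
  cb <- cut(tb, breaks, right = FALSE, include.lowest = TRUE)
  joint <- table(ca, cb) / length(ta)
  joint <- matrix(as.numeric(joint), nrow = nlevels(ca),
                  dimnames = list(levels(ca), levels(cb)))
  out <- list(joint = joint,
              marginalA = rowSums(joint),
              marginalB = colSums(joint),
              breaks = breaks)
  if (freeEnergy) out$freeEnergy <- -log(joint)
  out
}
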