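#' Describe a single proton pool
#'
#' @param name pool label.
#' @param kind `"labile"` (OH/NH sites exchanging with water), `"water"`, or
#'   `"nonlabile"` (CH sites).
#' @param M0 equilibrium magnetization, proportional to pool population
#'   (dimensionless, > 0).  The water pool of an aqueous sample is typically
#'   1e3-1e5 times the labile pool.
#' @param R1,R2 longitudinal and transverse relaxation rates (s^-1).  R2 is
#'   carried for the Liouville-space TOCSY engine only; the longitudinal
#'   NOESY engine ignores it.  `R2 >= R1` is flagged with a warning when
#'   violated, not enforced.
#' @param offset chemical-shift offset (Hz).
#' @return one-row data.frame suitable for [spinSystem()].
#' @examples
#' spinPool("OH", "labile", R1 = 1, R2 = 30)
#' @export
spinPool <- function(name, kind = c("labile", "water", "nonlabile"),
                     M0 = 1, R1 = 1, R2 = R1, offset = 0) {
  kind <- match.arg(kind)
  if (!is.finite(R1) || R1 <= 0)
    stop("R1 must be positive for pool '", name, "'", call. = FALSE)
  if (is.finite(R2) && R2 < R1)
    warning("pool '", name, "' has R2 < R1; carried as given", call. = FALSE)
  data.frame(name = as.character(name), kind = kind, M0 = M0, R1 = R1,
             R2 = R2, offset = offset, stringsAsFactors = FALSE)
}

.pairMatrix <- function(df, poolnames, cols, what) {
  n <- length(poolnames)
  m <- matrix(0, n, n, dimnames = list(poolnames, poolnames))
  if (is.null(df) || !nrow(df)) return(m)
  if (!all(cols %in% names(df)))
    stop(what, " table must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  for (r in seq_len(nrow(df))) {
    a <- as.character(df[[cols[1]]][r]); b <- as.character(df[[cols[2]]][r])
    for (x in c(a, b)) if (!x %in% poolnames)
      stop("unknown pool '", x, "' in ", what, " table", call. = FALSE)
    m[a, b] <- m[b, a] <- df[[cols[3]]][r]
  }
  m
}

#' Construct a validated spin system
#'
#' Builds a [SpinSystem-class] from pool descriptions and pairwise parameter
#' tables.  Exchange is directed; reverse rates that are not supplied are
#' auto-filled so that detailed balance `k(a->b) M0(a) = k(b->a) M0(b)`
#' holds exactly.  Declaring exchange between two nonlabile pools is an
#' error, as is a supplied pair of forward/reverse rates that contradicts
#' detailed balance.
#'
#' @param pools list of [spinPool()] rows (or an equivalent data.frame).
#' @param exchange data.frame with columns `from`, `to`, `k` (s^-1).
#' @param sigma data.frame with columns `a`, `b`, `value`: signed
#'   cross-relaxation rates (s^-1), stored symmetrically.  In the
#'   fast-tumbling (small-molecule) regime sigma is negative and produces
#'   NOESY cross-peaks opposite in sign to the diagonal under the default
#'   display convention.
#' @param J data.frame with columns `a`, `b`, `value`: scalar couplings (Hz).
#' @return a [SpinSystem-class].
#' @examples
#' sys <- spinSystem(
#'   list(spinPool("OH", "labile", R1 = 1, R2 = 30),
#'        spinPool("W", "water", M0 = 1000, R1 = 0.3),
#'        spinPool("CH", "nonlabile", R1 = 1)),
#'   exchange = data.frame(from = "OH", to = "W", k = 100),
#'   sigma = data.frame(a = "OH", b = "CH", value = -0.05),
#'   J = data.frame(a = "OH", b = "CH", value = 5))
#' exchangeRates(sys)["W", "OH"]   # detailed-balance reverse rate, 0.1 s^-1
#' @export
spinSystem <- function(pools, exchange = NULL, sigma = NULL, J = NULL) {
  if (is.data.frame(pools)) p <- pools else p <- do.call(rbind, pools)
  if (nrow(p) < 1) stop("at least one pool is required", call. = FALSE)
  pn <- p$name
  n <- length(pn)
  K <- matrix(0, n, n, dimnames = list(pn, pn))
  if (!is.null(exchange) && nrow(exchange)) {
    if (!all(c("from", "to", "k") %in% names(exchange)))
      stop("exchange table must have columns from, to, k", call. = FALSE)
    for (r in seq_len(nrow(exchange))) {
      a <- as.character(exchange$from[r]); b <- as.character(exchange$to[r])
      for (x in c(a, b)) if (!x %in% pn)
        stop("unknown pool '", x, "' in exchange table", call. = FALSE)
      k <- exchange$k[r]
      if (!is.finite(k) || k < 0)
        stop("exchange rates must be finite and non-negative", call. = FALSE)
      if (p$kind[p$name == a] == "nonlabile" &&
          p$kind[p$name == b] == "nonlabile")
        stop("exchange declared between two nonlabile pools '", a,
             "' and '", b, "'", call. = FALSE)
      K[a, b] <- k
    }
    ## auto-fill / check detailed balance
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || K[i, j] == 0) next
      rev <- K[i, j] * p$M0[i] / p$M0[j]
      if (K[j, i] == 0) {
        K[j, i] <- rev
      } else if (abs(K[j, i] - rev) / max(rev, 1e-300) > 1e-9) {
        stop("supplied exchange rates between '", pn[i], "' and '", pn[j],
             "' violate detailed balance", call. = FALSE)
      }
    }
  }
  S <- .pairMatrix(sigma, pn, c("a", "b", "value"), "sigma")
  Jm <- .pairMatrix(J, pn, c("a", "b", "value"), "J")
  diag(Jm) <- 0
  new("SpinSystem", pools = p, kex = K, sigma = S, J = Jm)
}

#' Build a spin system from a flat configuration mapping
#'
#' Accepts the parsed form of the package's YAML-compatible spin-system
#' schema (see [readSpinConfig()]): a list with a named `pools` mapping and
#' optional `exchange`, `sigma` and `J` entry lists.
#'
#' @param config list: `pools` = named list of `list(kind=, M0=, R1=, R2=,
#'   offset=)`; `exchange` = list of `list(from=, to=, k=)`; `sigma`/`J` =
#'   list of `list(a=, b=, value=)`.
#' @return a [SpinSystem-class].
#' @seealso [readSpinConfig()], [writeSpinConfig()]
#' @export
buildSpinSystem <- function(config) {
  if (is.null(config$pools) || length(config$pools) < 2)
    stop("config must name at least 2 pools", call. = FALSE)
  pools <- lapply(names(config$pools), function(nm) {
    pc <- config$pools[[nm]]
    spinPool(nm, kind = pc$kind,
             M0 = if (is.null(pc$M0)) 1 else pc$M0,
             R1 = if (is.null(pc$R1)) 1 else pc$R1,
             R2 = if (is.null(pc$R2)) max(1, pc$R1) else pc$R2,
             offset = if (is.null(pc$offset)) 0 else pc$offset)
  })
  asDf <- function(entries, cols) {
    if (is.null(entries) || !length(entries)) return(NULL)
    do.call(rbind, lapply(entries, function(e)
      as.data.frame(e[cols], stringsAsFactors = FALSE)))
  }
  spinSystem(pools,
             exchange = asDf(config$exchange, c("from", "to", "k")),
             sigma = asDf(config$sigma, c("a", "b", "value")),
             J = asDf(config$J, c("a", "b", "value")))
}

## ---- accessors -----------------------------------------------------------

#' @rdname lprosy-accessors
#' @export
setMethod("pools", "SpinSystem", function(object) object@pools)

#' @rdname lprosy-accessors
#' @export
setMethod("poolNames", "SpinSystem", function(object) object@pools$name)

#' @rdname lprosy-accessors
#' @export
setMethod("nPools", "SpinSystem", function(object) nrow(object@pools))

#' @rdname lprosy-accessors
#' @export
setMethod("exchangeRates", "SpinSystem", function(object) object@kex)

#' @rdname lprosy-accessors
#' @export
setMethod("crossRelaxation", "SpinSystem", function(object) object@sigma)

#' @rdname lprosy-accessors
#' @export
setMethod("jCouplings", "SpinSystem", function(object) object@J)

#' @export
#' @describeIn thermalEquilibrium equilibrium magnetization in pool order.
setMethod("thermalEquilibrium", "SpinSystem", function(object) {
  stats::setNames(object@pools$M0, object@pools$name)
})

setMethod("show", "SpinSystem", function(object) {
  p <- object@pools
  cat("SpinSystem with", nrow(p), "pools:",
      paste0(p$name, " (", p$kind, ")", collapse = ", "), "\n")
  nex <- sum(object@kex > 0) / 2
  cat(sprintf("  exchange pairs: %d | sigma pairs: %d | J pairs: %d\n",
              nex, sum(object@sigma[upper.tri(object@sigma)] != 0),
              sum(object@J[upper.tri(object@J)] != 0)))
})

## ---- modifiers (re-balanced copies, used by enhancement maps) ------------

#' Modified copies of a spin system
#'
#' Return a copy of `system` with one parameter replaced.
#' `setExchangeRate()` re-derives the reverse rate from detailed balance.
#'
#' @param system a [SpinSystem-class].
#' @param from,to,a,b,pool pool names.
#' @param k,value new rate (s^-1 or Hz).
#' @return a new [SpinSystem-class].
#' @export
setExchangeRate <- function(system, from, to, k) {
  p <- system@pools
  K <- system@kex
  K[from, to] <- k
  K[to, from] <- k * p$M0[p$name == from] / p$M0[p$name == to]
  new("SpinSystem", pools = p, kex = K, sigma = system@sigma, J = system@J)
}

#' @rdname setExchangeRate
#' @export
setCrossRelaxation <- function(system, a, b, value) {
  S <- system@sigma
  S[a, b] <- S[b, a] <- value
  new("SpinSystem", pools = system@pools, kex = system@kex, sigma = S,
      J = system@J)
}

#' @rdname setExchangeRate
#' @export
setJCoupling <- function(system, a, b, value) {
  Jm <- system@J
  Jm[a, b] <- Jm[b, a] <- value
  new("SpinSystem", pools = system@pools, kex = system@kex,
      sigma = system@sigma, J = Jm)
}

#' @rdname setExchangeRate
#' @export
setR1 <- function(system, pool, value) {
  p <- system@pools
  p$R1[p$name == pool] <- value
  new("SpinSystem", pools = p, kex = system@kex, sigma = system@sigma,
      J = system@J)
}

## ---- generator -----------------------------------------------------------

#' Build the longitudinal Bloch-McConnell/Solomon generator
#'
#' Assembles the affine evolution dM/dt = A M + b of the pool
#' z-magnetizations.  Off-diagonal entries carry cross-relaxation
#' (`A[i,j] += sigma[i,j]`) and exchange influx (`A[i,j] += k[j->i]`);
#' each diagonal entry is the R1 auto-relaxation augmented by the total
#' cross-relaxation and exchange leaving the pool,
#' `A[i,i] = -(R1_i + sum_j sigma[i,j] + sum_j k[i->j])`.  The recovery
#' vector is `b = -A %*% Meq`, which makes the thermal equilibrium the exact
#' stationary point; by detailed balance the exchange sub-matrix alone
#' annihilates `Meq` and its columns sum to zero (magnetization
#' conservation).
#'
#' @param object a [SpinSystem-class].
#' @return a [LongitudinalGenerator-class].
#' @examples
#' sys <- spinSystem(list(spinPool("A", "labile"), spinPool("B", "nonlabile")),
#'                   sigma = data.frame(a = "A", b = "B", value = -0.05))
#' gen <- buildGenerator(sys)
#' gen@matrix %*% thermalEquilibrium(sys) + gen@recovery  # ~ 0
#' @export
setGeneric("buildGenerator", function(object) standardGeneric("buildGenerator"))

#' @rdname buildGenerator
#' @export
setMethod("buildGenerator", "SpinSystem", function(object) {
  p <- object@pools
  K <- object@kex
  S <- object@sigma
  A <- S + t(K)
  diag(A) <- -(p$R1 + rowSums(S) + rowSums(K))
  b <- as.numeric(-A %*% p$M0)
  new("LongitudinalGenerator", matrix = A, recovery = b, poolNames = p$name)
})

setMethod("show", "LongitudinalGenerator", function(object) {
  cat("LongitudinalGenerator over pools:",
      paste(object@poolNames, collapse = ", "), "\n")
  cat("  eigenvalue real parts:",
      paste(signif(sort(Re(eigen(object@matrix, only.values = TRUE)$values)),
                   4), collapse = ", "), "\n")
})
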