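## provenance header written at the top of package CSV outputs
.provenance <- function(seed = NA) {
  sprintf("# lprosy %s | seed: %s | written: %s",
          as.character(utils::packageVersion("lprosy")),
          if (is.na(seed)) "none" else as.character(seed),
          format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Read / write a spin-system configuration
#'
#' Flat YAML mapping with a `pools` section (per pool: `kind`, `M0`, `R1`,
#' `R2`, `offset`) and optional `exchange` (`from`, `to`, `k`), `sigma` and
#' `J` (`a`, `b`, `value`) entry lists; rates s^-1, couplings Hz.  Reading
#' and writing round-trip losslessly.
#'
#' @param path file path.
#' @return [readSpinConfig()]: a [SpinSystem-class].
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeSpinConfig(sugarSpinSystem(), f)
#' readSpinConfig(f)
#' @export
readSpinConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  buildSpinSystem(yaml::read_yaml(path))
}

#' @rdname readSpinConfig
#' @param system a [SpinSystem-class].
#' @export
writeSpinConfig <- function(system, path) {
  p <- pools(system)
  cfg <- list(pools = stats::setNames(lapply(seq_len(nrow(p)), function(i)
    list(kind = p$kind[i], M0 = p$M0[i], R1 = p$R1[i], R2 = p$R2[i],
         offset = p$offset[i])), p$name))
  pairsOf <- function(m) {
    ut <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
    lapply(seq_len(nrow(ut)), function(r)
      list(a = p$name[ut[r, 1]], b = p$name[ut[r, 2]],
           value = m[ut[r, 1], ut[r, 2]]))
  }
  ## store one direction per exchanging pair; the reader re-derives the
  ## reverse rate from detailed balance
  ex <- which(upper.tri(system@kex) & system@kex != 0, arr.ind = TRUE)
  cfg$exchange <- lapply(seq_len(nrow(ex)), function(r)
    list(from = p$name[ex[r, 1]], to = p$name[ex[r, 2]],
         k = system@kex[ex[r, 1], ex[r, 2]]))
  cfg$sigma <- pairsOf(system@sigma)
  cfg$J <- pairsOf(system@J)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read / write simulated peak tables
#'
#' CSV (comma separator, dot decimal, mandatory header) with columns
#' `source`, `destination`, `amplitude`, `experiment`, `mixing`, `loops`,
#' preceded by a `#` provenance header.  A missing column is a fatal,
#' named error.
#'
#' @param path file path.
#' @param seed seed recorded in the provenance header (optional).
#' @return [readPeakTable()]: data.frame.
#' @export
readPeakTable <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("source", "destination", "amplitude", "experiment", "mixing",
            "loops")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("peak table ", path, " is missing column '", miss[1], "'",
         call. = FALSE)
  tab
}

#' @rdname readPeakTable
#' @param table data.frame (e.g. from [peakTable()]).
#' @export
writePeakTable <- function(table, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed), con)
  utils::write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- multi-MODEL PDB -----------------------------------------------------

#' Read a multi-MODEL PDB file as a conformer ensemble
#'
#' Parses MODEL/ENDMDL-framed coordinates (via bio3d) into a
#' [ConformerEnsemble-class]; occupancy and B-factor columns are carried
#' through untouched.  Mismatched atom counts between models are a fatal
#' error naming the offending model.
#'
#' @param path PDB file path.
#' @param stridePs picoseconds per frame metadata (optional).
#' @return a [ConformerEnsemble-class].
#' @seealso [writeEnsemblePDB()]
#' @export
readEnsemblePDB <- function(path, stridePs = NA_real_) {
  if (!file.exists(path)) stop("no such PDB file: ", path, call. = FALSE)
  lines <- readLines(path)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
    counts <- mapply(function(s, e) sum(isAtom[s:e]), starts, ends)
    if (length(unique(counts)) != 1) {
      bad <- which(counts != counts[1])[1]
      stop("model ", bad, " of ", path, " has ", counts[bad],
           " atoms but model 1 has ", counts[1], call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(0, c(nf, na, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(eleno = pdb$atom$eleno, elety = pdb$atom$elety,
                      resid = pdb$atom$resid, resno = pdb$atom$resno,
                      chain = ifelse(is.na(pdb$atom$chain), "A",
                                     pdb$atom$chain),
                      o = ifelse(is.na(pdb$atom$o), 1, pdb$atom$o),
                      b = ifelse(is.na(pdb$atom$b), 0, pdb$atom$b),
                      stringsAsFactors = FALSE)
  conformerEnsemble(coords, atoms, stridePs)
}

#' Write a conformer ensemble as a multi-MODEL PDB file
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEnsemblePDB <- function(ensemble, path) {
  a <- ensemble@atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- frameCoords(ensemble, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      a$eleno, substr(a$elety, 1, 4), substr(a$resid, 1, 4),
      substr(a$chain, 1, 1), a$resno, x[, 1], x[, 2], x[, 3], a$o, a$b),
      con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write an RMSD map or enhancement map as CSV
#'
#' @param map numeric matrix.
#' @param path output path.
#' @param seed provenance seed (optional).
#' @export
writeMapCSV <- function(map, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed), con)
  utils::write.csv(as.data.frame(map), con, row.names = TRUE)
  invisible(path)
}
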