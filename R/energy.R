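#' @include parameters.R
NULL

#' Sigmoidal contact kernel
#'
#' The probability-like contact weight
#' `f(r) = (1 + tanh(mu * (rc - r))) / 2`: monotone non-increasing in `r`,
#' tending to 1 as r tends to 0 and to 0 as r grows, with `f(rc) = 1/2`.
#' All finite-range attractive terms of the energy function (ideal
#' chromosome, type-to-type, loops) act through this kernel.
#'
#' @param r non-negative distances.
#' @param mu kernel steepness (1/length).
#' @param rc kernel midpoint (length).
#' @return Numeric vector of weights in `[0, 1]`.
#' @examples
#' contactKernel(1.78, 3.22, 1.78)  # 0.5 at the midpoint
#' @export
contactKernel <- function(r, mu = 3.22, rc = 1.78) {
  if (any(r < 0)) stop("distances must be non-negative")
  0.5 * (1 + tanh(mu * (rc - r)))
}

#' Energy terms of the chromatin model
#'
#' Each term of the energy landscape, separately evaluable over a
#' configuration (reduced units):
#'
#' * `energyBonded()` — polymer connectivity: a FENE bond
#'   `-k r0^2 log(1 - (r/r0)^2) / 2` plus a purely repulsive short-range
#'   core between bonded neighbours; diverges as r approaches `r0`.
#' * `energyConfinement()` — nuclear confinement by a repulsive spherical
#'   wall: zero inside radius `R`, `k (|r| - R)^2` outside.
#' * `energyIdealChromosome()` — the translationally invariant
#'   genomic-distance term `sum gamma(|i - j|) f(r_ij)` over pairs with
#'   `dMin <= |i - j| <= dMax`; depends on genomic separation only, never
#'   on bead identity.
#' * `energyTypeToType()` — chromatin type couplings
#'   `sum alpha(t_i, t_j) f(r_ij)` plus the excluded-volume core over
#'   non-bonded pairs (`|i - j| >= 2`).
#' * `energyLoops()` — `sum chi f(r_ab)` over the loop-anchor list;
#'   duplicate entries are collapsed with a warning.
#'
#' @param positions n-by-3 coordinate matrix.
#' @param params a [MiChroMParameters-class] (default
#'   [michromParameters()]).
#' @param beadTypes integer type indices in 0..6.
#' @param loops 2-column matrix of 1-based anchor pairs.
#' @return The term's energy (scalar).
#' @name energyTerms
NULL

#' @rdname energyTerms
#' @export
energyBonded <- function(positions, params = michromParameters()) {
  .cppEnergyBonded(as.matrix(positions), .paramsForCpp(params))
}

#' @rdname energyTerms
#' @export
energyConfinement <- function(positions, params = michromParameters()) {
  .cppEnergyConfinement(as.matrix(positions), .paramsForCpp(params))
}

#' @rdname energyTerms
#' @export
energyIdealChromosome <- function(positions, params = michromParameters()) {
  .cppEnergyIdeal(as.matrix(positions), .paramsForCpp(params))
}

#' @rdname energyTerms
#' @export
energyTypeToType <- function(positions, beadTypes,
                             params = michromParameters()) {
  .cppEnergyType(as.matrix(positions), as.integer(beadTypes),
                 .paramsForCpp(params))
}

#' @rdname energyTerms
#' @export
energyLoops <- function(positions, loops, params = michromParameters()) {
  loops <- as.matrix(loops)
  storage.mode(loops) <- "integer"
  if (nrow(loops)) loops <- dedupLoops(loops)
  .cppEnergyLoops(as.matrix(positions), loops, .paramsForCpp(params))
}

#' Total energy of a chromosome system
#'
#' Sum of the five energy terms (connectivity, confinement, ideal
#' chromosome, type-to-type, loops) over a configuration, with each term
#' separately reported.
#'
#' @param system a [ChromosomeSystem-class].
#' @param positions n-by-3 coordinate matrix.
#' @return A list with elements `total` and `terms` (named numeric vector
#'   `bonded`, `confinement`, `ideal`, `type`, `loops`).
#' @examples
#' sys <- makeBlockCopolymer(20, 10, seed = 1)
#' pos <- initialConformation(20, 5, seed = 1)
#' totalEnergy(sys, pos)
#' @export
totalEnergy <- function(system, positions) {
  validObject(system)
  p <- system@parameters
  terms <- c(
    bonded = energyBonded(positions, p),
    confinement = energyConfinement(positions, p),
    ideal = energyIdealChromosome(positions, p),
    type = energyTypeToType(positions, system@beadTypes, p),
    loops = if (nrow(system@loops))
      energyLoops(positions, system@loops, p) else 0
  )
  list(total = sum(terms), terms = terms)
}

#' Total force on each bead (internal surface for the sampler and tests)
#'
#' Negative gradient of the summed energy landscape.
#'
#' @inheritParams totalEnergy
#' @return n-by-3 matrix of forces.
#' @export
totalForces <- function(system, positions) {
  .cppForces(as.matrix(positions), system@beadTypes, system@loops,
             .paramsForCpp(system@parameters))
}

#' Deterministic initial chain conformation inside the confinement sphere
#'
#' A seeded self-avoiding-ish random walk: unit steps in random directions,
#' resampled when they would leave the sphere (with a half-bead margin) or
#' approach any earlier bead closer than 0.8 sigma. Deterministic given the
#' seed; consecutive-bead distances are 1, well within the FENE range.
#'
#' @param nBeads number of beads (>= 1).
#' @param confinementRadius sphere radius.
#' @param seed integer seed.
#' @param bondLength step length (default 1).
#' @return n-by-3 coordinate matrix.
#' @export
initialConformation <- function(nBeads, confinementRadius, seed,
                                bondLength = 1) {
  stopifnot(nBeads >= 1)
  rmax <- confinementRadius - 0.5
  if (rmax <= 0) stop("confinement sphere too small for any bead")
  # crude packing bound: bead volume vs sphere volume
  if (nBeads * pi / 6 > 0.55 * 4 / 3 * pi * confinementRadius^3)
    stop(sprintf(
      "cannot fit %d beads in a sphere of radius %g at a workable density",
      nBeads, confinementRadius))
  set.seed(seed)
  # the greedy walk can corner itself; restart from scratch (same RNG
  # stream, so still a pure function of the seed) up to a fixed budget
  for (attempt in seq_len(25L)) {
    pos <- matrix(0, nBeads, 3L)
    stuck <- FALSE
    for (i in seq_len(nBeads)[-1L]) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        u <- stats::rnorm(3)
        step <- u / sqrt(sum(u^2)) * bondLength
        cand <- pos[i - 1L, ] + step
        if (sqrt(sum(cand^2)) > rmax) next
        if (i > 2L) {
          prev <- seq_len(i - 2L)
          d2 <- rowSums((pos[prev, , drop = FALSE] -
                           matrix(cand, length(prev), 3L, byrow = TRUE))^2)
          if (any(d2 < 0.64)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) { stuck <- TRUE; break }
      pos[i, ] <- cand
    }
    if (!stuck) return(pos)
  }
  stop(sprintf(
    "cannot fit a %d-bead chain in a sphere of radius %g at the requested density",
    nBeads, confinementRadius))
}

## MD-engine input export ------------------------------------------------------

.XVG_SPACING <- 1e-3

.writeXvg <- function(path, r, u, title, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# %s", title),
               if (!is.null(comment)) sprintf("# %s", comment),
               sprintf("# r-grid: [0, %g], spacing %g", max(r), .XVG_SPACING),
               "@    xaxis label \"r\"",
               "@    yaxis label \"U(r)\""), con)
  writeLines(sprintf("%.6e %.15e", r, u), con)
  invisible(path)
}

#' Read a two-column .xvg table
#'
#' @param path path to an `.xvg` file written by [exportMdInputs()].
#' @return `data.frame` with columns `r` and `U`.
#' @export
readXvg <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "@")]
  m <- read.table(text = lines, col.names = c("r", "U"))
  m
}

#' Export a chromosome system as tabulated-potential MD-engine inputs
#'
#' Writes the full input set an external MD engine needs to simulate the
#' system with its effective energy function encoded as tables:
#'
#' * `table_b0.xvg` — polymer connectivity: FENE bond plus the
#'   nearest-neighbour steric core, as one merged per-bond curve `U(r)`.
#' * `table_b1.xvg` — nuclear confinement: half-harmonic wall energy as a
#'   function of distance from the sphere centre.
#' * `table_b2.xvg` — ideal-chromosome basis: the contact kernel `f(r)` at
#'   unit coefficient; the per-separation `gamma(d)` coefficients are
#'   listed in the `.top` file.
#' * `table.xvg` — type-to-type basis: the non-nearest-neighbour steric
#'   core plus the contact kernel at the reference coupling `alpha = 1`;
#'   per-pair-type couplings are listed in the `.top` file.
#' * `tablep.xvg` — loop-anchor potential `chi * f(r)`.
#'
#' plus `initial.gro` (initial xyz at one bead per 50-kb locus, with the
#' compartment annotation of each segment in the name columns) and
#' `system.top` (topology: bead types, chain connectivity, type-coupling
#' matrix, gamma coefficients and the loop list).
#'
#' All tables share a uniform grid r in `[0, 3 * confinementRadius]` with
#' spacing 1e-3, stated in each file's header. Tabulated values evaluated
#' at any grid point equal the in-package energy terms.
#'
#' @param system a [ChromosomeSystem-class].
#' @param positions n-by-3 initial coordinates (finite, inside the
#'   confinement sphere; beads outside trigger a warning).
#' @param outDir output directory (created if missing).
#' @param annotations optional per-bead labels for the `.gro` name columns;
#'   defaults to the type labels implied by `beadTypes`.
#' @return Named character vector of the seven file paths, invisibly.
#' @export
exportMdInputs <- function(system, positions, outDir, annotations = NULL) {
  validObject(system)
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("positions must be finite")
  p <- system@parameters
  radii <- sqrt(rowSums(positions^2))
  if (any(radii > p@confinementRadius))
    warning(sprintf("%d bead(s) outside the confinement sphere", sum(radii > p@confinementRadius)))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("unwritable output directory: ", outDir)

  rmax <- 3 * p@confinementRadius
  r <- seq(0, rmax, by = .XVG_SPACING)
  rpos <- pmax(r, 1e-9)

  wca <- function(rr) {
    cut <- 2^(1 / 6) * p@stericSigma
    u <- numeric(length(rr))
    sel <- rr < cut
    sr6 <- (p@stericSigma / rr[sel])^6
    u[sel] <- 4 * p@stericEpsilon * (sr6^2 - sr6) + p@stericEpsilon
    u
  }
  fene <- function(rr) {
    u <- rep(Inf, length(rr))
    sel <- rr < p@feneR0
    u[sel] <- -0.5 * p@feneK * p@feneR0^2 * log(1 - (rr[sel] / p@feneR0)^2)
    u
  }
  fk <- contactKernel(r, p@contactMu, p@contactRc)

  # bonded table is only meaningful below r0; cap at a large finite value
  ub0 <- fene(rpos) + wca(rpos)
  ub0[!is.finite(ub0)] <- 1e10
  paths <- c(
    table_b0 = file.path(outDir, "table_b0.xvg"),
    table_b1 = file.path(outDir, "table_b1.xvg"),
    table_b2 = file.path(outDir, "table_b2.xvg"),
    table = file.path(outDir, "table.xvg"),
    tablep = file.path(outDir, "tablep.xvg"),
    gro = file.path(outDir, "initial.gro"),
    top = file.path(outDir, "system.top")
  )
  .writeXvg(paths["table_b0"], r, ub0,
            "polymer connectivity: FENE bond + nearest-neighbour steric core",
            sprintf("FENE k=%g r0=%g; core eps=%g sigma=%g (values past r0 capped at 1e10)",
                    p@feneK, p@feneR0, p@stericEpsilon, p@stericSigma))
  .writeXvg(paths["table_b1"], r,
            ifelse(r > p@confinementRadius,
                   p@confinementK * (r - p@confinementRadius)^2, 0),
            "nuclear confinement: repulsive spherical wall vs distance from centre",
            sprintf("R=%g k=%g", p@confinementRadius, p@confinementK))
  .writeXvg(paths["table_b2"], r, fk,
            "ideal-chromosome basis: contact kernel f(r) at unit gamma",
            sprintf("mu=%g rc=%g; per-separation gamma(d) coefficients in system.top",
                    p@contactMu, p@contactRc))
  .writeXvg(paths["table"], r, wca(rpos) + fk,
            "type-to-type basis: non-nearest-neighbour steric core + f(r) at reference coupling alpha=1",
            "per-type-pair couplings alpha(ti,tj) in system.top")
  .writeXvg(paths["tablep"], r, p@loopChi * fk,
            "stable chromatin loops: chi * f(r)",
            sprintf("chi=%g; anchor pairs in system.top", p@loopChi))

  labels <- if (is.null(annotations)) .TYPE_LABELS[system@beadTypes + 1L]
            else as.character(annotations)
  writeGro(round(positions, 3L), labels, paths["gro"],
           title = sprintf("chromosome system, %d beads at %g bp/bead",
                           system@nBeads, system@resolution))
  .writeTop(system, paths["top"])
  invisible(paths)
}

# .top dialect (documented field by field):
#   [ system ]       name, bead count, resolution
#   [ atoms ]        index  type-index  type-label
#   [ bonds ]        i  j  table (b0), consecutive beads
#   [ typematrix ]   ti  tj  alpha     (7x7, upper triangle)
#   [ idealgamma ]   g1 g2 g3 dmin dmax
#   [ pairs ]        a  b  class      (loop anchors, table tablep)
.writeTop <- function(system, path) {
  p <- system@parameters
  n <- system@nBeads
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("; chromosome topology",
               "[ system ]",
               sprintf("chromosome %d %g", n, system@resolution),
               "", "[ atoms ]"), con)
  writeLines(sprintf("%8d %2d %-3s", seq_len(n), system@beadTypes,
                     .TYPE_LABELS[system@beadTypes + 1L]), con)
  writeLines(c("", "[ bonds ]"), con)
  if (n > 1L)
    writeLines(sprintf("%8d %8d b0", seq_len(n - 1L), seq_len(n - 1L) + 1L), con)
  writeLines(c("", "[ typematrix ]"), con)
  tm <- p@typeMatrix
  for (i in 1:7) for (j in i:7)
    writeLines(sprintf("%2d %2d %.15g", i - 1L, j - 1L, tm[i, j]), con)
  writeLines(c("", "[ idealgamma ]",
               sprintf("%.15g %.15g %.15g %d %d",
                       p@idealGamma[1L], p@idealGamma[2L], p@idealGamma[3L],
                       p@dMin, p@dMax),
               "", "[ pairs ]"), con)
  if (nrow(system@loops))
    writeLines(sprintf("%8d %8d UNKNOWN", system@loops[, 1L],
                       system@loops[, 2L]), con)
  invisible(path)
}

#' Parse a .top topology file written by [exportMdInputs()]
#'
#' @param path path to a `.top` file.
#' @return A list with `nBeads`, `resolution`, `beadTypes` (integer),
#'   `bonds` (2-column matrix), `typeMatrix` (7x7), `idealGamma`, `dMin`,
#'   `dMax`, and `loops` (2-column matrix of anchor pairs).
#' @export
parseTop <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  sec <- NA_character_
  out <- list(beadTypes = integer(), bonds = NULL, loops = NULL,
              typeMatrix = matrix(0, 7, 7))
  bonds <- list(); pairs <- list()
  for (line in lines) {
    if (grepl("^\\[", line)) {
      sec <- gsub("[][ ]", "", line)
      next
    }
    tok <- strsplit(line, "[[:space:]]+")[[1L]]
    if (sec == "system") {
      out$nBeads <- as.integer(tok[2L]); out$resolution <- as.numeric(tok[3L])
    } else if (sec == "atoms") {
      out$beadTypes[as.integer(tok[1L])] <- as.integer(tok[2L])
    } else if (sec == "bonds") {
      bonds[[length(bonds) + 1L]] <- as.integer(tok[1:2])
    } else if (sec == "typematrix") {
      i <- as.integer(tok[1L]) + 1L; j <- as.integer(tok[2L]) + 1L
      out$typeMatrix[i, j] <- out$typeMatrix[j, i] <- as.numeric(tok[3L])
    } else if (sec == "idealgamma") {
      out$idealGamma <- as.numeric(tok[1:3])
      out$dMin <- as.integer(tok[4L]); out$dMax <- as.integer(tok[5L])
    } else if (sec == "pairs") {
      pairs[[length(pairs) + 1L]] <- as.integer(tok[1:2])
    }
  }
  out$bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(integer(), ncol = 2L)
  out$loops <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(), ncol = 2L)
  out
}
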