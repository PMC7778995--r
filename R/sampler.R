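#' @include energy.R
NULL

#' Sample a structural ensemble by Langevin dynamics
#'
#' Integrates the chromosome energy landscape with a BAOAB-discretised
#' Langevin thermostat (unit bead mass, reduced units) and collects a
#' structural ensemble. Frames are saved every `saveEvery` steps after the
#' fixed equilibration period, giving
#' `floor((nSteps - equilibrationSteps) / saveEvery)` frames; the result is
#' a time series. The trajectory is deterministic given the seed.
#' Equilibration is not detected automatically: the burn-in length is fixed
#' by the configuration, and an integrated-autocorrelation diagnostic of
#' the radius-of-gyration series is reported in the ensemble header
#' (`diagnostics$rg_autocorrelation_time`, in saved frames).
#'
#' @param system a [ChromosomeSystem-class].
#' @param positions n-by-3 initial coordinates satisfying the bond
#'   constraints (see [initialConformation()]).
#' @param config a [SamplerConfig-class].
#' @return A [ChromEnsemble-class] time series whose records carry the
#'   system's bead types and 50-kb genomic windows.
#' @examples
#' sys <- makeBlockCopolymer(20, 10, seed = 1,
#'   parameters = michromParameters(confinementRadius = 4))
#' pos <- initialConformation(20, 4, seed = 1)
#' cfg <- samplerConfig(nSteps = 500, saveEvery = 100, seed = 7)
#' e <- runLangevin(sys, pos, cfg)
#' nModels(e)
#' @export
runLangevin <- function(system, positions, config) {
  validObject(system); validObject(config)
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == system@nBeads)
  res <- .cppLangevin(positions, system@beadTypes, system@loops,
                      .paramsForCpp(system@parameters),
                      config@nSteps, config@saveEvery,
                      config@equilibrationSteps,
                      config@timestep, config@friction, config@temperature,
                      config@seed)
  nf <- res$n_frames
  fr <- res$frames
  models <- lapply(seq_len(nf), function(k) matrix(fr[, , k], ncol = 3L))
  rec <- beadRecords(system@nBeads,
                     codes = .TYPE_LABELS[system@beadTypes + 1L],
                     resolution = system@resolution)
  lp <- if (nrow(system@loops))
    data.frame(anchor_a = system@loops[, 1L], anchor_b = system@loops[, 2L],
               loop_class = "UNKNOWN", stringsAsFactors = FALSE)
  else NULL
  rg <- vapply(models, function(m) {
    c0 <- colMeans(m)
    sqrt(mean(rowSums((m - matrix(c0, nrow(m), 3L, byrow = TRUE))^2)))
  }, numeric(1))
  chromEnsemble(rec, models, loops = lp,
                header = list(
                  title = "Langevin trajectory",
                  length_unit = "reduced",
                  diagnostics = list(
                    rg_autocorrelation_time = .integratedAct(rg),
                    seed = config@seed)),
                isTimeSeries = TRUE)
}

# integrated autocorrelation time (in saved frames) with a standard
# self-consistent window
.integratedAct <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(NA_real_)
  acf <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[, 1L, 1L]
  tau <- 0.5
  for (k in 2:length(acf)) {
    tau <- tau + acf[k]
    if (k > 5 * tau) break
  }
  max(2 * tau, 1)
}

#' Run independent sampler replicas
#'
#' Replica `k` differs from the base configuration only by its RNG stream:
#' its seed is `seed + k - 1`. Replicas are run sequentially.
#'
#' @param system a [ChromosomeSystem-class].
#' @param config a [SamplerConfig-class] with `nReplicas` set.
#' @param positions optional shared initial coordinates; by default a
#'   deterministic initial conformation is built from the configuration
#'   seed.
#' @return A list of [ChromEnsemble-class] objects, one per replica.
#' @seealso [poolEnsembles()]
#' @export
runReplicas <- function(system, config, positions = NULL) {
  validObject(system); validObject(config)
  if (is.null(positions))
    positions <- initialConformation(system@nBeads,
                                     system@parameters@confinementRadius,
                                     seed = config@seed)
  lapply(seq_len(config@nReplicas), function(k) {
    cfg <- config
    cfg@seed <- config@seed + k - 1L
    cfg@nReplicas <- 1L
    runLangevin(system, positions, cfg)
  })
}

#' Pool replica ensembles into one
#'
#' Concatenates the frames of ensembles sharing identical records and
#' loops. The pooled ensemble is no longer a time series.
#'
#' @param ensembles list of [ChromEnsemble-class] objects.
#' @return A pooled [ChromEnsemble-class].
#' @export
poolEnsembles <- function(ensembles) {
  stopifnot(length(ensembles) >= 1L)
  first <- ensembles[[1L]]
  for (e in ensembles[-1L]) {
    if (!identical(e@records, first@records))
      stop("cannot pool ensembles with differing records")
    if (!identical(e@loops, first@loops))
      stop("cannot pool ensembles with differing loops")
  }
  chromEnsemble(first@records, do.call(c, lapply(ensembles, slot, "models")),
                loops = if (nrow(first@loops)) first@loops else NULL,
                header = first@header[setdiff(names(first@header),
                                              c("model_count",
                                                "compartment_sequence",
                                                "diagnostics"))],
                isTimeSeries = FALSE)
}
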