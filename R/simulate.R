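## Serial-dilution evolution simulator. Each daily cycle is grow ->
## mutate -> dilute: growth within a cycle is deterministic (the fastest
## genotype completes log2(dilutionFactor) doublings, slower genotypes
## proportionally fewer), mutation events are Poisson draws at the cycle
## boundary, and the 1:100 transfer is a multinomial bottleneck — the
## dominant source of drift in serial passage. This generator is what the
## rest of the package is tested against: it emits plate-reader CSVs and
## clone mutation tables with the statistical structure the analysis
## assumes.

#' Number of generations of regrowth per dilution cycle
#'
#' A culture diluted 1:`dilutionFactor` must double `log2(dilutionFactor)`
#' times to regain its pre-dilution density, so a daily 1:100 transfer
#' allows ~6.6 generations of growth per cycle.
#'
#' @param dilutionFactor Fold-dilution per transfer (default 100).
#' @return Numeric scalar, `log2(dilutionFactor)`.
#' @export
#' @examples
#' generationsPerCycle()  # 6.64
generationsPerCycle <- function(dilutionFactor = 100) {
  stopifnot(dilutionFactor > 1)
  log2(dilutionFactor)
}

#' Genotype table for the simulator
#'
#' @param genotypeId Character ids.
#' @param relativeRate Growth rate relative to wild type (1 = wild type);
#'   the anRNAPC cost anchor is a ~20% reduction, i.e. 0.8.
#' @param mutator Logical; mutator genotypes multiply both mutation rates
#'   by the configured `mutatorFactor`.
#' @param carriesAnrnapc Logical; whether the genotype carries the costly
#'   anRNAPC allele (the substrate for reversion/compensation).
#' @param baseMutationLoad Expected number of passenger mutations per
#'   sampled clone (Poisson mean), used by [emitCloneSample()].
#' @return data.frame, one row per genotype.
#' @export
genotypeSpecs <- function(genotypeId, relativeRate, mutator = FALSE,
                          carriesAnrnapc = FALSE, baseMutationLoad = 0) {
  if (any(relativeRate <= 0)) stop("relative rates must be positive")
  df <- data.frame(genotypeId = as.character(genotypeId),
                   relativeRate = as.numeric(relativeRate),
                   mutator = as.logical(mutator),
                   carriesAnrnapc = as.logical(carriesAnrnapc),
                   baseMutationLoad = as.numeric(baseMutationLoad),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$genotypeId)) stop("genotype ids must be unique")
  df
}

#' Serial-dilution simulation settings
#'
#' Defaults encode the experimental regime: 1:100 daily transfers for 16
#' cycles, hence ~6.6 generations of regrowth per cycle. Mutation rates
#' and the bottleneck size are not reported quantities; the defaults are
#' documented illustrative values in a biologically plausible range.
#'
#' @param dilutionFactor Fold-dilution per cycle.
#' @param bottleneckN Cells sampled at each transfer.
#' @param cycles Number of daily transfers.
#' @param muReversion Per-genome, per-generation probability of a
#'   reversion mutation restoring the ancestral allele (single target).
#' @param muCompensation Per-genome, per-generation probability of a
#'   compensatory mutation (several possible target sites, hence the
#'   higher default).
#' @param mutatorFactor Multiplier applied to both rates for mutator
#'   genotypes.
#' @param compensationRateRecovery Fraction of the growth-rate cost
#'   removed by a compensatory mutation (1 = full recovery).
#' @param seed Optional integer seed; when set, [runExperiment()] is
#'   reproducible.
#' @return List of class `"SimulationConfig"`, with
#'   `generationsPerCycle` filled in as `log2(dilutionFactor)`.
#' @export
simulationConfig <- function(dilutionFactor = 100, bottleneckN = 1e6,
                             cycles = 16L, muReversion = 1e-9,
                             muCompensation = 5e-9, mutatorFactor = 100,
                             compensationRateRecovery = 1,
                             seed = NULL) {
  stopifnot(dilutionFactor > 1, bottleneckN >= 1, cycles >= 1,
            muReversion >= 0, muReversion <= 1,
            muCompensation >= 0, muCompensation <= 1,
            mutatorFactor > 0,
            compensationRateRecovery >= 0, compensationRateRecovery <= 1)
  structure(list(dilutionFactor = dilutionFactor,
                 generationsPerCycle = generationsPerCycle(dilutionFactor),
                 bottleneckN = bottleneckN, cycles = as.integer(cycles),
                 muReversion = muReversion, muCompensation = muCompensation,
                 mutatorFactor = mutatorFactor,
                 compensationRateRecovery = compensationRateRecovery,
                 seed = seed),
            class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat(sprintf(paste0("SimulationConfig: 1:%g dilution (%.2f generations/",
                     "cycle), %d cycles, bottleneck %g\n"),
              x$dilutionFactor, x$generationsPerCycle, x$cycles,
              x$bottleneckN))
  cat(sprintf("  mu(reversion) = %g, mu(compensation) = %g, mutator x%g, cost recovery %g\n",
              x$muReversion, x$muCompensation, x$mutatorFactor,
              x$compensationRateRecovery))
  invisible(x)
}

.specRates <- function(state, specs) {
  i <- match(names(state@counts), specs$genotypeId)
  if (anyNA(i))
    stop("population state contains genotype(s) absent from the spec table: ",
         paste(names(state@counts)[is.na(i)], collapse = ", "))
  specs[i, , drop = FALSE]
}

#' One cycle of deterministic within-cycle growth
#'
#' The fastest genotype present completes exactly
#' `generationsPerCycle` doublings; genotype *i* multiplies its abundance
#' by `2^(g * rate_i / max rate)`. Abundances are real-valued at this
#' stage; stochasticity enters only at mutation and dilution.
#'
#' @param state A [PopulationState-class].
#' @param specs A [genotypeSpecs()] table covering every genotype present.
#' @param cfg A [simulationConfig()].
#' @return A [PopulationState-class] of pre-dilution abundances.
#' @export
growCycle <- function(state, specs, cfg) {
  if (sum(state@counts) <= 0) stop("cannot grow an empty population")
  sp <- .specRates(state, specs)
  g <- cfg$generationsPerCycle
  mult <- 2^(g * sp$relativeRate / max(sp$relativeRate))
  PopulationState(state@counts * mult, cycle = state@cycle)
}

#' Multinomial bottleneck transfer
#'
#' Samples `bottleneckN` cells with probabilities proportional to the
#' current abundances; the returned counts sum exactly to the bottleneck
#' size and the cycle index advances by one.
#'
#' @inheritParams growCycle
#' @return A [PopulationState-class] of post-dilution integer counts.
#' @export
diluteState <- function(state, cfg) {
  tot <- sum(state@counts)
  if (tot <= 0) stop("cannot dilute an empty population")
  drawn <- stats::rmultinom(1, size = cfg$bottleneckN,
                            prob = state@counts / tot)[, 1L]
  PopulationState(stats::setNames(as.numeric(drawn), names(state@counts)),
                  cycle = state@cycle + 1L)
}

#' Apply reversion and compensation mutations at a cycle boundary
#'
#' For every genotype carrying the anRNAPC allele, the expected number of
#' events of each kind over the cycle is
#' `abundance x generations x mu` (times `mutatorFactor` for mutators);
#' actual event counts are Poisson draws, capped by the available cells.
#' Reversion moves cells to a derived genotype with the allele removed
#' and its growth rate restored to 1; compensation moves cells to a
#' derived genotype that retains the allele with the rate cost reduced by
#' `compensationRateRecovery`. Derived genotypes are appended to the spec
#' table on first occurrence.
#'
#' @inheritParams growCycle
#' @return List with elements `state`, `specs` and `events` (named vector
#'   `c(reversion =, compensation =)` of event counts this call).
#' @export
mutateState <- function(state, specs, cfg) {
  counts <- state@counts
  events <- c(reversion = 0, compensation = 0)
  g <- cfg$generationsPerCycle
  for (id in names(counts)) {
    sp <- specs[specs$genotypeId == id, ]
    if (!sp$carriesAnrnapc || counts[[id]] <= 0) next
    fac <- if (sp$mutator) cfg$mutatorFactor else 1
    lamRev <- counts[[id]] * g * cfg$muReversion * fac
    lamComp <- counts[[id]] * g * cfg$muCompensation * fac
    nRev <- min(stats::rpois(1, lamRev), floor(counts[[id]]))
    nComp <- min(stats::rpois(1, lamComp),
                 floor(counts[[id]] - nRev))
    if (nRev > 0) {
      did <- paste0(id, "_rev")
      if (!(did %in% specs$genotypeId))
        specs <- rbind(specs, genotypeSpecs(did, 1.0, sp$mutator, FALSE,
                                            sp$baseMutationLoad))
      counts[did] <- (if (did %in% names(counts)) counts[[did]] else 0) + nRev
      counts[id] <- counts[[id]] - nRev
      events["reversion"] <- events[["reversion"]] + nRev
    }
    if (nComp > 0) {
      did <- paste0(id, "_comp")
      if (!(did %in% specs$genotypeId)) {
        newRate <- sp$relativeRate +
          (1 - sp$relativeRate) * cfg$compensationRateRecovery
        specs <- rbind(specs, genotypeSpecs(did, newRate, sp$mutator, TRUE,
                                            sp$baseMutationLoad))
      }
      counts[did] <- (if (did %in% names(counts)) counts[[did]] else 0) + nComp
      counts[id] <- counts[[id]] - nComp
      events["compensation"] <- events[["compensation"]] + nComp
    }
  }
  list(state = PopulationState(counts, cycle = state@cycle),
       specs = specs, events = events)
}

#' Run a serial-dilution experiment
#'
#' Iterates grow -> mutate -> dilute for `cfg$cycles` cycles from the
#' founding state. Reproducible when `cfg$seed` is set.
#'
#' @param initial A [PopulationState-class] founding inoculum (cycle 0).
#' @param specs A [genotypeSpecs()] table.
#' @param cfg A [simulationConfig()].
#' @return List with:
#'   \describe{
#'     \item{trajectory}{data.frame `cycle`, `genotypeId`, `count`,
#'       `frequency`, including the founding state at cycle 0.}
#'     \item{meanRelativeRate}{data.frame `cycle`,
#'       `meanRelativeRate` — the abundance-weighted mean relative growth
#'       rate after each dilution.}
#'     \item{states}{list of per-cycle [PopulationState-class].}
#'     \item{specs}{final spec table (including derived genotypes).}
#'     \item{events}{cumulative reversion/compensation event counts.}
#'   }
#' @export
runExperiment <- function(initial, specs, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  stateRows <- function(st) {
    fr <- st@counts / sum(st@counts)
    data.frame(cycle = st@cycle, genotypeId = names(st@counts),
               count = as.numeric(st@counts), frequency = as.numeric(fr),
               stringsAsFactors = FALSE)
  }
  meanRate <- function(st, sp) {
    r <- .specRates(st, sp)$relativeRate
    sum(st@counts * r) / sum(st@counts)
  }
  state <- initial
  traj <- list(stateRows(state))
  rates <- list(data.frame(cycle = state@cycle,
                           meanRelativeRate = meanRate(state, specs)))
  states <- list(state)
  events <- c(reversion = 0, compensation = 0)
  for (k in seq_len(cfg$cycles)) {
    state <- growCycle(state, specs, cfg)
    mt <- mutateState(state, specs, cfg)
    state <- mt$state
    specs <- mt$specs
    events <- events + mt$events
    state <- diluteState(state, cfg)
    traj[[k + 1L]] <- stateRows(state)
    rates[[k + 1L]] <- data.frame(cycle = state@cycle,
                                  meanRelativeRate = meanRate(state, specs))
    states[[k + 1L]] <- state
  }
  list(trajectory = do.call(rbind, traj),
       meanRelativeRate = do.call(rbind, rates),
       states = states, specs = specs, events = events)
}

## Deterministic synthetic founder mutations for one genotype: positions
## are spread over the genome away from the fabricated anRNAPC/RNAPC
## coordinates used below.
.founderMutations <- function(specRow, genotypeIndex) {
  muts <- emptyMutationTable()
  base <- 100000L + genotypeIndex * 10000L
  nFounder <- 3L
  muts <- rbind(muts, mutationRecord(base + seq_len(nFounder) * 97L,
                                     "A", "G", paste0("gene", genotypeIndex,
                                                      "_", seq_len(nFounder)),
                                     10L + seq_len(nFounder),
                                     "nonsynonymous"))
  if (specRow$mutator)
    muts <- rbind(muts, mutationRecord(2740000L + genotypeIndex, "G", "T",
                                       "mutS", 250L, "nonsynonymous"))
  if (specRow$carriesAnrnapc)
    muts <- rbind(muts, mutationRecord(4185000L + genotypeIndex, "C", "T",
                                       "rpoB", 1272L, "nonsynonymous"))
  muts
}

#' Sample sequenced clones from a population state
#'
#' Draws `nClones` clones with genotype probabilities proportional to the
#' current abundances and fabricates each clone's mutation table: a small
#' deterministic set of founder-defining mutations per genotype (plus a
#' mismatch-repair mutation for mutators and the anRNAPC allele when
#' carried), and `Poisson(baseMutationLoad)` passenger point mutations
#' whose nonsynonymous/synonymous classes are drawn in proportion to the
#' supplied fractional site counts.
#'
#' @param state A [PopulationState-class].
#' @param specs A [genotypeSpecs()] table.
#' @param nClones Number of clones to draw.
#' @param sites A [SiteCounts-class] giving the neutral NS:S proportion
#'   for passenger classes.
#' @param population Population label for the emitted clones.
#' @return List of [CloneGenotype-class] objects, tagged with the state's
#'   cycle.
#' @export
emitCloneSample <- function(state, specs, nClones,
                            sites = siteCountsFromCodonUsage(ecoliCodonUsage()),
                            population = "sim") {
  stopifnot(nClones >= 1)
  fr <- genotypeFrequencies(state)
  picks <- sample(names(fr), nClones, replace = TRUE, prob = fr)
  pNs <- sites@nsSites / (sites@nsSites + sites@synSites)
  lapply(seq_len(nClones), function(j) {
    id <- picks[j]
    gi <- match(id, specs$genotypeId)
    sp <- specs[gi, ]
    muts <- .founderMutations(sp, gi)
    nPass <- stats::rpois(1, sp$baseMutationLoad)
    if (nPass > 0) {
      pos <- sample(setdiff(seq(500000L, 2500000L, by = 13L),
                            muts$position), nPass)
      cls <- ifelse(stats::runif(nPass) < pNs, "nonsynonymous", "synonymous")
      muts <- rbind(muts, mutationRecord(pos, "T", "C",
                                         paste0("pgene", seq_len(nPass)),
                                         5L, cls))
    }
    CloneGenotype(cloneId = sprintf("%s_c%d_%d", id, state@cycle, j),
                  population = population, day = 127,
                  cycle = state@cycle, mutations = muts,
                  mutator = sp$mutator)
  })
}

#' Emit synthetic plate-reader OD curves for a set of genotypes
#'
#' Generates one logistic OD600 trajectory per genotype, sampled every
#' `intervalMin` minutes: intrinsic rate `relativeRate * wildtypeRate`,
#' optional lag, carrying capacity `capacity` (use `Inf` for pure
#' exponential growth), and Gaussian measurement noise. The default
#' noise model is proportional (a standard deviation of `noiseSd` on the
#' log scale, i.e. ~0.2% relative read error at the default), which keeps
#' the signal-to-noise profile uniform across the fitted OD range;
#' `noiseModel = "additive"` instead adds `noiseSd` in OD units
#' (truncated at zero), which leaves low-OD readings noise-dominated and
#' degrades sliding-window rate estimates accordingly.
#'
#' @param specs A [genotypeSpecs()] table; one curve per row.
#' @param wildtypeRate Wild-type exponential rate constant, per minute
#'   (default 0.025, a ~28-minute doubling time in rich medium).
#' @param od0 Inoculum OD (default 0.005).
#' @param capacity Saturating OD (default 1.0).
#' @param lagMin Lag before exponential growth starts, minutes.
#' @param noiseSd Standard deviation of the measurement noise: on the
#'   log scale for `"proportional"`, in OD units for `"additive"`.
#' @param noiseModel `"proportional"` (default) or `"additive"`.
#' @param intervalMin Sampling interval, minutes (default 10).
#' @param durationMin Total duration, minutes.
#' @return Named list of [ODCurve-class], one per genotype.
#' @export
emitOdCurves <- function(specs, wildtypeRate = 0.025, od0 = 0.005,
                         capacity = 1.0, lagMin = 0, noiseSd = 0.002,
                         noiseModel = c("proportional", "additive"),
                         intervalMin = 10, durationMin = 600) {
  noiseModel <- match.arg(noiseModel)
  times <- seq(0, durationMin, by = intervalMin)
  curves <- lapply(seq_len(nrow(specs)), function(i) {
    r <- specs$relativeRate[i] * wildtypeRate
    tEff <- pmax(times - lagMin, 0)
    od <- if (is.infinite(capacity)) od0 * exp(r * tEff)
          else capacity * od0 * exp(r * tEff) /
               (capacity + od0 * (exp(r * tEff) - 1))
    if (noiseSd > 0) {
      od <- if (noiseModel == "proportional")
        od * exp(stats::rnorm(length(od), 0, noiseSd))
      else pmax(od + stats::rnorm(length(od), 0, noiseSd), 0)
    }
    ODCurve(specs$genotypeId[i], times, od)
  })
  stats::setNames(curves, specs$genotypeId)
}
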