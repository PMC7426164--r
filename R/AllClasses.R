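#' @import methods
NULL

#' Mutation classes recognised by the package
#'
#' The annotation vocabulary used throughout the mutation catalogue:
#' point mutations within coding regions are `nonsynonymous`, `synonymous`
#' or `nonsense`; short indels within coding regions are `frameshift`;
#' `noncoding` covers mutations in untranslated but transcribed features,
#' `intergenic` those between annotated features; `large_deletion` and
#' `new_junction` are the structural events a resequencing caller reports.
#'
#' @return Character vector of the eight recognised class labels.
#' @export
#' @examples
#' mutationClasses()
mutationClasses <- function() {
  c("nonsynonymous", "synonymous", "nonsense", "frameshift",
    "noncoding", "intergenic", "large_deletion", "new_junction")
}

## Column layout shared by every mutation table in the package.
.mutationCols <- c(position = "integer", ref = "character", alt = "character",
                   gene = "character", aaPosition = "integer",
                   mclass = "character")

#' A single well's optical-density time series
#'
#' One OD600 trajectory from a plate reader: a sample identifier, a strictly
#' increasing vector of times (minutes) and one non-negative OD reading per
#' time point.
#'
#' @slot sampleId Character scalar naming the well/sample.
#' @slot times Numeric vector of measurement times in minutes, strictly
#'   increasing.
#' @slot od Numeric vector of OD600 readings, same length as `times`,
#'   all values >= 0.
#'
#' @export
#' @examples
#' ODCurve("wt1", times = seq(0, 200, 10), od = 0.01 * exp(0.02 * seq(0, 200, 10)))
setClass("ODCurve",
         representation(sampleId = "character", times = "numeric",
                        od = "numeric"))

setValidity("ODCurve", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-NA string")
  if (length(object@times) != length(object@od))
    msg <- c(msg, "'times' and 'od' must have equal length")
  if (anyNA(object@times) || is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "'times' must be strictly increasing and free of NA")
  if (anyNA(object@od) || any(object@od < 0))
    msg <- c(msg, "'od' values must be non-negative and free of NA")
  if (length(msg)) msg else TRUE
})

#' @rdname ODCurve-class
#' @param sampleId,times,od See slots above.
#' @export
ODCurve <- function(sampleId, times, od) {
  new("ODCurve", sampleId = as.character(sampleId),
      times = as.numeric(times), od = as.numeric(od))
}

#' Result of a sliding-window exponential growth-rate fit
#'
#' Produced by [fitExponentialRate()]. When no window of the curve passes
#' the R-squared acceptance threshold the estimate is unqualified and the
#' rate is `NA`.
#'
#' @slot rate Per-minute slope of ln(OD) against time for the winning
#'   window; `NA_real_` when unqualified.
#' @slot windowStart Integer index (into the curve's time vector) of the
#'   first point of the winning window; `NA` when unqualified.
#' @slot windowR2 Coefficient of determination of the winning window;
#'   `NA` when unqualified.
#' @slot qualified Logical; `TRUE` when some window met the threshold.
#'
#' @export
setClass("GrowthRateEstimate",
         representation(rate = "numeric", windowStart = "integer",
                        windowR2 = "numeric", qualified = "logical"))

setValidity("GrowthRateEstimate", function(object) {
  msg <- character()
  if (length(object@qualified) != 1L || is.na(object@qualified))
    msg <- c(msg, "'qualified' must be TRUE or FALSE")
  else if (object@qualified) {
    if (is.na(object@rate)) msg <- c(msg, "qualified estimates carry a rate")
    if (is.na(object@windowR2) || object@windowR2 < 0 || object@windowR2 > 1)
      msg <- c(msg, "'windowR2' must lie in [0, 1]")
  } else if (!is.na(object@rate)) {
    msg <- c(msg, "unqualified estimates must have NA rate")
  }
  if (length(msg)) msg else TRUE
})

#' A sequenced clone and its mutation set
#'
#' The genotype of one clone: identifying metadata (population of origin,
#' LTSP day sampled, serial-dilution cycle sampled) plus the set of
#' mutations called against the ancestral reference, stored as a
#' data.frame with columns `position`, `ref`, `alt`, `gene`, `aaPosition`
#' and `mclass`. Mutation identity is the (position, alt) pair; duplicates
#' under that key are rejected.
#'
#' @slot cloneId Character scalar, e.g. `"2_13"`.
#' @slot population Character scalar identifying the source population.
#' @slot day Numeric LTSP day at which the founding sample was taken.
#' @slot cycle Numeric serial-dilution cycle at which the clone was
#'   sampled (0 for LTSP isolates themselves).
#' @slot mutations data.frame of mutations (see Details).
#' @slot mutator Logical; curated mutator status.
#' @slot reference Character scalar naming the reference genome the
#'   coordinates refer to.
#'
#' @export
setClass("CloneGenotype",
         representation(cloneId = "character", population = "character",
                        day = "numeric", cycle = "numeric",
                        mutations = "data.frame", mutator = "logical",
                        reference = "character"))

setValidity("CloneGenotype", function(object) {
  msg <- character()
  m <- object@mutations
  missing <- setdiff(names(.mutationCols), names(m))
  if (length(missing))
    msg <- c(msg, paste0("mutation table lacks column(s): ",
                         paste(missing, collapse = ", ")))
  else {
    if (nrow(m) && anyDuplicated(m[, c("position", "alt")]))
      msg <- c(msg, "duplicate (position, alt) mutation keys")
    if (nrow(m) && any(m$position < 1L, na.rm = TRUE))
      msg <- c(msg, "positions must be >= 1")
    bad <- setdiff(unique(m$mclass), mutationClasses())
    if (length(bad))
      msg <- c(msg, paste0("unknown mutation class(es): ",
                           paste(bad, collapse = ", ")))
  }
  if (length(object@mutator) != 1L || is.na(object@mutator))
    msg <- c(msg, "'mutator' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Mutations ever observed in a population's sequencing history
#'
#' The deduplicated union of all mutations seen in any sequenced clone of
#' one population across its sampled time points. Used to define which
#' mutations of a later clone count as new (see
#' [newMutationsVsHistory()]).
#'
#' @slot population Character scalar.
#' @slot observedMutations Mutation data.frame (same layout as in
#'   [CloneGenotype-class]), deduplicated by (position, alt).
#'
#' @export
setClass("PopulationHistory",
         representation(population = "character",
                        observedMutations = "data.frame"))

setValidity("PopulationHistory", function(object) {
  m <- object@observedMutations
  if (nrow(m) && anyDuplicated(m[, c("position", "alt")]))
    "observed mutations must be deduplicated by (position, alt)" else TRUE
})

#' Genome-wide fractional site counts
#'
#' Fractional counts of nonsynonymous and synonymous sites summed over a
#' set of coding sequences: each coding position contributes to each class
#' the fraction of its possible single-nucleotide substitutions producing
#' that class of change.
#'
#' @slot nsSites Fractional count of nonsynonymous sites.
#' @slot synSites Fractional count of synonymous sites.
#'
#' @export
setClass("SiteCounts",
         representation(nsSites = "numeric", synSites = "numeric"))

setValidity("SiteCounts", function(object) {
  if (length(object@nsSites) != 1L || length(object@synSites) != 1L ||
      is.na(object@nsSites) || is.na(object@synSites) ||
      object@nsSites < 0 || object@synSites < 0)
    "'nsSites' and 'synSites' must be single non-negative numbers" else TRUE
})

#' dN/dS and its enrichment test for one mutation set
#'
#' Counts of nonsynonymous and synonymous new mutations, the per-site rate
#' ratio dN/dS (NA when no synonymous mutations were observed), and the
#' 1-df chi-squared goodness-of-fit statistic with its upper-tail p-value
#' against the neutral expectation implied by the site counts.
#'
#' @slot nNsMut,nSynMut Observed mutation counts.
#' @slot dnds Ratio of per-site rates; `NA_real_` when `nSynMut == 0`.
#' @slot chi2Stat,pValue Goodness-of-fit statistic and p-value.
#' @slot sites The [SiteCounts-class] used.
#'
#' @export
setClass("DnDsResult",
         representation(nNsMut = "numeric", nSynMut = "numeric",
                        dnds = "numeric", chi2Stat = "numeric",
                        pValue = "numeric", sites = "SiteCounts"))

setValidity("DnDsResult", function(object) {
  msg <- character()
  if (object@nNsMut < 0 || object@nSynMut < 0)
    msg <- c(msg, "mutation counts must be non-negative")
  if (!is.na(object@dnds) && object@dnds < 0)
    msg <- c(msg, "dnds must be >= 0")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Genotype abundances at one point of a serial-dilution experiment
#'
#' A named vector of cell counts (or, transiently between growth and
#' dilution, real-valued abundances) per genotype, tagged with the cycle
#' index.
#'
#' @slot cycle Integer dilution-cycle index (0 = founding inoculum).
#' @slot counts Named numeric vector, one entry per genotype, all >= 0.
#'
#' @export
setClass("PopulationState",
         representation(cycle = "integer", counts = "numeric"))

setValidity("PopulationState", function(object) {
  msg <- character()
  if (is.null(names(object@counts)) || anyNA(names(object@counts)))
    msg <- c(msg, "'counts' must be named by genotype id")
  if (anyNA(object@counts) || any(object@counts < 0))
    msg <- c(msg, "'counts' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname PopulationState-class
#' @param counts Named non-negative numeric vector of genotype abundances.
#' @param cycle Integer cycle index.
#' @export
PopulationState <- function(counts, cycle = 0L) {
  new("PopulationState", cycle = as.integer(cycle), counts = counts)
}
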