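#' @name accessors
#' @title Accessors for the core classes
#' @description Small accessor generics so user code never touches slots.
#' @param object One of the package's S4 objects.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "ODCurve", function(object) object@sampleId)

#' @rdname accessors
#' @export
setGeneric("odReadings", function(object) standardGeneric("odReadings"))
#' @rdname accessors
#' @export
setMethod("odReadings", "ODCurve", function(object)
  data.frame(time_min = object@times, od = object@od))

#' @rdname accessors
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))
#' @rdname accessors
#' @export
setMethod("growthRate", "GrowthRateEstimate", function(object) object@rate)

#' @rdname accessors
#' @export
setGeneric("isQualified", function(object) standardGeneric("isQualified"))
#' @rdname accessors
#' @export
setMethod("isQualified", "GrowthRateEstimate", function(object) object@qualified)

#' @rdname accessors
#' @export
setGeneric("windowR2", function(object) standardGeneric("windowR2"))
#' @rdname accessors
#' @export
setMethod("windowR2", "GrowthRateEstimate", function(object) object@windowR2)

#' @rdname accessors
#' @export
setGeneric("windowStart", function(object) standardGeneric("windowStart"))
#' @rdname accessors
#' @export
setMethod("windowStart", "GrowthRateEstimate", function(object) object@windowStart)

#' @rdname accessors
#' @export
setGeneric("cloneId", function(object) standardGeneric("cloneId"))
#' @rdname accessors
#' @export
setMethod("cloneId", "CloneGenotype", function(object) object@cloneId)

#' @rdname accessors
#' @export
setGeneric("mutations", function(object) standardGeneric("mutations"))
#' @rdname accessors
#' @export
setMethod("mutations", "CloneGenotype", function(object) object@mutations)
#' @rdname accessors
#' @export
setMethod("mutations", "PopulationHistory", function(object)
  object@observedMutations)

#' @rdname accessors
#' @export
setGeneric("isMutator", function(object) standardGeneric("isMutator"))
#' @rdname accessors
#' @export
setMethod("isMutator", "CloneGenotype", function(object) object@mutator)

#' @rdname accessors
#' @export
setGeneric("population", function(object) standardGeneric("population"))
#' @rdname accessors
#' @export
setMethod("population", "CloneGenotype", function(object) object@population)
#' @rdname accessors
#' @export
setMethod("population", "PopulationHistory", function(object) object@population)

#' @rdname accessors
#' @export
setGeneric("dilutionCycle", function(object) standardGeneric("dilutionCycle"))
#' @rdname accessors
#' @export
setMethod("dilutionCycle", "CloneGenotype", function(object) object@cycle)
#' @rdname accessors
#' @export
setMethod("dilutionCycle", "PopulationState", function(object) object@cycle)

#' @rdname accessors
#' @export
setGeneric("nsSites", function(object) standardGeneric("nsSites"))
#' @rdname accessors
#' @export
setMethod("nsSites", "SiteCounts", function(object) object@nsSites)

#' @rdname accessors
#' @export
setGeneric("synSites", function(object) standardGeneric("synSites"))
#' @rdname accessors
#' @export
setMethod("synSites", "SiteCounts", function(object) object@synSites)

#' @rdname accessors
#' @export
setGeneric("dndsValue", function(object) standardGeneric("dndsValue"))
#' @rdname accessors
#' @export
setMethod("dndsValue", "DnDsResult", function(object) object@dnds)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "DnDsResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("chi2Stat", function(object) standardGeneric("chi2Stat"))
#' @rdname accessors
#' @export
setMethod("chi2Stat", "DnDsResult", function(object) object@chi2Stat)

#' @rdname accessors
#' @export
setGeneric("genotypeCounts", function(object) standardGeneric("genotypeCounts"))
#' @rdname accessors
#' @export
setMethod("genotypeCounts", "PopulationState", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("genotypeFrequencies",
           function(object) standardGeneric("genotypeFrequencies"))
#' @rdname accessors
#' @export
setMethod("genotypeFrequencies", "PopulationState", function(object) {
  tot <- sum(object@counts)
  if (tot == 0) stop("population state has zero total abundance")
  object@counts / tot
})

setMethod("show", "ODCurve", function(object) {
  cat("ODCurve '", object@sampleId, "': ", length(object@times),
      " readings, t = ", min(object@times), "-", max(object@times),
      " min, OD ", signif(min(object@od), 3), "-",
      signif(max(object@od), 3), "\n", sep = "")
})

setMethod("show", "GrowthRateEstimate", function(object) {
  if (object@qualified)
    cat(sprintf("GrowthRateEstimate: %.6g /min (window start %d, R2 = %.4f)\n",
                object@rate, object@windowStart, object@windowR2))
  else cat("GrowthRateEstimate: unqualified (no window met the R2 threshold)\n")
})

setMethod("show", "CloneGenotype", function(object) {
  cat(sprintf("CloneGenotype '%s' (population %s, day %g, cycle %g): %d mutations, %s\n",
              object@cloneId, object@population, object@day, object@cycle,
              nrow(object@mutations),
              if (object@mutator) "mutator" else "non-mutator"))
})

setMethod("show", "SiteCounts", function(object) {
  cat(sprintf("SiteCounts: %.2f nonsynonymous, %.2f synonymous (NS:S = %.4f)\n",
              object@nsSites, object@synSites,
              object@nsSites / object@synSites))
})

setMethod("show", "DnDsResult", function(object) {
  cat(sprintf("DnDsResult: %g NS / %g S new mutations; dN/dS = %s; chi2 = %.3g, p = %.3g\n",
              object@nNsMut, object@nSynMut,
              ifelse(is.na(object@dnds), "N/A", sprintf("%.4f", object@dnds)),
              object@chi2Stat, object@pValue))
})

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState (cycle %d): %d genotypes, total %.4g cells\n",
              object@cycle, length(object@counts), sum(object@counts)))
})
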