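## Fractional-site dN/dS. Each coding position contributes to the
## nonsynonymous and synonymous site totals the fraction of its three
## possible single-nucleotide substitutions that produce each kind of
## change; the third position of a 4-fold degenerate codon is a full
## synonymous site, that of a 2-fold degenerate codon contributes 1/3
## synonymous and 2/3 nonsynonymous. dN/dS is then the ratio of observed
## per-site mutation rates, and enrichment against the neutral
## expectation is tested by a 1-df chi-squared goodness of fit.

.NT <- c("A", "C", "G", "T")

.normCodon <- function(codon) {
  codon <- toupper(gsub("U", "T", codon))
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("'", codon, "' is not an unambiguous DNA codon")
  codon
}

#' The genetic code used by default (bacterial, translation table 11)
#'
#' @return Named character vector mapping the 64 codons to amino acids
#'   (`*` for stops), from [Biostrings::getGeneticCode()].
#' @export
defaultGeneticCode <- function() Biostrings::getGeneticCode("11")

#' Per-position fractional site contributions of one codon
#'
#' Enumerates the three single-nucleotide substitutions at each codon
#' position. Under the default `stop_as_ns` policy a substitution
#' creating a stop codon counts as nonsynonymous, so each position's two
#' fractions sum to exactly 1 and the codon contributes 3 sites in total;
#' under `exclude_stop_targets` substitutions to stop codons are removed
#' from the denominator (positions whose every substitution creates a
#' stop contribute nothing).
#'
#' @param codon A sense codon (DNA or RNA alphabet); stop codons are
#'   rejected.
#' @param code Genetic code, as from [Biostrings::getGeneticCode()].
#' @param stopPolicy `"stop_as_ns"` (default) or `"exclude_stop_targets"`.
#' @return List with elements `codon` and `perPosition`, a 3 x 2 matrix
#'   with columns `ns` and `syn`.
#' @export
#' @examples
#' codonSiteContributions("GGG")$perPosition  # third row: 0 ns, 1 syn
#' codonSiteContributions("AAT")$perPosition  # third row: 2/3 ns, 1/3 syn
codonSiteContributions <- function(codon, code = defaultGeneticCode(),
                                   stopPolicy = c("stop_as_ns",
                                                  "exclude_stop_targets")) {
  stopPolicy <- match.arg(stopPolicy)
  codon <- .normCodon(codon)
  aa <- code[[codon]]
  if (is.null(aa) || aa == "*")
    stop("'", codon, "' is a stop codon; site contributions are defined ",
         "for sense codons only")
  per <- matrix(0, nrow = 3, ncol = 2, dimnames = list(NULL, c("ns", "syn")))
  for (p in 1:3) {
    nSyn <- 0L; nNs <- 0L
    for (nt in setdiff(.NT, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- nt
      maa <- code[[mut]]
      if (maa == "*") {
        if (stopPolicy == "stop_as_ns") nNs <- nNs + 1L
        ## else: dropped from the denominator
      } else if (maa == aa) nSyn <- nSyn + 1L else nNs <- nNs + 1L
    }
    denom <- if (stopPolicy == "stop_as_ns") 3L else nSyn + nNs
    if (denom > 0L) {
      per[p, "syn"] <- nSyn / denom
      per[p, "ns"] <- nNs / denom
    }
  }
  list(codon = codon, perPosition = per)
}

## codon -> c(ns, syn) totals for all sense codons of `code`.
.contribTable <- function(code = defaultGeneticCode(),
                          stopPolicy = "stop_as_ns") {
  sense <- names(code)[code != "*"]
  t(vapply(sense, function(cd)
    colSums(codonSiteContributions(cd, code, stopPolicy)$perPosition),
    numeric(2)))[, c("ns", "syn"), drop = FALSE]
}

#' @rdname SiteCounts-class
#' @param nsSites,synSites Fractional site totals.
#' @export
SiteCounts <- function(nsSites, synSites) {
  new("SiteCounts", nsSites = as.numeric(nsSites),
      synSites = as.numeric(synSites))
}

#' Fractional site counts over a set of coding sequences
#'
#' Sums per-codon fractional contributions over every codon of every CDS.
#' A terminal stop codon, when present, is excluded from counting;
#' internal stop codons and lengths not divisible by three are errors
#' unless `onInvalid = "skip"`, in which case the offending record is
#' dropped with a warning.
#'
#' @param cds A [Biostrings::DNAStringSet], or a character vector of DNA
#'   sequences.
#' @param code,stopPolicy See [codonSiteContributions()].
#' @param onInvalid `"error"` (default) or `"skip"`.
#' @return A [SiteCounts-class].
#' @export
#' @examples
#' siteCounts(c("ATGGGG"))
siteCounts <- function(cds, code = defaultGeneticCode(),
                       stopPolicy = c("stop_as_ns", "exclude_stop_targets"),
                       onInvalid = c("error", "skip")) {
  stopPolicy <- match.arg(stopPolicy)
  onInvalid <- match.arg(onInvalid)
  if (is(cds, "DNAStringSet")) cds <- as.character(cds)
  cds <- toupper(gsub("U", "T", cds))
  if (length(cds) == 0L) stop("empty CDS input")
  stops <- names(code)[code == "*"]
  contrib <- .contribTable(code, stopPolicy)
  counts <- numeric(nrow(contrib))
  names(counts) <- rownames(contrib)
  nm <- if (!is.null(names(cds))) names(cds) else as.character(seq_along(cds))
  for (i in seq_along(cds)) {
    s <- cds[[i]]
    bad <- NULL
    if (nchar(s) %% 3L != 0L)
      bad <- paste0("length ", nchar(s), " not divisible by 3")
    else {
      codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
      if (length(codons) && codons[length(codons)] %in% stops)
        codons <- codons[-length(codons)]       # terminal stop not counted
      if (any(codons %in% stops))
        bad <- "internal stop codon"
      else if (any(grepl("[^ACGT]", codons)))
        bad <- "non-ACGT character"
    }
    if (!is.null(bad)) {
      if (onInvalid == "error")
        stop("CDS record '", nm[i], "': ", bad)
      warning("skipping CDS record '", nm[i], "': ", bad)
      next
    }
    if (length(codons)) {
      tab <- table(codons)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  if (sum(counts) == 0)
    stop("no countable codons in input")
  SiteCounts(sum(counts * contrib[, "ns"]), sum(counts * contrib[, "syn"]))
}

#' Fractional site counts from a codon-usage composition
#'
#' Site counts are linear in codon counts, so the genome-wide fractional
#' site totals of a CDS complement are fully determined by its codon
#' usage. This computes them from any relative codon-usage vector
#' (absolute counts, frequencies per 1000, or fractions — the dN/dS ratio
#' and the enrichment test depend only on the NS:S proportion, which is
#' scale-free).
#'
#' @param usage Named numeric vector of non-negative codon weights; names
#'   are codons (DNA or RNA alphabet). Stop codons, if present, are
#'   ignored with a message.
#' @param code,stopPolicy See [codonSiteContributions()].
#' @return A [SiteCounts-class].
#' @export
#' @examples
#' siteCountsFromCodonUsage(ecoliCodonUsage())
siteCountsFromCodonUsage <- function(usage, code = defaultGeneticCode(),
                                     stopPolicy = c("stop_as_ns",
                                                    "exclude_stop_targets")) {
  stopPolicy <- match.arg(stopPolicy)
  if (is.null(names(usage)) || anyNA(names(usage)))
    stop("'usage' must be a named codon vector")
  names(usage) <- toupper(gsub("U", "T", names(usage)))
  if (any(usage < 0, na.rm = TRUE)) stop("codon weights must be >= 0")
  stops <- names(code)[code == "*"]
  if (any(names(usage) %in% stops)) {
    message("ignoring ", sum(names(usage) %in% stops),
            " stop-codon entries in the usage vector")
    usage <- usage[!(names(usage) %in% stops)]
  }
  unknown <- setdiff(names(usage), names(code))
  if (length(unknown))
    stop("unknown codon(s) in usage vector: ", paste(unknown, collapse = ", "))
  contrib <- .contribTable(code, stopPolicy)
  w <- usage[rownames(contrib)]
  w[is.na(w)] <- 0
  SiteCounts(sum(w * contrib[, "ns"]), sum(w * contrib[, "syn"]))
}

#' Codon usage of the E. coli K-12 MG1655 coding-gene complement
#'
#' The relative codon usage (frequency per 1000 codons) of the protein-
#' coding genes of E. coli K-12 MG1655, as tabulated in the standard
#' codon-usage compilations, shipped with the package as a plain-text
#' table. Feed it to [siteCountsFromCodonUsage()] to obtain the
#' genome-wide fractional site counts without the CDS FASTA itself.
#'
#' @return Named numeric vector over the 61 sense codons.
#' @export
ecoliCodonUsage <- function() {
  path <- system.file("extdata", "NC_000913_codon_usage.tsv",
                      package = "ltspRecovery", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(df$per_1000, df$codon)
}

#' dN/dS from mutation counts and site counts
#'
#' The ratio of per-site mutation rates:
#' `(nNsMut / nsSites) / (nSynMut / synSites)`. Undefined (returned as
#' `NA_real_`) when no synonymous mutations were observed.
#'
#' @param nNsMut,nSynMut Observed counts of nonsynonymous and synonymous
#'   new mutations.
#' @param sites A [SiteCounts-class].
#' @return Numeric scalar, or `NA_real_` when `nSynMut == 0`.
#' @export
#' @examples
#' dnds(160, 104, siteCountsFromCodonUsage(ecoliCodonUsage()))  # ~0.47
dnds <- function(nNsMut, nSynMut, sites) {
  stopifnot(is(sites, "SiteCounts"), nNsMut >= 0, nSynMut >= 0)
  if (nSynMut == 0) return(NA_real_)
  (nNsMut / sites@nsSites) / (nSynMut / sites@synSites)
}

#' Chi-squared test of NS/S enrichment against the neutral expectation
#'
#' Two-category goodness of fit: under neutrality the observed mutations
#' split between nonsynonymous and synonymous in proportion to the
#' fractional site counts. The statistic is the usual
#' `sum((obs - exp)^2 / exp)` with 1 degree of freedom and no continuity
#' correction; the p-value is its upper tail.
#'
#' @inheritParams dnds
#' @return List with `chi2Stat` and `pValue`.
#' @export
chiSquareEnrichment <- function(nNsMut, nSynMut, sites) {
  stopifnot(is(sites, "SiteCounts"))
  total <- nNsMut + nSynMut
  if (total <= 0) stop("no observed mutations to test")
  pNs <- sites@nsSites / (sites@nsSites + sites@synSites)
  expected <- total * c(pNs, 1 - pNs)
  observed <- c(nNsMut, nSynMut)
  stat <- sum((observed - expected)^2 / expected)
  list(chi2Stat = stat,
       pValue = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Full dN/dS result for one mutation set
#'
#' @inheritParams dnds
#' @return A [DnDsResult-class].
#' @export
dndsResult <- function(nNsMut, nSynMut, sites) {
  chi <- chiSquareEnrichment(nNsMut, nSynMut, sites)
  new("DnDsResult", nNsMut = as.numeric(nNsMut), nSynMut = as.numeric(nSynMut),
      dnds = dnds(nNsMut, nSynMut, sites), chi2Stat = chi$chi2Stat,
      pValue = chi$pValue, sites = sites)
}

#' Generate synthetic coding sequences from a codon usage
#'
#' Draws sense codons in proportion to a codon-usage vector, prepends an
#' ATG start and appends a TAA terminal stop. Useful for exercising the
#' FASTA-based site-counting path without a reference download; the
#' resulting sequences are synthetic, not genomic.
#'
#' @param n Number of sequences.
#' @param lengthCodons Number of internal codons per sequence.
#' @param usage Codon-usage weights (default [ecoliCodonUsage()]).
#' @return A [Biostrings::DNAStringSet].
#' @export
syntheticCodingSequences <- function(n, lengthCodons,
                                     usage = ecoliCodonUsage()) {
  names(usage) <- toupper(gsub("U", "T", names(usage)))
  seqs <- vapply(seq_len(n), function(i) {
    body <- sample(names(usage), lengthCodons, replace = TRUE,
                   prob = usage / sum(usage))
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, paste0("synthetic_cds_",
                                                        seq_len(n))))
}
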