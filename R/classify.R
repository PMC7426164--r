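## Classification of RNA polymerase core-enzyme (RNAPC) alleles and of
## recovery outcomes (reversion vs compensation vs retention).

#' Configuration of the convergent, antagonistically pleiotropic RNAPC sites
#'
#' The anRNAPC sites are the three convergent RNAPC residues repeatedly
#' mutated during LTSP adaptation: RpoB 1272, RpoC 334 and RpoC 428.
#' Clones with RNAPC mutations elsewhere are classified `other_RNAPC`.
#'
#' @param sites data.frame with columns `gene` and `aaPosition` naming the
#'   anRNAPC residues.
#' @param rnapcGenes Character vector of RNAPC gene names.
#' @return A list of class `"AnRnapcConfig"`.
#' @export
#' @examples
#' anRnapcConfig()
anRnapcConfig <- function(sites = data.frame(
                            gene = c("rpoB", "rpoC", "rpoC"),
                            aaPosition = c(1272L, 334L, 428L),
                            stringsAsFactors = FALSE),
                          rnapcGenes = c("rpoA", "rpoB", "rpoC")) {
  stopifnot(all(c("gene", "aaPosition") %in% names(sites)),
            all(sites$aaPosition >= 1))
  if (!all(tolower(sites$gene) %in% tolower(rnapcGenes)))
    stop("anRNAPC sites must lie within the configured RNAPC genes")
  structure(list(sites = sites, rnapcGenes = rnapcGenes),
            class = "AnRnapcConfig")
}

#' @export
print.AnRnapcConfig <- function(x, ...) {
  cat("AnRnapcConfig:", paste0(x$sites$gene, " ", x$sites$aaPosition,
                               collapse = ", "),
      "| RNAPC genes:", paste(x$rnapcGenes, collapse = ", "), "\n")
  invisible(x)
}

.siteLabel <- function(gene, aaPosition) {
  ## "rpoB" 1272 -> "anRNAPC_rpoB1272"
  paste0("anRNAPC_", gene, aaPosition)
}

#' RNAPC category labels for a configuration
#'
#' @param cfg An [anRnapcConfig()].
#' @return Character vector: one `anRNAPC_<gene><residue>` label per
#'   configured site (sorted), then `other_RNAPC`, then `none`.
#' @export
rnapcCategories <- function(cfg = anRnapcConfig()) {
  c(sort(.siteLabel(cfg$sites$gene, cfg$sites$aaPosition)),
    "other_RNAPC", "none")
}

.anrnapcHits <- function(clone, cfg) {
  m <- clone@mutations
  coding <- m[!is.na(m$aaPosition) & !is.na(m$gene), , drop = FALSE]
  if (nrow(coding) == 0L) return(coding)
  key <- paste(tolower(coding$gene), coding$aaPosition)
  cfgKey <- paste(tolower(cfg$sites$gene), cfg$sites$aaPosition)
  coding[key %in% cfgKey, , drop = FALSE]
}

#' Classify a clone's RNAPC allele category
#'
#' A clone carrying a coding mutation at one of the configured anRNAPC
#' sites is assigned that site's category (anRNAPC categories take
#' precedence over `other_RNAPC`); a clone with any other mutation in an
#' RNAPC gene is `other_RNAPC`; otherwise `none`. A clone carrying
#' mutations at two configured sites is reported under the
#' lexicographically first site label, with a message.
#'
#' @param clone A [CloneGenotype-class].
#' @param cfg An [anRnapcConfig()].
#' @return Character scalar: one of [rnapcCategories()].
#' @export
classifyRnapc <- function(clone, cfg = anRnapcConfig()) {
  hits <- .anrnapcHits(clone, cfg)
  if (nrow(hits)) {
    cfgLabels <- .siteLabel(cfg$sites$gene, cfg$sites$aaPosition)
    cfgKeys <- paste(tolower(cfg$sites$gene), cfg$sites$aaPosition)
    hitKeys <- unique(paste(tolower(hits$gene), hits$aaPosition))
    matched <- sort(cfgLabels[cfgKeys %in% hitKeys])
    if (length(matched) > 1L)
      message("clone '", clone@cloneId, "' carries mutations at ",
              length(matched), " anRNAPC sites; reporting '", matched[1L], "'")
    return(matched[1L])
  }
  m <- clone@mutations
  if (any(tolower(m$gene) %in% tolower(cfg$rnapcGenes), na.rm = TRUE))
    "other_RNAPC"
  else "none"
}

#' Classify the recovery outcome of a descendant relative to its founder
#'
#' For serial-dilution experiments founded by a single clone: if the
#' founder carried no anRNAPC mutation the outcome is `not_applicable`.
#' Otherwise the outcome is `reversion` when the founder's anRNAPC allele
#' (same position and alternate allele, i.e. nucleotide-level identity) is
#' absent from the descendant; `compensation` when the allele is retained
#' and the descendant carries at least one additional RNAPC-gene mutation
#' absent from the founder; and `retained` otherwise. A same-codon
#' substitution restoring the ancestral amino acid but not the ancestral
#' nucleotide therefore counts as compensation, not reversion.
#'
#' @param founder,descendant [CloneGenotype-class] objects; the caller
#'   asserts the descendant derives from the founder.
#' @param cfg An [anRnapcConfig()].
#' @return One of `"reversion"`, `"compensation"`, `"retained"`,
#'   `"not_applicable"`.
#' @export
classifyOutcome <- function(founder, descendant, cfg = anRnapcConfig()) {
  fHits <- .anrnapcHits(founder, cfg)
  if (nrow(fHits) == 0L) return("not_applicable")
  dm <- descendant@mutations
  retainedAllele <- all(.mutKey(fHits) %in% .mutKey(dm))
  if (!retainedAllele) return("reversion")
  newMuts <- newMutationsVsAncestor(descendant, founder)
  rnapcNew <- any(tolower(newMuts$gene) %in% tolower(cfg$rnapcGenes),
                  na.rm = TRUE)
  if (rnapcNew) "compensation" else "retained"
}

#' Per-cycle RNAPC category frequencies
#'
#' Tabulates, for each dilution cycle represented among the clones, the
#' percentage of sequenced clones in each RNAPC category.
#'
#' @param clones List of [CloneGenotype-class] objects.
#' @param cfg An [anRnapcConfig()].
#' @return data.frame with columns `cycle`, `category`, `n`, `percent`;
#'   within each cycle the percentages sum to 100.
#' @export
frequencyTable <- function(clones, cfg = anRnapcConfig()) {
  if (!length(clones)) stop("no clones supplied")
  cats <- vapply(clones, classifyRnapc, character(1), cfg = cfg)
  cyc <- vapply(clones, function(cl) cl@cycle, numeric(1))
  levs <- rnapcCategories(cfg)
  out <- do.call(rbind, lapply(sort(unique(cyc)), function(k) {
    sel <- cats[cyc == k]
    tab <- table(factor(sel, levels = levs))
    data.frame(cycle = k, category = levs, n = as.integer(tab),
               percent = 100 * as.integer(tab) / length(sel),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of mutator clones per cycle
#'
#' @param clones List of [CloneGenotype-class] objects.
#' @return data.frame with columns `cycle`, `n`, `fractionMutator`.
#' @export
mutatorSummary <- function(clones) {
  if (!length(clones))
    return(data.frame(cycle = numeric(0), n = integer(0),
                      fractionMutator = numeric(0)))
  cyc <- vapply(clones, function(cl) cl@cycle, numeric(1))
  mut <- vapply(clones, function(cl) cl@mutator, logical(1))
  out <- do.call(rbind, lapply(sort(unique(cyc)), function(k) {
    sel <- mut[cyc == k]
    data.frame(cycle = k, n = length(sel), fractionMutator = mean(sel))
  }))
  rownames(out) <- NULL
  out
}
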