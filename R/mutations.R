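## Clone mutation catalogue: constructors, "new mutation" set logic, and
## table IO (package TSV dialect and Breseq GenomeDiff).

#' Build a mutation data.frame
#'
#' Convenience constructor for the mutation-table layout used throughout
#' the package. All arguments are recycled to a common length.
#'
#' @param position 1-based genomic coordinate on the reference.
#' @param ref,alt Reference and alternate alleles (free text; structural
#'   events may use descriptive strings).
#' @param gene Gene name, or an intergenic label.
#' @param aaPosition 1-based amino-acid residue number (counted from the
#'   initiator methionine); `NA` for non-coding events.
#' @param mclass Mutation class, one of [mutationClasses()].
#' @return data.frame with columns `position`, `ref`, `alt`, `gene`,
#'   `aaPosition`, `mclass`.
#' @export
#' @examples
#' mutationRecord(1272000, "C", "T", "rpoB", 1272, "nonsynonymous")
mutationRecord <- function(position, ref, alt, gene = NA_character_,
                           aaPosition = NA_integer_,
                           mclass = "nonsynonymous") {
  df <- data.frame(position = as.integer(position), ref = as.character(ref),
                   alt = as.character(alt), gene = as.character(gene),
                   aaPosition = as.integer(aaPosition),
                   mclass = as.character(mclass),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$mclass), mutationClasses())
  if (length(bad))
    stop("unknown mutation class(es): ", paste(bad, collapse = ", "))
  df
}

emptyMutationTable <- function() {
  mutationRecord(integer(0), character(0), character(0), character(0),
                 integer(0), character(0))
}

#' @rdname CloneGenotype-class
#' @param cloneId,population,day,cycle,mutations,mutator,reference See slots.
#' @export
CloneGenotype <- function(cloneId, population = "1", day = 127, cycle = 0,
                          mutations = emptyMutationTable(), mutator = FALSE,
                          reference = "NC_000913") {
  if (nrow(mutations) == 0L) mutations <- emptyMutationTable()
  new("CloneGenotype", cloneId = as.character(cloneId),
      population = as.character(population), day = as.numeric(day),
      cycle = as.numeric(cycle),
      mutations = mutations[, names(emptyMutationTable()), drop = FALSE],
      mutator = as.logical(mutator), reference = as.character(reference))
}

#' @rdname PopulationHistory-class
#' @param population Population identifier.
#' @param clones Optional list of [CloneGenotype-class] whose mutation
#'   sets seed the history (their union, deduplicated by key).
#' @export
PopulationHistory <- function(population, clones = list()) {
  muts <- emptyMutationTable()
  for (cl in clones) {
    if (!identical(cl@population, as.character(population)))
      stop("clone '", cl@cloneId, "' belongs to population '",
           cl@population, "', not '", population, "'")
    muts <- rbind(muts, cl@mutations)
  }
  muts <- muts[!duplicated(muts[, c("position", "alt")]), , drop = FALSE]
  new("PopulationHistory", population = as.character(population),
      observedMutations = muts)
}

.mutKey <- function(m) paste(m$position, m$alt, sep = ":")

#' New mutations relative to the founding ancestor
#'
#' The set difference of the descendant's mutations over the ancestor's,
#' keyed by (position, alt). An ancestral mutation missing from the
#' descendant is not reported here; allele loss is what
#' [classifyOutcome()] reads as reversion.
#'
#' @param descendant,ancestor [CloneGenotype-class] objects called against
#'   the same reference.
#' @return Mutation data.frame of the descendant's private mutations.
#' @export
newMutationsVsAncestor <- function(descendant, ancestor) {
  if (!identical(descendant@reference, ancestor@reference))
    stop("clones are called against different references ('",
         descendant@reference, "' vs '", ancestor@reference, "')")
  d <- descendant@mutations
  d[!(.mutKey(d) %in% .mutKey(ancestor@mutations)), , drop = FALSE]
}

#' New mutations relative to a population's sequencing history
#'
#' Mutations of the clone never seen in any sequenced clone of its source
#' population, i.e. the set difference over the history's observed union.
#'
#' @param clone A [CloneGenotype-class].
#' @param history A [PopulationHistory-class] for the same population.
#' @return Mutation data.frame.
#' @export
newMutationsVsHistory <- function(clone, history) {
  if (!identical(clone@population, history@population))
    stop("clone population '", clone@population,
         "' does not match history population '", history@population, "'")
  m <- clone@mutations
  m[!(.mutKey(m) %in% .mutKey(history@observedMutations)), , drop = FALSE]
}

#' Count mutations per class
#'
#' @param muts Mutation data.frame (e.g. from [mutations()] or the
#'   new-mutation operations).
#' @return Named integer vector over all of [mutationClasses()]; the
#'   counts always sum to `nrow(muts)`.
#' @export
classCounts <- function(muts) {
  tab <- table(factor(muts$mclass, levels = mutationClasses()))
  out <- as.integer(tab)
  names(out) <- mutationClasses()
  out
}

#' Flag a clone as mutator from its mutated genes
#'
#' Marks a clone as a mutator when it carries any mutation within a
#' configurable list of mismatch-repair genes. Curated metadata (the
#' `mutator` slot set at construction) is authoritative; this helper
#' supports building that metadata from annotation alone.
#'
#' @param clone A [CloneGenotype-class].
#' @param mmrGenes Character vector of mismatch-repair gene names.
#' @return Logical scalar.
#' @export
hasMutatorMutation <- function(clone,
                               mmrGenes = c("mutS", "mutL", "mutH", "uvrD")) {
  any(tolower(clone@mutations$gene) %in% tolower(mmrGenes))
}

.tsvCols <- c("clone_id", "population", "day", "cycle", "position", "ref",
              "alt", "gene", "aa_position", "mclass", "mutator")

#' Read a clone mutation table
#'
#' Two dialects are supported. `"tsv"` is the package's tab-separated
#' layout (columns `clone_id`, `population`, `day`, `cycle`, `position`,
#' `ref`, `alt`, `gene`, `aa_position`, `mclass`, `mutator`; header
#' required; one row per mutation). `"genomediff"` reads the mutation
#' lines (SNP, SUB, INS, DEL, MOB, AMP, JC) of a Breseq GenomeDiff file as
#' one clone. Unknown mutation-class annotations fall back to
#' `"noncoding"` with a warning.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"genomediff"`.
#' @return List of [CloneGenotype-class] objects (one per distinct
#'   `clone_id` for the TSV dialect; a single element for GenomeDiff).
#' @export
readMutationTable <- function(path, dialect = c("tsv", "genomediff")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") .readMutationTsv(path) else .readGenomeDiff(path)
}

.coerceClass <- function(x, where) {
  bad <- !(x %in% mutationClasses()) & !is.na(x)
  if (any(bad)) {
    warning("unknown mutation class(es) ", paste(unique(x[bad]), collapse = ", "),
            " in ", where, "; recorded as 'noncoding'")
    x[bad] <- "noncoding"
  }
  x[is.na(x)] <- "noncoding"
  x
}

.readMutationTsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = c(clone_id = "character",
                                     population = "character",
                                     ref = "character", alt = "character",
                                     gene = "character",
                                     mclass = "character")),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  missing <- setdiff(.tsvCols, names(df))
  if (length(missing))
    stop("mutation table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("mutation table '", path, "' has no rows")
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos))
    stop("non-integer position at line ",
         which(is.na(pos))[1L] + 1L, " of '", path, "'")
  df$mclass <- .coerceClass(as.character(df$mclass), path)
  byClone <- split(df, factor(df$clone_id, levels = unique(df$clone_id)))
  lapply(byClone, function(g) {
    CloneGenotype(cloneId = g$clone_id[1L], population = g$population[1L],
                  day = g$day[1L], cycle = g$cycle[1L],
                  mutations = mutationRecord(g$position, g$ref, g$alt,
                                             g$gene, g$aa_position, g$mclass),
                  mutator = as.logical(g$mutator[1L]))
  })
}

## Breseq GenomeDiff: whitespace/tab-separated mutation lines of the form
##   TYPE  id  parent_ids  seq_id  position  <type fields>  [key=value ...]
## Only evidence-free mutation records are consumed; evidence lines (RA,
## MC, JC evidence ids, UN) are ignored.
.readGenomeDiff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#=GENOME_DIFF", lines[1L]))
    stop("'", path, "' does not start with a #=GENOME_DIFF header")
  title <- sub("^#=TITLE\\s+", "",
               grep("^#=TITLE\\s", lines, value = TRUE)[1L])
  if (is.na(title)) title <- tools::file_path_sans_ext(basename(path))
  mutTypes <- c("SNP", "SUB", "INS", "DEL", "MOB", "AMP", "JC", "CON", "INV")
  recs <- emptyMutationTable()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "\t")[[1L]]
    if (length(f) == 1L) f <- strsplit(trimws(ln), "\\s+")[[1L]]
    type <- f[1L]
    if (!(type %in% mutTypes)) next
    if (length(f) < 5L)
      stop("malformed GenomeDiff record at line ", i, " of '", path, "'")
    pos <- suppressWarnings(as.integer(f[5L]))
    if (is.na(pos))
      stop("malformed position at line ", i, " of '", path, "'")
    kv <- f[grepl("=", f, fixed = TRUE)]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    getkv <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    gene <- getkv("gene_name")
    aa <- suppressWarnings(as.integer(getkv("aa_position")))
    mclass <- switch(type,
      SNP = , SUB = {
        st <- getkv("snp_type")
        if (!is.na(st) && st %in% c("nonsynonymous", "synonymous",
                                    "nonsense", "intergenic", "noncoding"))
          st
        else .coerceClass(st, paste0(path, " line ", i))
      },
      INS = "frameshift",
      DEL = {
        size <- suppressWarnings(as.integer(f[6L]))
        if (!is.na(size) && size >= 50L) "large_deletion" else "frameshift"
      },
      AMP = "large_deletion",
      MOB = , JC = , CON = , INV = "new_junction")
    alt <- switch(type,
      SNP = , SUB = f[6L],
      INS = paste0("+", f[6L]),
      DEL = paste0("del", f[6L]),
      paste0(tolower(type), "@", pos))
    recs <- rbind(recs, mutationRecord(pos, NA_character_, alt, gene, aa,
                                       mclass))
  }
  if (nrow(recs) == 0L)
    stop("no mutation records found in '", path, "'")
  list(CloneGenotype(cloneId = title, mutations = recs,
                     mutator = FALSE))
}

#' Write clone genotypes to the package's TSV dialect
#'
#' @param clones List of [CloneGenotype-class] objects.
#' @param path Output path.
#' @return Invisibly, the path. Reading the file back with
#'   [readMutationTable()] reproduces the mutation sets exactly.
#' @export
writeMutationTable <- function(clones, path) {
  rows <- lapply(clones, function(cl) {
    m <- cl@mutations
    if (nrow(m) == 0L) return(NULL)
    data.frame(clone_id = cl@cloneId, population = cl@population,
               day = cl@day, cycle = cl@cycle, position = m$position,
               ref = m$ref, alt = m$alt, gene = m$gene,
               aa_position = m$aaPosition, mclass = m$mclass,
               mutator = cl@mutator, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no mutations to write")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
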