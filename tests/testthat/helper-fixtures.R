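## Shared fixture builders; everything is generated in code.

expCurve <- function(id = "w", rate = 0.02, od0 = 0.01,
                     times = seq(0, 200, 10)) {
  ODCurve(id, times, od0 * exp(rate * times))
}

## A minimal clone with mutations given as "gene:aa:pos:alt:class" strings.
makeClone <- function(id, muts = character(0), population = "2",
                      cycle = 0, mutator = FALSE) {
  tab <- emptyTab <- mutationRecord(integer(0), character(0), character(0),
                                    character(0), integer(0), character(0))
  for (m in muts) {
    f <- strsplit(m, ":", fixed = TRUE)[[1]]
    tab <- rbind(tab, mutationRecord(as.integer(f[3]), "A", f[4],
                                     gene = if (nzchar(f[1])) f[1] else NA,
                                     aaPosition = if (!f[2] %in% c("", "NA"))
                                       as.integer(f[2]) else NA,
                                     mclass = f[5]))
  }
  CloneGenotype(id, population = population, cycle = cycle,
                mutations = tab, mutator = mutator)
}

## Independent brute-force oracle: exhaustive scan of every 5-point (or
## `window`-point) regression via lm(), no window skipping logic shared
## with the implementation.
bruteForceBestWindow <- function(times, od, window = 5, r2Min = 0.99,
                                 odFloor = 0.01) {
  best <- NULL
  for (i in seq_len(length(od) - window + 1)) {
    idx <- i:(i + window - 1)
    if (any(od[idx] <= odFloor)) next
    fit <- lm(log(od[idx]) ~ times[idx])
    r2 <- summary(fit)$r.squared
    slope <- unname(coef(fit)[2])
    if (is.finite(r2) && r2 > r2Min &&
        (is.null(best) || slope > best$slope))
      best <- list(slope = slope, start = i, r2 = r2)
  }
  best
}

## Write a small plate CSV from a list of ODCurve sharing a time base.
writePlate <- function(curves, path) {
  df <- data.frame(time_min = curves[[1]]@times)
  for (cv in curves) df[[sampleId(cv)]] <- cv@od
  write.csv(df, path, row.names = FALSE)
  path
}

usageSites <- function() siteCountsFromCodonUsage(ecoliCodonUsage())
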