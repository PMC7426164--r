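noMutationCfg <- function(...) {
  simulationConfig(muReversion = 0, muCompensation = 0, ...)
}

test_that("deterministic growth multiplies abundances by relative doublings", {
  cfg <- noMutationCfg()
  specs <- genotypeSpecs("wt", 1.0)
  st <- PopulationState(c(wt = 1e4))
  grown <- growCycle(st, specs, cfg)
  expect_equal(unname(genotypeCounts(grown)), 1e4 * 100)  # 2^log2(100)
  # two genotypes: per-cycle log2 abundance gap grows by g * dr / max rate
  specs2 <- genotypeSpecs(c("wt", "an"), c(1.0, 0.8))
  st2 <- PopulationState(c(wt = 1e4, an = 1e4))
  g2 <- growCycle(st2, specs2, cfg)
  gap <- diff(log2(genotypeCounts(g2)[c("an", "wt")]))
  expect_equal(unname(gap), log2(100) * 0.2, tolerance = 1e-12)
  # equal rates leave frequencies unchanged
  specs3 <- genotypeSpecs(c("a", "b", "c"), c(0.9, 0.9, 0.9))
  st3 <- PopulationState(c(a = 100, b = 500, c = 900))
  g3 <- growCycle(st3, specs3, cfg)
  expect_equal(genotypeFrequencies(g3), genotypeFrequencies(st3))
  expect_error(growCycle(PopulationState(c(a = 0)), specs3, cfg), "empty")
})

test_that("dilution is a multinomial bottleneck with exact total", {
  cfg <- noMutationCfg(bottleneckN = 1000)
  set.seed(1)
  one <- diluteState(PopulationState(c(only = 5e7)), cfg)
  expect_equal(unname(genotypeCounts(one)), 1000)
  expect_equal(dilutionCycle(one), 1L)
  zero <- diluteState(PopulationState(c(a = 5e7, b = 0)), cfg)
  expect_equal(unname(genotypeCounts(zero)["b"]), 0)
  # binomial moments over replicates at 50/50
  set.seed(2)
  freqs <- replicate(1e4, {
    st <- diluteState(PopulationState(c(a = 1e6, b = 1e6)), cfg)
    genotypeFrequencies(st)[["a"]]
  })
  expect_lt(abs(mean(freqs) - 0.5), 3 * sd(freqs) / sqrt(1e4))
  v <- var(freqs)
  expect_lt(abs(v - 0.25 / 1000), 3 * sqrt(2 / (1e4 - 1)) * v)
})

test_that("mutation moves cells between genotypes at the configured rates", {
  specs <- genotypeSpecs(c("wt", "an"), c(1.0, 0.8),
                         carriesAnrnapc = c(FALSE, TRUE))
  st <- PopulationState(c(wt = 1e6, an = 1e6))
  off <- mutateState(st, specs, noMutationCfg())
  expect_equal(genotypeCounts(off$state), genotypeCounts(st))
  expect_equal(sum(off$events), 0)
  expect_equal(nrow(off$specs), 2)

  # full cost recovery: the compensated genotype grows at the wild-type rate
  cfg <- simulationConfig(muReversion = 0, muCompensation = 1e-4,
                          compensationRateRecovery = 1)
  set.seed(3)
  on <- mutateState(st, specs, cfg)
  expect_gt(on$events[["compensation"]], 0)
  expect_equal(on$specs$relativeRate[on$specs$genotypeId == "an_comp"], 1.0)
  expect_true(on$specs$carriesAnrnapc[on$specs$genotypeId == "an_comp"])
  # partial recovery halves the cost
  cfgHalf <- simulationConfig(muReversion = 0, muCompensation = 1e-4,
                              compensationRateRecovery = 0.5)
  set.seed(3)
  half <- mutateState(st, specs, cfgHalf)
  expect_equal(half$specs$relativeRate[half$specs$genotypeId == "an_comp"],
               0.9)
  # a revertant sheds the allele and regains rate 1
  cfgRev <- simulationConfig(muReversion = 1e-4, muCompensation = 0)
  set.seed(4)
  rv <- mutateState(st, specs, cfgRev)
  expect_gt(rv$events[["reversion"]], 0)
  expect_equal(rv$specs$relativeRate[rv$specs$genotypeId == "an_rev"], 1.0)
  expect_false(rv$specs$carriesAnrnapc[rv$specs$genotypeId == "an_rev"])
  # conservation of cells
  expect_equal(sum(genotypeCounts(rv$state)), sum(genotypeCounts(st)))
})

test_that("mutator genotypes accumulate events at mutatorFactor times the rate", {
  mu <- 2e-7
  cfg <- simulationConfig(muReversion = mu, muCompensation = 0,
                          mutatorFactor = 100)
  specsNon <- genotypeSpecs("an", 0.8, mutator = FALSE, carriesAnrnapc = TRUE)
  specsMut <- genotypeSpecs("an", 0.8, mutator = TRUE, carriesAnrnapc = TRUE)
  st <- PopulationState(c(an = 1e6))
  set.seed(6)
  evNon <- sum(replicate(200, mutateState(st, specsNon, cfg)$events[["reversion"]]))
  evMut <- sum(replicate(200, mutateState(st, specsMut, cfg)$events[["reversion"]]))
  lamNon <- 1e6 * cfg$generationsPerCycle * mu * 200
  lamMut <- lamNon * 100
  # Poisson totals within 4 sd of their expectations, scaling ~x100
  expect_lt(abs(evNon - lamNon), 4 * sqrt(lamNon))
  expect_lt(abs(evMut - lamMut), 4 * sqrt(lamMut))
})

test_that("experiments are seed-reproducible and neutral for a lone wild type", {
  specs <- genotypeSpecs(c("a", "b"), c(1.0, 0.9),
                         carriesAnrnapc = c(FALSE, TRUE))
  init <- PopulationState(c(a = 500, b = 500))
  cfg <- simulationConfig(bottleneckN = 1000, cycles = 5,
                          muReversion = 1e-6, muCompensation = 1e-6,
                          seed = 77L)
  r1 <- runExperiment(init, specs, cfg)
  r2 <- runExperiment(init, specs, cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$events, r2$events)

  solo <- runExperiment(PopulationState(c(wt = 1000)),
                        genotypeSpecs("wt", 1.0),
                        noMutationCfg(bottleneckN = 1000, cycles = 6,
                                      seed = 5L))
  expect_equal(solo$meanRelativeRate$meanRelativeRate, rep(1, 7))
  expect_equal(max(abs(solo$trajectory$frequency - 1)), 0)
})

test_that("equal-rate genotypes drift as a martingale across replicates", {
  specs <- genotypeSpecs(c("a", "b"), c(1.0, 1.0))
  cfg <- noMutationCfg(bottleneckN = 200, cycles = 4)
  set.seed(123)
  finals <- replicate(1e4, {
    res <- runExperiment(PopulationState(c(a = 60, b = 140)), specs, cfg)
    last <- res$states[[length(res$states)]]
    genotypeFrequencies(last)[["a"]]
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.3), 3 * se)
})

test_that("clone samples reflect genotype frequencies and configured loads", {
  specs <- genotypeSpecs(c("an", "wt"), c(0.8, 1.0),
                         mutator = c(TRUE, FALSE),
                         carriesAnrnapc = c(TRUE, FALSE),
                         baseMutationLoad = c(0, 0))
  fixed <- PopulationState(c(an = 1000, wt = 0), cycle = 2L)
  set.seed(9)
  clones <- emitCloneSample(fixed, specs, 10)
  expect_length(clones, 10)
  cats <- vapply(clones, classifyRnapc, character(1))
  expect_true(all(cats == "anRNAPC_rpoB1272"))  # fixed population: all carry it
  expect_true(all(vapply(clones, isMutator, logical(1))))
  expect_true(all(vapply(clones, dilutionCycle, numeric(1)) == 2))
  # load 0: founder-defining mutations only (3 core + mutS + anRNAPC)
  expect_true(all(vapply(clones, function(cl)
    nrow(mutations(cl)), numeric(1)) == 5))
  # passenger NS:S classes follow the supplied site fractions
  sc <- usageSites()
  pNs <- nsSites(sc) / (nsSites(sc) + synSites(sc))
  specsLoad <- genotypeSpecs("wt", 1.0, baseMutationLoad = 500)
  set.seed(10)
  big <- emitCloneSample(PopulationState(c(wt = 100)), specsLoad, 20, sc)
  cls <- unlist(lapply(big, function(cl) {
    m <- mutations(cl)
    m$mclass[grepl("^pgene", m$gene)]
  }))
  n <- length(cls)
  expect_gt(n, 8000)
  pHat <- mean(cls == "nonsynonymous")
  expect_lt(abs(pHat - pNs), 3 * sqrt(pNs * (1 - pNs) / n))
})

test_that("emitted OD curves round-trip through the growth-rate fitter", {
  specs <- genotypeSpecs(c("wt", "an"), c(1.0, 0.8))
  # no noise, no lag, unbounded growth: exact recovery
  pure <- emitOdCurves(specs, wildtypeRate = 0.025, capacity = Inf,
                       noiseSd = 0, durationMin = 300)
  expect_equal(growthRate(fitExponentialRate(pure$wt)), 0.025,
               tolerance = 1e-6)
  expect_equal(growthRate(fitExponentialRate(pure$an)), 0.02,
               tolerance = 1e-6)
  # noisy logistic curves: relative rate within 2% of configured
  set.seed(21)
  noisy <- emitOdCurves(specs, wildtypeRate = 0.025, capacity = 1,
                        noiseSd = 0.002, lagMin = 30)
  rel <- relativeGrowthRate(fitExponentialRate(noisy$an),
                            fitExponentialRate(noisy$wt))
  expect_lt(abs(rel - 80), 2)
  # zero rate, zero noise: flat curve never qualifies
  flatSpec <- genotypeSpecs("dead", 1e-9)
  flat <- emitOdCurves(flatSpec, wildtypeRate = 0, noiseSd = 0, od0 = 0.5)
  expect_false(isQualified(fitExponentialRate(flat$dead)))
})

test_that("compensation outnumbers reversion about k-to-1 with k targets", {
  # one reversion target vs k equal-rate compensatory targets at equal
  # per-site rates and full cost recovery
  k <- 5
  mu <- 4e-8
  cfg <- simulationConfig(bottleneckN = 1e5, cycles = 8,
                          muReversion = mu, muCompensation = k * mu,
                          compensationRateRecovery = 1)
  specs <- genotypeSpecs("an", 0.8, carriesAnrnapc = TRUE)
  set.seed(31)
  ev <- c(reversion = 0, compensation = 0)
  for (i in 1:60) {
    res <- runExperiment(PopulationState(c(an = 1e5)), specs, cfg)
    ev <- ev + res$events
  }
  total <- sum(ev)
  expect_gt(total, 100)
  pHat <- ev[["compensation"]] / total
  pExp <- k / (k + 1)
  expect_lt(abs(pHat - pExp), 3 * sqrt(pExp * (1 - pExp) / total))
})
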