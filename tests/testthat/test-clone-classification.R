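test_that("RNAPC categories follow site membership with anRNAPC precedence", {
  cfg <- anRnapcConfig()
  expect_equal(classifyRnapc(makeClone("a", "rpoC:428:10:T:nonsynonymous")),
               "anRNAPC_rpoC428")
  expect_equal(classifyRnapc(makeClone("b", "rpoC:1075:11:T:nonsynonymous")),
               "other_RNAPC")
  expect_equal(classifyRnapc(makeClone("c", "acnB:55:12:T:nonsynonymous")),
               "none")
  expect_equal(classifyRnapc(CloneGenotype("d")), "none")
  # precedence: adding an other-RNAPC mutation never demotes an anRNAPC clone
  both <- makeClone("e", c("rpoB:1272:20:T:nonsynonymous",
                           "rpoB:546:21:C:nonsynonymous"))
  expect_equal(classifyRnapc(both), "anRNAPC_rpoB1272")
  # configurable sites
  custom <- anRnapcConfig(sites = data.frame(gene = "rpoA",
                                             aaPosition = 10L))
  expect_equal(classifyRnapc(makeClone("f", "rpoA:10:30:T:nonsynonymous"),
                             custom), "anRNAPC_rpoA10")
})

test_that("a clone at two configured sites reports the first site with a message", {
  two <- makeClone("g", c("rpoC:334:40:T:nonsynonymous",
                          "rpoC:428:41:T:nonsynonymous"))
  expect_message(cat1 <- classifyRnapc(two), "2 anRNAPC sites")
  expect_equal(cat1, "anRNAPC_rpoC334")
})

test_that("recovery outcomes distinguish reversion, compensation and retention", {
  founder <- makeClone("2_1", c("rpoB:1272:4185000:T:nonsynonymous",
                                sprintf("g%d:10:%d:T:nonsynonymous", 1:7,
                                        1:7 * 1000)))
  # allele retained + new RNAPC mutation elsewhere -> compensation
  comp <- makeClone("2_1_d1", c("rpoB:1272:4185000:T:nonsynonymous",
                                "rpoB:546:4182000:C:nonsynonymous",
                                sprintf("g%d:10:%d:T:nonsynonymous", 1:7,
                                        1:7 * 1000)))
  expect_equal(classifyOutcome(founder, comp), "compensation")
  # allele absent -> reversion
  revd <- makeClone("2_1_d2", sprintf("g%d:10:%d:T:nonsynonymous", 1:7,
                                      1:7 * 1000))
  expect_equal(classifyOutcome(founder, revd), "reversion")
  # allele retained, no new RNAPC mutation -> retained
  ret <- makeClone("2_1_d3", c("rpoB:1272:4185000:T:nonsynonymous",
                               sprintf("g%d:10:%d:T:nonsynonymous", 1:8,
                                       1:8 * 1000)))
  expect_equal(classifyOutcome(founder, ret), "retained")
  # founder without anRNAPC -> not applicable whatever the descendant
  noAn <- makeClone("2_6", sprintf("g%d:10:%d:T:nonsynonymous", 1:4,
                                   1:4 * 1000))
  expect_equal(classifyOutcome(noAn, revd), "not_applicable")
  # a second substitution in the same codon (ancestral allele retained at
  # the nucleotide level) is compensation, not reversion
  sameCodon <- makeClone("2_1_d4", c("rpoB:1272:4185000:T:nonsynonymous",
                                     "rpoB:1272:4185001:G:nonsynonymous",
                                     sprintf("g%d:10:%d:T:nonsynonymous",
                                             1:7, 1:7 * 1000)))
  expect_equal(classifyOutcome(founder, sameCodon), "compensation")
  # whereas replacement of the founder allele by a different alternate
  # allele at the same position reads as loss of the allele
  replaced <- makeClone("2_1_d5", c("rpoB:1272:4185000:G:nonsynonymous",
                                    sprintf("g%d:10:%d:T:nonsynonymous",
                                            1:7, 1:7 * 1000)))
  expect_equal(classifyOutcome(founder, replaced), "reversion")
})

test_that("a clone is retained or not-applicable against itself", {
  clones <- list(makeClone("x", "rpoB:1272:100:T:nonsynonymous"),
                 makeClone("y", "rpoC:1075:200:T:nonsynonymous"),
                 CloneGenotype("z"))
  for (cl in clones)
    expect_true(classifyOutcome(cl, cl) %in% c("retained", "not_applicable"))
})

test_that("frequency tables give per-cycle percentages that sum to 100", {
  day127 <- c(lapply(1:5, function(i)
                makeClone(paste0("a", i), "rpoB:1272:100:T:nonsynonymous")),
              lapply(1:3, function(i)
                makeClone(paste0("b", i), "rpoC:334:200:T:nonsynonymous")),
              list(makeClone("c1", "rpoC:428:300:T:nonsynonymous"),
                   makeClone("d1", sprintf("g:1:400%d:T:nonsynonymous", 1)),
                   makeClone("d2", sprintf("g:1:500%d:T:nonsynonymous", 1))))
  ft <- frequencyTable(day127)
  expect_equal(sum(ft$percent), 100)
  an <- ft[grepl("^anRNAPC", ft$category), ]
  expect_equal(sum(an$percent), 100 * 9 / 11, tolerance = 1e-9)
  expect_equal(ft$percent[ft$category == "none"], 100 * 2 / 11,
               tolerance = 1e-9)

  allNone <- lapply(1:4, function(i) CloneGenotype(paste0("n", i)))
  ftn <- frequencyTable(allNone)
  expect_equal(ftn$percent[ftn$category == "none"], 100)
  expect_equal(sum(ftn$percent), 100)

  four <- list(makeClone("p", "rpoB:1272:1:T:nonsynonymous"),
               makeClone("q", "rpoB:546:2:T:nonsynonymous"),
               CloneGenotype("r"), CloneGenotype("s"))
  ft4 <- frequencyTable(four)
  expect_equal(ft4$percent[ft4$category == "anRNAPC_rpoB1272"], 25)
  expect_equal(ft4$percent[ft4$category == "other_RNAPC"], 25)
  expect_equal(ft4$percent[ft4$category == "none"], 50)
  # property: per-cycle sums are always 100 on random mixtures
  set.seed(5)
  pool <- c(day127, allNone, four)
  mixed <- lapply(seq_along(pool), function(i) {
    cl <- pool[[i]]
    initialize(cl, cycle = as.numeric(sample(0:3, 1)))
  })
  ftm <- frequencyTable(mixed)
  sums <- tapply(ftm$percent, ftm$cycle, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("mutator fractions are tabulated per cycle", {
  clones <- c(lapply(1:3, function(i)
                makeClone(paste0("m", i), mutator = TRUE)),
              lapply(4:10, function(i)
                makeClone(paste0("m", i), mutator = FALSE)))
  ms <- mutatorSummary(clones)
  expect_equal(ms$fractionMutator, 0.3)
  expect_equal(ms$n, 10L)
  allMut <- lapply(1:5, function(i) makeClone(paste0("x", i), mutator = TRUE))
  expect_equal(mutatorSummary(allMut)$fractionMutator, 1)
  expect_equal(nrow(mutatorSummary(list())), 0)
})
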