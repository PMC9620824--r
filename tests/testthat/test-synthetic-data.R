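test_that("generation is deterministic under a fixed seed", {
  sp <- small_spec(seed = 71L, n = 40L)
  g1 <- generateProteome(sp)
  g2 <- generateProteome(sp)
  expect_identical(as.character(g1$proteome), as.character(g2$proteome))
  expect_identical(as.data.frame(truthRegions(g1$truth)),
                   as.data.frame(truthRegions(g2$truth)))
  a1 <- generateAnnotations(sp, g1$truth)
  a2 <- generateAnnotations(sp, g2$truth)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  # FASTA bytes identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeProteome(g1$proteome, f1); writeProteome(g2$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted regions are recovered with precision = recall = 1", {
  for (seed in c(73L, 79L, 83L)) {
    sp <- small_spec(seed = seed)
    g <- generateProteome(sp)
    truth <- truthRegions(g$truth)
    dp <- detectPure(g$proteome)
    di <- detectImpure(g$proteome)
    tp <- as.data.frame(truth[purity(truth) == "pure"])
    ti <- as.data.frame(truth[purity(truth) == "impure"])
    dpd <- as.data.frame(dp)
    did <- as.data.frame(di)
    ord <- function(d) {
      d <- d[order(d$protein_id, d$start), ]
      rownames(d) <- NULL
      d
    }
    expect_identical(ord(dpd), ord(tp))
    expect_identical(ord(did), ord(ti))
  }
})

test_that("background composition matches the spec within sampling error", {
  bg <- stats::setNames(rep((1 - 0.08) / 19, 20),
                        polyAcontext:::.AA20)
  bg["A"] <- 0.08
  sp <- syntheticSpec(
    nProteins = 300L, lengthRange = c(330L, 340L), background = bg,
    planPure = data.frame(length = integer(), count = integer()),
    planImpure = data.frame(length = integer(), nImpurities = integer(),
                            count = integer()),
    seed = 89L)
  g <- generateProteome(sp)
  bc <- backgroundComposition(g$proteome)
  n <- totalResidues(bc)
  expect_gt(n, 99000)
  se <- sqrt(0.08 * 0.92 / n)
  expect_lt(abs(bgFreq(bc)["A"] - 0.08), 3 * se)
})

test_that("annotation coupling follows the class probabilities", {
  sp <- small_spec(seed = 97L)
  sp$pepProbs[["2"]] <- c(mTP = 1, SP = 0)
  g <- generateProteome(sp)
  ann <- generateAnnotations(sp, g$truth)
  df <- as.data.frame(ann)
  cls <- truthProteins(g$truth)$startClass
  expect_true(all(df$peptide[cls == "2"] == "mTP"))

  # coupling off: labels independent of class, all labels from the prior
  expect_true(all(df$location %in% c("Nucleus", "Cytoplasm",
                                     "Mitochondrion", "Secreted",
                                     "Other/Mixed")))
})

test_that("location coupling plants a position effect", {
  sp <- small_spec(seed = 101L, n = 300L)
  sp$locationRelpos <- list(Mitochondrion = c(0.05, 0.05),
                            Nucleus = c(0.5, 0.15))
  g <- generateProteome(sp)
  ann <- generateAnnotations(sp, g$truth)
  regions <- c(detectPure(g$proteome), detectImpure(g$proteome))
  samples <- relativePositions(mostNTerminalRegion(regions), g$proteome)
  out <- stratifyByLocation(samples, ann)
  s <- out$summary
  expect_lt(s$median[s$group == "Mitochondrion"],
            s$median[s$group == "Nucleus"])
  expect_lt(out$p.values["Mitochondrion", "Nucleus"], 0.01)
})

test_that("propensity fixture biases are constructed as declared", {
  u <- generatePropensityFixture(0, 0)
  expect_true(all(abs(u@probs - 1 / 27) < 1e-12))
  expect_equal(nrow(u@probs), 8000L)

  tab <- generatePropensityFixture(0.8, 0.6)
  expect_equal(unname(tab@probs["AAA", "aaa"]), 0.8 + 0.2 / 27)
  gaa <- tab@probs["GAA", ]
  expect_equal(unname(gaa["aaa"]), 0.4 / 27)
  expect_equal(sum(gaa[!names(gaa) %in% c("aaa", "bbb")]),
               0.6 + 25 * 0.4 / 27)
  expect_equal(unname(rowSums(tab@probs)), rep(1, 8000L),
               tolerance = 1e-12)
})

test_that("fixture plus planted G+1 bias raises 'others' right after the repeat", {
  # contrast design: same fixture, same region plan, flanked by G at +1
  # with probability 1 versus a structure-neutral L at +1 — the breaker
  # table rows must raise the grouped 'others' fraction at +1/+2 in the
  # G-flanked scenario relative to the L-flanked one
  tab <- generatePropensityFixture(0.8, 0.6)
  prof_for <- function(letter, seed) {
    sp <- syntheticSpec(
      nProteins = 150L,
      planPure = data.frame(length = 8L, count = 150L),
      planImpure = data.frame(length = integer(), nImpurities = integer(),
                              count = integer()),
      flankBias = data.frame(position = 1L, letter = letter, prob = 1),
      startAtTwoFraction = 0, seed = seed)
    g <- generateProteome(sp)
    as.data.frame(aggregateRegionProfiles(detectPure(g$proteome),
                                          g$proteome, tab))
  }
  pg <- prof_for("G", 103L)
  pl <- prof_for("L", 103L)
  for (pos in c("+1", "+2")) {
    expect_gt(pg$others[pg$position == pos],
              pl$others[pl$position == pos])
  }
  # and the repeat itself is helical under this table
  expect_gt(pg$aaa[pg$position == "0"], 0.5)
})

test_that("infeasible plans are rejected up front", {
  expect_error(syntheticSpec(nProteins = 10L, planPure = data.frame(
    length = 6L, count = 50L)), "exceeds nProteins")
  expect_error(syntheticSpec(lengthRange = c(30L, 40L)), "infeasible")
  expect_error(syntheticSpec(planImpure = data.frame(
    length = 12L, nImpurities = 2L, count = 1L)), "too long")
  expect_error(syntheticSpec(planImpure = data.frame(
    length = 8L, nImpurities = 3L, count = 1L)), "at most")
  expect_error(syntheticSpec(flankBias = data.frame(
    position = 1L, letter = "A", prob = 0.5)), "differ from the target")
})
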