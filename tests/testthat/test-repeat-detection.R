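test_that("pure detection finds exactly the maximal runs", {
  expect_equal(as.data.frame(detectPure(c(p = "MAAAAG")))[, c("start", "end")],
               data.frame(start = 2L, end = 5L))
  expect_equal(length(detectPure(c(p = "MAAAG"))), 0L)
  r <- detectPure(c(p = "AAAAAAA"))
  expect_equal(c(start(r), end(r), width(r)), c(1L, 7L, 7L))
  # parameterised: other targets and thresholds
  r2 <- detectPure(c(p = "MQQQQQAQ"), target = "Q", minLen = 5L)
  expect_equal(c(start(r2), end(r2)), c(2L, 6L))
  expect_error(detectPure(c(p = "MAAA"), minLen = 0L), ">= 1")
})

test_that("impure detection matches its window-union definition", {
  r <- detectImpure(c(p = "MAAAGAAM"))
  expect_equal(c(start(r), end(r)), c(2L, 7L))
  expect_equal(impurities(r)[[1]],
               data.frame(offset = 4L, residue = "G"))

  expect_equal(length(detectImpure(c(p = "MAAAAG"))), 0L)
  expect_equal(length(detectImpure(c(p = "MAAAAAAG"),
                                   requireImpurity = FALSE)), 1L)

  r3 <- detectImpure(c(p = "AAGAAGAA"))
  expect_equal(c(start(r3), end(r3)), c(1L, 8L))
  expect_equal(impurities(r3)[[1]]$offset, c(3L, 6L))

  # terminal short windows: a protein ending ...GAAAA behaves like its
  # reverse (no qualifying window of width >= 4 holds an impurity here)
  fwd <- detectImpure(c(p = "GGAAAAG"))
  rev <- detectImpure(c(p = "GAAAAGG"))
  expect_equal(length(fwd), length(rev))
})

test_that("impure detection equals brute-force enumeration on a grid", {
  set.seed(101)
  grid <- list(c(6L, 4L), c(6L, 5L), c(4L, 3L), c(8L, 5L))
  for (g in grid) {
    for (rep in 1:60) {
      s <- random_seq(sample(5:120, 1), runif(1, 0.1, 0.5))
      got <- impure_as_oracle(detectImpure(
        c(p = s), window = g[1], windowMinCount = g[2]))
      want <- oracle_impure(s, window = g[1], k = g[2])
      expect_equal(got$start, want$start,
                   info = sprintf("w=%d k=%d seq=%s", g[1], g[2], s))
      expect_equal(got$end, want$end)
      expect_equal(got$imp, want$imp)
    }
  }
})

test_that("detection is position-covariant under non-target prefixes", {
  set.seed(7)
  for (rep in 1:25) {
    s <- random_seq(sample(20:80, 1), 0.35)
    k <- sample(1:12, 1)
    shifted <- paste0(strrep("G", k), s)
    p0 <- detectPure(c(p = s)); p1 <- detectPure(c(p = shifted))
    expect_equal(start(p1), start(p0) + k)
    expect_equal(end(p1), end(p0) + k)
    i0 <- detectImpure(c(p = s)); i1 <- detectImpure(c(p = shifted))
    expect_equal(start(i1), start(i0) + k)
    expect_equal(end(i1), end(i0) + k)
  }
})

test_that("pure runs >= windowMinCount lie inside the qualifying-window union", {
  set.seed(13)
  for (rep in 1:25) {
    s <- random_seq(sample(20:100, 1), 0.4)
    p <- detectPure(c(p = s))
    t <- strsplit(s, "")[[1]] == "A"
    spans <- polyAcontext:::.impure_spans(t, 6L, 4L)
    for (j in seq_along(p)) {
      if (width(p)[j] < 4L) next
      covered <- any(BiocGenerics::start(spans) <= start(p)[j] &
                       BiocGenerics::end(spans) >= end(p)[j])
      expect_true(covered, info = s)
    }
  }
})

test_that("count table stratifies by length class with protein dedup", {
  r <- RepeatRegions(c("p1", "p1", "p2"), c(2L, 10L, 3L), c(5L, 13L, 9L),
                     rep("pure", 3))
  ct <- summarizeCounts(r)
  pure <- ct[ct$purity == "pure", ]
  expect_equal(pure$regions[pure$class == "4"], 2L)
  expect_equal(pure$proteins[pure$class == "4"], 1L)
  expect_equal(pure$regions[pure$class == ">4"], 1L)
  expect_equal(pure$regions[pure$class == "Total"], 3L)
  expect_equal(pure$proteins[pure$class == "Total"], 2L)

  empty <- summarizeCounts(RepeatRegions())
  expect_true(all(empty$regions == 0L))

  # class counts sum to totals on detector output
  sp <- small_spec(seed = 5L)
  g <- generateProteome(sp)
  regions <- c(detectPure(g$proteome), detectImpure(g$proteome))
  ct2 <- summarizeCounts(regions, g$proteome)
  for (pu in c("pure", "impure")) {
    sub <- ct2[ct2$purity == pu, ]
    expect_equal(sub$regions[sub$class == "Total"],
                 sum(sub$regions[sub$class != "Total"]))
  }
})

test_that("most N-terminal region selection and tie-breaking", {
  r <- RepeatRegions(c("p1", "p1"), c(2L, 40L), c(6L, 44L),
                     c("pure", "pure"))
  nt <- mostNTerminalRegion(r)
  expect_equal(start(nt), 2L)

  tie <- RepeatRegions(
    c("p1", "p1"), c(2L, 2L), c(5L, 9L), c("pure", "impure"),
    impurities = list(
      data.frame(offset = integer(), residue = character()),
      data.frame(offset = 5L, residue = "G")))
  nt2 <- mostNTerminalRegion(tie)
  expect_equal(purity(nt2), "impure")
  expect_equal(end(nt2), 9L)

  expect_false("p2" %in% proteinId(nt2))
})

test_that("regions TSV round-trips through write/read", {
  sp <- small_spec(seed = 21L, n = 60L)
  g <- generateProteome(sp)
  r <- c(detectPure(g$proteome), detectImpure(g$proteome))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRegions(r, f)
  back <- readRegions(f)
  expect_equal(as.data.frame(back), as.data.frame(r))
})
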