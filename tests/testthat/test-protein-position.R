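test_that("relative position modes rescale correctly", {
  pr <- c(p1 = paste(rep("G", 20), collapse = ""))
  r <- RepeatRegions("p1", 1L, 10L, "pure", target = "G")
  rp <- relativePositions(r, pr)
  expect_equal(rp$relpos, 5.5 / 20)
  rp_s <- relativePositions(r, pr, mode = "start")
  expect_equal(rp_s$relpos, 1 / 20)

  # region spanning an entire protein stays within [0, 1]
  pr2 <- c(p1 = paste(rep("A", 12), collapse = ""))
  r2 <- detectPure(pr2)
  rp2 <- relativePositions(r2, pr2)
  expect_equal(rp2$relpos, 0.5 + 1 / 24)
  expect_lte(rp2$relpos, 1)

  # length-1 regions: start and midpoint agree exactly
  r3 <- RepeatRegions("p1", 7L, 7L, "pure", target = "G")
  expect_equal(relativePositions(r3, pr)$relpos,
               relativePositions(r3, pr, mode = "start")$relpos)
})

test_that("Mann-Whitney matches hand cases and exact enumeration", {
  res <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1 / 3)
  expect_true(res$exact)

  # identical samples: U = n^2/2, far from significance
  res2 <- mannWhitneyU(1:10, 1:10)
  expect_equal(res2$statistic, 50)
  expect_gt(res2$p.value, 0.9)

  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")

  # randomized property: exact branch equals combinatorial enumeration
  set.seed(37)
  for (rep in 1:200) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    vals <- sample(1000, na + nb)   # untied
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    got <- mannWhitneyU(a, b)
    want <- oracle_mw_exact(a, b)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation agrees with wilcox.test on ties", {
  set.seed(41)
  for (rep in 1:50) {
    a <- sample(1:8, 30, replace = TRUE)
    b <- sample(2:9, 25, replace = TRUE)
    got <- mannWhitneyU(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE,
                                               exact = FALSE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("well-separated samples give vanishing p-values", {
  set.seed(43)
  a <- rnorm(200, 0); b <- rnorm(200, 3)
  expect_lt(mannWhitneyU(a, b)$p.value, 1e-6)
})

test_that("location stratification summarises and tests pairwise", {
  # planted effect: mitochondrial repeats N-terminal, nuclear internal
  set.seed(47)
  n <- 120
  ids <- sprintf("p%04d", seq_len(n))
  relpos <- c(abs(rnorm(n / 2, 0.05, 0.03)), rnorm(n / 2, 0.35, 0.1))
  samples <- data.frame(protein_id = ids, start = 2L, end = 7L,
                        relpos = pmin(pmax(relpos, 0.001), 0.999),
                        mode = "midpoint")
  ann <- methods::new("AnnotationTable", id = ids,
                      location = rep(c("Mitochondrion", "Nucleus"),
                                     each = n / 2),
                      peptide = rep(NA_character_, n))
  out <- stratifyByLocation(samples, ann)
  s <- out$summary
  expect_lt(s$median[s$group == "Mitochondrion"],
            s$median[s$group == "Nucleus"])
  expect_lt(out$p.values["Mitochondrion", "Nucleus"], 0.01)
  expect_true(all(c("Cytoplasm", "Secreted") %in% out$omitted))

  # unannotated proteins fall into Other/Mixed; single group edge case
  ann2 <- methods::new("AnnotationTable", id = ids,
                       location = rep(NA_character_, n),
                       peptide = rep(NA_character_, n))
  out2 <- stratifyByLocation(samples, ann2)
  expect_equal(out2$summary$group, "Other/Mixed")
  expect_true(all(is.na(out2$p.values)))
})

test_that("TP table reproduces the hand-counted example and identities", {
  pr <- c(p1 = strrep("G", 40), p2 = strrep("G", 40),
          p3 = strrep("G", 40), p4 = strrep("G", 40))
  r <- RepeatRegions(c("p1", "p2", "p3"), c(2L, 5L, 30L),
                     c(6L, 9L, 34L), rep("pure", 3), target = "G")
  ann <- methods::new("AnnotationTable", id = c("p1", "p2", "p3", "p4"),
                      location = rep(NA_character_, 4),
                      peptide = c("mTP", "SP", NA, NA))
  tab <- tpEnrichmentTable(pr, r, ann)
  get <- function(cl, col) tab[tab$class == cl, col]
  expect_equal(get("no polyA", "proteins"), 1L)
  expect_equal(get("any", "proteins"), 3L)
  expect_equal(get("any", "mTP"), 1L)
  expect_equal(get("any", "SP"), 1L)
  expect_equal(get("2", "proteins"), 1L)
  expect_equal(get("2", "pct_mTP"), 100)
  expect_equal(get("3-20", "SP"), 1L)
  expect_equal(get("3-20", "pct_SP"), 100)
  expect_equal(get(">20", "proteins"), 1L)
  expect_equal(get(">20", "mTP"), 0L)

  # bookkeeping identities hold on every input
  expect_equal(get("any", "proteins") + get("no polyA", "proteins"),
               length(pr))
  expect_equal(get("any", "proteins"),
               sum(tab$proteins[tab$class %in% c("1", "2", "3-20", ">20")]))

  # no regions at all
  tab0 <- tpEnrichmentTable(pr, RepeatRegions(target = "G"), ann)
  expect_equal(tab0$proteins[tab0$class == "any"], 0L)
  expect_equal(tab0$proteins[tab0$class == "no polyA"], 4L)

  # a region starting at position 1 is classed apart from "2"
  r1 <- RepeatRegions("p1", 1L, 5L, "pure", target = "G")
  tab1 <- tpEnrichmentTable(pr, r1, ann)
  expect_equal(tab1$proteins[tab1$class == "1"], 1L)
  expect_equal(tab1$proteins[tab1$class == "2"], 0L)
})
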