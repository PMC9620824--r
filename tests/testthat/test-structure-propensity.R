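cls27 <- structureClasses()

# tiny hand-built table: AAA concentrated on "aaa", GAA flat on "others"
tiny_table <- function() {
  probs <- rbind(
    AAA = ifelse(cls27 == "aaa", 0.8, 0.2 / 26),
    GAA = ifelse(!cls27 %in% c("aaa", "bbb"), 1 / 25, 0))
  colnames(probs) <- cls27
  methods::new("PropensityTable", probs = probs, provenance = "tiny")
}

test_that("propensity table TSV loads, validates and round-trips", {
  tab <- tiny_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  writePropensityTable(tab, f)
  back <- loadPropensityTable(f)
  expect_equal(back@probs, tab@probs, tolerance = 1e-12)

  # lookup of an absent tripeptide falls back to uniform
  lk <- propensityLookup(back, c("AAA", "WCW"))
  expect_equal(unname(lk["WCW", ]), rep(1 / 27, 27))
  expect_equal(attr(lk, "nMissing"), 1L)
  expect_equal(unname(lk["AAA", "aaa"]), 0.8, tolerance = 1e-12)

  # malformed tables are rejected
  df <- utils::read.delim(f, check.names = FALSE)
  g <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[, -2], g, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(loadPropensityTable(g), "columns")

  df2 <- utils::read.delim(f, check.names = FALSE)
  df2[1, 2] <- df2[1, 2] + 0.5
  h <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df2, h, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadPropensityTable(h), "sum to 1.*AAA")
})

test_that("uniform table is a fixed point of context averaging", {
  u <- generatePropensityFixture(0, 0)
  p <- predictProfile("MKLVNQWD", u)
  expect_equal(unname(p[, "aaa"]), rep(1 / 27, nrow(p)))
  expect_equal(unname(p[, "bbb"]), rep(1 / 27, nrow(p)))
  expect_equal(unname(p[, "others"]), rep(25 / 27, nrow(p)))
  expect_equal(rownames(p), as.character(2:7))
})

test_that("homopolymer interior equals the single-tripeptide vector", {
  tab <- tiny_table()
  p <- suppressWarnings(predictProfile("AAAAAAA", tab))
  mid <- p["4", ]
  expect_equal(unname(mid["aaa"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(mid["bbb"]), 0.2 / 26, tolerance = 1e-12)
  expect_equal(sum(mid), 1)
})

test_that("context averaging matches direct arithmetic at the centre", {
  tab <- tiny_table()
  # sequence GAAAAAA: tripeptides at centres 2..6 are GAA, AAA, AAA, ...
  p <- suppressWarnings(predictProfile("GAAAAAA", tab))
  w <- c(1, 2, 4, 2, 1)
  vGAA <- tab@probs["GAA", ]
  vAAA <- tab@probs["AAA", ]
  # centre residue 4: neighbours at 2(GAA),3,4,5,6 (AAA)
  want <- (w[1] * vGAA + sum(w[2:5]) * vAAA) / sum(w)
  expect_equal(unname(p["4", "aaa"]), unname(want["aaa"]), tolerance = 1e-12)
  expect_equal(unname(p["4", "others"]),
               unname(1 - want["aaa"] - want["bbb"]), tolerance = 1e-12)

  # degenerate weights reproduce the raw lookup
  p0 <- suppressWarnings(predictProfile("GAAAAAA", tab,
                                        contextWeights = c(0, 0, 1, 0, 0)))
  expect_equal(unname(p0["2", "others"]), 1, tolerance = 1e-12)
  expect_equal(unname(p0["3", "aaa"]), 0.8, tolerance = 1e-12)

  expect_error(predictProfile("MA", tab), "length >= 3")
  expect_error(predictProfile("MAAAA", tab, contextWeights = c(1, 1)),
               "weights")
})

test_that("probability is conserved at every predicted residue", {
  set.seed(53)
  tab <- generatePropensityFixture(0.8, 0.6)
  for (rep in 1:20) {
    s <- random_seq(sample(10:60, 1), 0.3,
                    letters = c("A", "G", "P", "L", "S", "V", "W", "C"))
    p <- predictProfile(s, tab)
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)))
    expect_true(all(p >= 0))
  }
})

test_that("region aggregation is linear and handles boundaries", {
  tab <- generatePropensityFixture(0.8, 0.6)
  sp <- small_spec(seed = 59L)
  g <- generateProteome(sp)
  r <- detectPure(g$proteome)
  n <- length(r)
  half <- seq_len(n %/% 2)
  a <- aggregateRegionProfiles(r[half], g$proteome, tab)
  b <- aggregateRegionProfiles(r[setdiff(seq_len(n), half)], g$proteome,
                               tab)
  whole <- aggregateRegionProfiles(r, g$proteome, tab)
  na_ <- a@n; nb_ <- b@n
  pooled <- (a@fractions * na_ + b@fractions * nb_) / pmax(na_ + nb_, 1L)
  pooled[na_ + nb_ == 0L, ] <- 0
  expect_equal(whole@fractions, pooled, tolerance = 1e-12)
  expect_equal(whole@n, na_ + nb_)

  # a region at the protein N-terminus has no negative-position residues
  pr <- c(p1 = paste0(strrep("A", 6), strrep("G", 30)))
  r1 <- detectPure(pr)
  prof <- aggregateRegionProfiles(r1, pr, tab)
  d <- as.data.frame(prof)
  expect_true(all(d$n[d$position %in% as.character(-10:-1)] == 0L))
  expect_gt(d$n[d$position == "0"], 0L)
})

test_that("uniform table yields a flat aggregated profile", {
  u <- generatePropensityFixture(0, 0)
  sp <- small_spec(seed = 61L, n = 60L)
  g <- generateProteome(sp)
  r <- detectPure(g$proteome)
  prof <- aggregateRegionProfiles(r, g$proteome, u)
  d <- as.data.frame(prof)
  on_support <- d$n > 0
  expect_equal(d$aaa[on_support], rep(1 / 27, sum(on_support)))
  expect_equal(d$others[on_support], rep(25 / 27, sum(on_support)))
})
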