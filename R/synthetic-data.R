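# Synthetic proteome generator with a ground-truth ledger.
#
# By default 730 of 1000 proteins host exactly one region (the remainder
# populate the "no polyA" class so peptide-call contrasts are testable).
# Proteins are i.i.d. background sequences (position 1 fixed to M) into
# which repeat regions of declared purity, length and impurity count are
# stamped at recorded coordinates, with guard bands of non-target residues
# around each region and optional flank-bias rules (e.g. G at +1 with a
# set probability). Background stretches that would themselves trigger the
# detectors are rejected and redrawn, so the truth ledger is exhaustive
# and detection on clean synthetic data recovers exactly the planted
# regions.

#' Build a synthetic-proteome specification
#'
#' Returns the validated parameter list consumed by [generateProteome()],
#' [generateAnnotations()] and the truth-driven tests. Defaults encode the
#' planted study conditions: 1000 proteins, uniform background, a mixed
#' pure/impure region plan with at most one region per protein, impurities
#' enriched 3-fold in proline relative to background, glycine at flank
#' position +1 with probability 0.4, a quarter of regions starting at
#' position 2, and a 0.5 mitochondrial-transit-peptide probability for
#' proteins whose repeat starts at position 2 (0.02 otherwise).
#'
#' @param nProteins Number of proteins.
#' @param lengthRange Min/max protein length (uniform).
#' @param background Named frequency vector over the 20 standard letters,
#'   or NULL for uniform.
#' @param planPure data.frame(length, count) of pure regions to plant.
#' @param planImpure data.frame(length, nImpurities, count) of impure
#'   regions; at most \code{window - windowMinCount} impurities per region
#'   so that every length-\code{window} window inside a region still
#'   qualifies, which guarantees exact recovery by [detectImpure()].
#' @param impurityEnrichment Named fold-changes applied to the background
#'   when drawing impurity letters (e.g. \code{c(P = 3)}); remaining
#'   letters share the leftover mass proportionally to background. The
#'   target letter is never an impurity.
#' @param flankBias data.frame(position, letter, prob): at flank position
#'   \code{position} (negative = before start, positive = after end) the
#'   residue is \code{letter} with probability \code{prob}, otherwise a
#'   background draw excluding both the target and \code{letter} (so the
#'   planted frequency equals \code{prob} exactly in expectation).
#' @param startAtTwoFraction Fraction of regions forced to start at
#'   position 2 (right after the initial methionine); the rest start
#'   uniformly in the feasible interior.
#' @param pepProbs Named list (classes "1", "2", "3-20", ">20", "none") of
#'   \code{c(mTP = , SP = )} probabilities for [generateAnnotations()].
#' @param locationPrior Named prior over the five location labels.
#' @param locationRelpos NULL for labels independent of position, or a
#'   named list label -> c(mean, sd): labels are then sampled with weight
#'   prior x normal density at the protein's repeat relative position,
#'   planting a location/position coupling.
#' @param suppressBackgroundRuns Reject-and-redraw background stretches
#'   that the detectors would call (default TRUE). Disable for stress
#'   tests only; the truth ledger is then no longer exhaustive.
#' @param target,minPureLen,window,windowMinCount Detector parameters the
#'   truth must satisfy.
#' @param seed Single integer governing all randomness.
#' @return A validated list of class \code{polyASyntheticSpec}.
#' @export
syntheticSpec <- function(nProteins = 1000L,
                          lengthRange = c(150L, 400L),
                          background = NULL,
                          planPure = data.frame(
                            length = c(4L, 5L, 6L, 8L, 10L),
                            count = c(100L, 80L, 60L, 40L, 20L)),
                          planImpure = data.frame(
                            length = c(5L, 6L, 7L, 8L, 10L),
                            nImpurities = c(1L, 1L, 2L, 2L, 2L),
                            count = c(90L, 100L, 100L, 80L, 60L)),
                          impurityEnrichment = c(P = 3),
                          flankBias = data.frame(position = 1L,
                                                 letter = "G", prob = 0.4),
                          startAtTwoFraction = 0.25,
                          pepProbs = list(
                            "1" = c(mTP = 0.02, SP = 0.05),
                            "2" = c(mTP = 0.5, SP = 0.05),
                            "3-20" = c(mTP = 0.02, SP = 0.25),
                            ">20" = c(mTP = 0.02, SP = 0.1),
                            "none" = c(mTP = 0.02, SP = 0.18)),
                          locationPrior = c(Nucleus = 0.3, Cytoplasm = 0.3,
                                            Mitochondrion = 0.1,
                                            Secreted = 0.1,
                                            "Other/Mixed" = 0.2),
                          locationRelpos = NULL,
                          suppressBackgroundRuns = TRUE,
                          target = "A", minPureLen = 4L, window = 6L,
                          windowMinCount = 4L, seed = 1L) {
  .stopifnot_scalar_letter(target)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20L), .AA20)
  } else {
    if (!all(.AA20 %in% names(background)))
      stop("background must name all 20 standard letters")
    background <- background[.AA20] / sum(background[.AA20])
  }
  stopifnot(length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2],
            startAtTwoFraction >= 0, startAtTwoFraction <= 1,
            all(flankBias$prob >= 0), all(flankBias$prob <= 1),
            all(abs(flankBias$position) >= 1),
            all(abs(flankBias$position) <= 10))
  if (any(flankBias$letter == target))
    stop("flank-bias letters must differ from the target residue")
  if (any(planImpure$nImpurities > window - windowMinCount))
    stop("at most ", window - windowMinCount,
         " impurities per region: exact recovery is otherwise not ",
         "guaranteed")
  if (any(planImpure$nImpurities < 1L))
    stop("impure regions need at least one impurity")
  # every run of target inside an impure region must stay below minPureLen
  max_len <- planImpure$nImpurities +
    (planImpure$nImpurities + 1L) * (minPureLen - 1L)
  if (any(planImpure$length > max_len))
    stop("impure region too long for its impurity count (internal pure ",
         "runs would arise)")
  if (any(planImpure$length < 5L))
    stop("impure regions must have length >= 5")
  if (any(planPure$length < minPureLen))
    stop("pure regions must have length >= minPureLen")
  n_regions <- sum(planPure$count) + sum(planImpure$count)
  if (n_regions > nProteins)
    stop("region plan exceeds nProteins (one region per protein)")
  max_region <- max(c(planPure$length, planImpure$length, 0L))
  if (lengthRange[1] < max_region + 30L)
    stop("region plan infeasible: proteins too short for the 12-residue ",
         "flank clearance")
  planPure$length <- as.integer(planPure$length)
  planPure$count <- as.integer(planPure$count)
  planImpure$length <- as.integer(planImpure$length)
  planImpure$nImpurities <- as.integer(planImpure$nImpurities)
  planImpure$count <- as.integer(planImpure$count)
  flankBias$position <- as.integer(flankBias$position)
  spec <- list(nProteins = as.integer(nProteins),
               lengthRange = as.integer(lengthRange),
               background = background, planPure = planPure,
               planImpure = planImpure,
               impurityEnrichment = impurityEnrichment,
               flankBias = flankBias,
               startAtTwoFraction = startAtTwoFraction,
               pepProbs = pepProbs, locationPrior = locationPrior,
               locationRelpos = locationRelpos,
               suppressBackgroundRuns = suppressBackgroundRuns,
               target = target, minPureLen = as.integer(minPureLen),
               window = as.integer(window),
               windowMinCount = as.integer(windowMinCount),
               seed = as.integer(seed))
  class(spec) <- "polyASyntheticSpec"
  spec
}

# Impurity letter distribution: background with fold-changes applied,
# target excluded, remaining letters scaled to fill the leftover mass.
.impurity_composition <- function(background, enrichment, target) {
  bg <- background[setdiff(names(background), target)]
  q <- bg / sum(bg) * 0  # init
  enr_letters <- intersect(names(enrichment), names(bg))
  q[enr_letters] <- background[enr_letters] * enrichment[enr_letters]
  if (sum(q) >= 1)
    stop("impurity enrichment leaves no mass for other letters")
  rest <- setdiff(names(bg), enr_letters)
  q[rest] <- bg[rest] / sum(bg[rest]) * (1 - sum(q))
  q
}

# Sample impurity offsets for a region so that no internal target run
# reaches minPureLen; offsets lie in 2..len-1.
.sample_offsets <- function(len, k, min_pure) {
  for (try in seq_len(1000L)) {
    offs <- sort(sample(seq(2L, len - 1L), k))
    runs <- diff(c(0L, offs, len + 1L)) - 1L
    if (all(runs < min_pure)) return(offs)
  }
  stop("could not place ", k, " impurities in region of length ", len)
}

# Detection result signature for exact truth comparison.
.det_signature <- function(seqs, target, min_pure, window, wmin) {
  p <- detectPure(seqs, target = target, minLen = min_pure)
  im <- detectImpure(seqs, target = target, window = window,
                     windowMinCount = wmin)
  list(pure = cbind(start(p), end(p)),
       impure = cbind(start(im), end(im)),
       offsets = lapply(impurities(im), `[[`, "offset"))
}

#' Generate a synthetic proteome with ground truth
#'
#' Realises a [syntheticSpec()]: draws protein lengths and background
#' residues, stamps the planted regions (with guard bands of non-target
#' residues and flank-bias rules), and — unless suppression is disabled —
#' redraws any background stretch on which the detectors would fire, so
#' that running [detectPure()] / [detectImpure()] on the output recovers
#' exactly the truth ledger. Byte-identical output under the same seed.
#'
#' @param spec A \code{polyASyntheticSpec} from [syntheticSpec()].
#' @return A list with elements \code{proteome} (named
#'   \code{AAStringSet}) and \code{truth} (\linkS4class{SyntheticTruth}).
#' @export
generateProteome <- function(spec) {
  stopifnot(inherits(spec, "polyASyntheticSpec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  ids <- sprintf("sp%05d", seq_len(spec$nProteins))
  # expand and shuffle the region plan; one region per protein
  plan <- rbind(
    do.call(rbind, lapply(seq_len(nrow(spec$planPure)), function(i)
      data.frame(purity = "pure", length = spec$planPure$length[i],
                 nImpurities = 0L)[rep(1, spec$planPure$count[i]), ])),
    do.call(rbind, lapply(seq_len(nrow(spec$planImpure)), function(i)
      data.frame(purity = "impure", length = spec$planImpure$length[i],
                 nImpurities = spec$planImpure$nImpurities[i]
                 )[rep(1, spec$planImpure$count[i]), ])))
  if (is.null(plan))
    plan <- data.frame(purity = character(), length = integer(),
                       nImpurities = integer())
  n_reg <- nrow(plan)
  plan <- plan[sample.int(n_reg), , drop = FALSE]
  host <- sample.int(spec$nProteins, n_reg)   # hosting protein per region

  bg <- spec$background
  imp_q <- .impurity_composition(bg, spec$impurityEnrichment, spec$target)
  guard_bg <- bg[setdiff(.AA20, spec$target)]
  guard_bg <- guard_bg / sum(guard_bg)
  guard_w <- spec$window - 1L

  len_pool <- seq(spec$lengthRange[1], spec$lengthRange[2])
  lens <- if (length(len_pool) == 1L) rep(len_pool, spec$nProteins)
    else sample(len_pool, spec$nProteins, replace = TRUE)
  seqs <- character(spec$nProteins)

  t_pid <- character(0); t_st <- integer(0); t_en <- integer(0)
  t_pur <- character(0); t_imp <- list()

  region_of <- rep(NA_integer_, spec$nProteins)
  region_of[host] <- seq_len(n_reg)

  for (i in seq_len(spec$nProteins)) {
    L <- lens[i]
    ri <- region_of[i]
    stamp <- rep(NA_character_, L)   # fixed residues (region/guard/bias)
    protected <- rep(FALSE, L)
    truth_here <- NULL
    if (!is.na(ri)) {
      len <- plan$length[ri]
      at2 <- stats::runif(1) < spec$startAtTwoFraction
      st <- if (at2) 2L else
        sample(seq(guard_w + 10L, L - len - guard_w - 9L), 1L)
      en <- st + len - 1L
      content <- rep(spec$target, len)
      imp_df <- data.frame(offset = integer(), residue = character())
      if (plan$purity[ri] == "impure") {
        offs <- .sample_offsets(len, plan$nImpurities[ri],
                                spec$minPureLen)
        letters <- sample(names(imp_q), length(offs), replace = TRUE,
                          prob = imp_q)
        content[offs] <- letters
        imp_df <- data.frame(offset = offs, residue = letters,
                             stringsAsFactors = FALSE)
      }
      stamp[st:en] <- content
      protected[st:en] <- TRUE
      # guard bands of non-target residues on both sides
      gl <- if (st - 1L >= 2L) seq(max(2L, st - guard_w), st - 1L)
        else integer(0)
      gr <- if (en + 1L <= L) seq(en + 1L, min(L, en + guard_w))
        else integer(0)
      if (length(gl) > 0L) {
        stamp[gl] <- sample(names(guard_bg), length(gl), replace = TRUE,
                            prob = guard_bg)
        protected[gl] <- TRUE
      }
      if (length(gr) > 0L) {
        stamp[gr] <- sample(names(guard_bg), length(gr), replace = TRUE,
                            prob = guard_bg)
        protected[gr] <- TRUE
      }
      # flank-bias rules override guard draws
      for (r in seq_len(nrow(spec$flankBias))) {
        p <- spec$flankBias$position[r]
        abs_pos <- if (p < 0) st + p else en + p
        if (abs_pos < 2L || abs_pos > L) next
        lt <- spec$flankBias$letter[r]
        alt <- guard_bg[setdiff(names(guard_bg), lt)]
        alt <- alt / sum(alt)
        stamp[abs_pos] <- if (stats::runif(1) < spec$flankBias$prob[r]) lt
          else sample(names(alt), 1L, prob = alt)
        protected[abs_pos] <- TRUE
      }
      truth_here <- list(st = st, en = en, pur = plan$purity[ri],
                         imp = imp_df)
    }
    stamp[1L] <- "M"; protected[1L] <- TRUE
    free <- which(!protected)
    want <- list(
      pure = if (!is.null(truth_here) && truth_here$pur == "pure")
        cbind(truth_here$st, truth_here$en) else
        matrix(integer(), ncol = 2),
      impure = if (!is.null(truth_here) && truth_here$pur == "impure")
        cbind(truth_here$st, truth_here$en) else
        matrix(integer(), ncol = 2),
      offsets = if (!is.null(truth_here) && truth_here$pur == "impure")
        list(truth_here$imp$offset) else list())
    for (attempt in seq_len(200L)) {
      ch <- stamp
      ch[free] <- sample(.AA20, length(free), replace = TRUE, prob = bg)
      sq <- stats::setNames(paste(ch, collapse = ""), ids[i])
      if (!spec$suppressBackgroundRuns) break
      sig <- .det_signature(sq, spec$target, spec$minPureLen,
                            spec$window, spec$windowMinCount)
      if (identical(unname(sig$pure), unname(want$pure)) &&
          identical(unname(sig$impure), unname(want$impure)) &&
          identical(lapply(sig$offsets, as.integer),
                    lapply(want$offsets, as.integer))) break
      if (attempt == 200L)
        stop("failed to realise protein ", ids[i],
             " without spurious detections")
    }
    seqs[i] <- sq
    if (!is.null(truth_here)) {
      t_pid <- c(t_pid, ids[i]); t_st <- c(t_st, truth_here$st)
      t_en <- c(t_en, truth_here$en); t_pur <- c(t_pur, truth_here$pur)
      t_imp <- c(t_imp, list(truth_here$imp))
    }
  }

  regions <- RepeatRegions(t_pid, t_st, t_en, t_pur,
                           target = spec$target, impurities = t_imp)
  start_class <- stats::setNames(rep("none", spec$nProteins), ids)
  if (length(regions) > 0L) {
    nt <- mostNTerminalRegion(regions)
    start_class[proteinId(nt)] <- .start_class(start(nt))
  }
  proteins <- data.frame(id = ids, length = lens,
                         startClass = unname(start_class),
                         stringsAsFactors = FALSE)
  proteome <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  truth <- methods::new("SyntheticTruth", regions = regions,
                        proteins = proteins,
                        params = list(seed = spec$seed, spec = spec,
                                      impurityComposition = imp_q))
  list(proteome = proteome, truth = truth)
}

#' Generate annotations coupled to a synthetic truth
#'
#' Samples a peptide call (mTP / SP / other) per protein from the
#' class-conditional probabilities in the spec, the class being the start
#' class of the protein's most N-terminal planted region ("none" for
#' proteins without one). Location labels are drawn from the prior,
#' optionally re-weighted by a normal density at the protein's repeat
#' relative position (midpoint mode) to plant a location/position
#' coupling.
#'
#' @param spec The \code{polyASyntheticSpec} used for generation.
#' @param truth The matching \linkS4class{SyntheticTruth}.
#' @return An \linkS4class{AnnotationTable}.
#' @export
generateAnnotations <- function(spec, truth) {
  stopifnot(inherits(spec, "polyASyntheticSpec"),
            methods::is(truth, "SyntheticTruth"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed + 1L)

  prot <- truthProteins(truth)
  n <- nrow(prot)
  # relative position (midpoint) of the most N-terminal region, NA if none
  relpos <- rep(NA_real_, n)
  regions <- truthRegions(truth)
  if (length(regions) > 0L) {
    nt <- mostNTerminalRegion(regions)
    idx <- match(proteinId(nt), prot$id)
    relpos[idx] <- ((start(nt) + end(nt)) / 2) / prot$length[idx]
  }
  pep <- character(n)
  for (i in seq_len(n)) {
    cl <- prot$startClass[i]
    pp <- spec$pepProbs[[cl]]
    if (is.null(pp)) pp <- c(mTP = 0, SP = 0)
    pep[i] <- sample(c("mTP", "SP", "other"), 1L,
                     prob = c(pp["mTP"], pp["SP"],
                              max(0, 1 - pp["mTP"] - pp["SP"])))
  }
  prior <- spec$locationPrior / sum(spec$locationPrior)
  loc <- character(n)
  for (i in seq_len(n)) {
    w <- prior
    if (!is.null(spec$locationRelpos) && !is.na(relpos[i])) {
      for (lab in names(w)) {
        par <- spec$locationRelpos[[lab]]
        if (!is.null(par))
          w[lab] <- w[lab] * stats::dnorm(relpos[i], par[1], par[2])
      }
      if (sum(w) == 0) w <- prior
    }
    loc[i] <- sample(names(w), 1L, prob = w)
  }
  methods::new("AnnotationTable", id = prot$id, location = loc,
               peptide = pep)
}

#' Generate a synthetic tripeptide propensity fixture
#'
#' Builds a full 20^3-tripeptide table caricaturing the structural roles
#' seen around alanine repeats: all-alanine tripeptides lean toward the
#' all-helical class ("aaa"), tripeptides containing the helix breakers G
#' or P lean toward the grouped "others" classes, and everything else is
#' near-uniform. Each biased row is the convex mixture
#' \code{bias * concentrated + (1 - bias) * uniform}, so both biases at 0
#' give the exactly uniform table.
#'
#' @param alanineHelixBias Mass moved toward "aaa" for all-alanine
#'   tripeptides (and half that for tripeptides with two alanines and no
#'   breaker), in [0, 1].
#' @param gpBreakerBias Mass moved toward the 25 "others" classes for
#'   tripeptides containing G or P, in [0, 1].
#' @return A \linkS4class{PropensityTable} covering all 8000 tripeptides.
#' @export
generatePropensityFixture <- function(alanineHelixBias = 0.8,
                                      gpBreakerBias = 0.6) {
  stopifnot(alanineHelixBias >= 0, alanineHelixBias <= 1,
            gpBreakerBias >= 0, gpBreakerBias <= 1)
  tris <- as.vector(outer(outer(.AA20, .AA20, paste0), .AA20, paste0))
  probs <- matrix(1 / 27, nrow = length(tris), ncol = 27L,
                  dimnames = list(tris, .CLASS27))
  others_idx <- !.CLASS27 %in% c("aaa", "bbb")
  u_others <- ifelse(others_idx, 1 / 25, 0)
  e_aaa <- as.numeric(.CLASS27 == "aaa")
  nA <- vapply(strsplit(tris, ""), function(x) sum(x == "A"), integer(1))
  hasGP <- grepl("[GP]", tris)
  for (i in seq_along(tris)) {
    if (hasGP[i]) {
      probs[i, ] <- gpBreakerBias * u_others +
        (1 - gpBreakerBias) / 27
    } else if (nA[i] == 3L) {
      probs[i, ] <- alanineHelixBias * e_aaa +
        (1 - alanineHelixBias) / 27
    } else if (nA[i] == 2L) {
      probs[i, ] <- (alanineHelixBias / 2) * e_aaa +
        (1 - alanineHelixBias / 2) / 27
    }
  }
  methods::new("PropensityTable", probs = probs,
               provenance = sprintf(
                 "synthetic fixture (alanineHelixBias=%g, gpBreakerBias=%g)",
                 alanineHelixBias, gpBreakerBias))
}
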