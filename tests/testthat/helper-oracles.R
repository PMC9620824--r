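# Brute-force oracles and fixture builders shared across tests. The
# oracles deliberately re-derive results from first principles (regex run
# enumeration, explicit window enumeration, combinatorial enumeration of
# rank orderings) so they stay independent of the package's code paths.

# Maximal-run enumeration for pure repeats, via regex.
oracle_pure <- function(s, target = "A", min_len = 4L) {
  m <- gregexpr(sprintf("%s{%d,}", target, min_len), s)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Window-union brute force for impure repeats: enumerate every window of
# length `window` (plus shorter windows touching a sequence end), mark
# those holding >= k target residues, union the covered residues, trim
# each covered stretch to target termini, apply the length / target-count
# / impurity filters.
oracle_impure <- function(s, target = "A", window = 6L, k = 4L,
                          require_impurity = TRUE) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  t <- ch == target
  cover <- rep(FALSE, L)
  if (L >= window) {
    for (i in seq_len(L - window + 1L)) {
      if (sum(t[i:(i + window - 1L)]) >= k)
        cover[i:(i + window - 1L)] <- TRUE
    }
  }
  for (len in seq_len(min(L, window - 1L))) {
    if (sum(t[seq_len(len)]) >= k) cover[seq_len(len)] <- TRUE
    if (sum(t[seq(L - len + 1L, L)]) >= k) cover[seq(L - len + 1L, L)] <- TRUE
  }
  r <- rle(cover)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = integer(), end = integer(),
                    imp = character(), stringsAsFactors = FALSE)
  for (j in which(r$values)) {
    a <- starts[j]; b <- ends[j]
    idx <- which(t[a:b])
    if (length(idx) == 0L) next
    a2 <- a + idx[1] - 1L
    b2 <- a + idx[length(idx)] - 1L
    len <- b2 - a2 + 1L
    nt <- sum(t[a2:b2])
    if (len < 5L || nt < k) next
    if (require_impurity && nt == len) next
    offs <- which(!t[a2:b2])
    out <- rbind(out, data.frame(
      start = a2, end = b2, imp = paste(offs, collapse = ","),
      stringsAsFactors = FALSE))
  }
  out
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of
# the pooled values to the two groups (untied samples only).
oracle_mw_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  centre <- na * nb / 2
  p <- if (u_obs <= centre) 2 * mean(us <= u_obs) else 2 * mean(us >= u_obs)
  list(statistic = u_obs, p.value = min(1, p))
}

# Random protein-like sequence with a given alanine frequency.
random_seq <- function(L, a_freq, letters = c("A", "G", "P", "L", "S", "V")) {
  probs <- c(a_freq, rep((1 - a_freq) / (length(letters) - 1),
                         length(letters) - 1))
  paste(sample(letters, L, replace = TRUE, prob = probs), collapse = "")
}

# Flatten detector output for one protein into the oracle layout.
impure_as_oracle <- function(regions) {
  df <- as.data.frame(regions)
  data.frame(start = df$start, end = df$end,
             imp = vapply(impurities(regions), function(d)
               paste(d$offset, collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}

# A small deterministic spec for fast synthetic runs; region counts scale
# with the proteome size (about 2/3 of proteins host one region).
small_spec <- function(seed = 11L, n = 120L) {
  syntheticSpec(
    nProteins = n,
    planPure = data.frame(length = c(4L, 6L),
                          count = c(n %/% 6L, n %/% 8L)),
    planImpure = data.frame(length = c(5L, 7L), nImpurities = c(1L, 2L),
                            count = c(n %/% 4L, n %/% 5L)),
    seed = seed)
}
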