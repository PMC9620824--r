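# Internal helpers shared across modules.

# The 20 standard amino-acid letters, alphabetical.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard letters tolerated in sequences but excluded from
# every composition denominator.
.AA_AMBIG <- c("X", "B", "Z", "U", "O")

.AA_LEGAL <- c(.AA20, .AA_AMBIG)

# Split a character vector of sequences into a list of single-letter vectors.
.seq_chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)

# Coerce a proteome argument to a named character vector of sequences.
.as_seqvec <- function(proteome) {
  if (methods::is(proteome, "XStringSet")) {
    out <- as.character(proteome)
  } else if (is.character(proteome)) {
    out <- proteome
  } else {
    stop("'proteome' must be an AAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("proteome sequences must be named with protein ids")
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate protein id in proteome: ",
         names(out)[anyDuplicated(names(out))])
  }
  out
}

# Flank position labels -flank..-1, +1..+flank (no 0), in display order.
.flank_labels <- function(flank) {
  c(sprintf("%d", seq(-flank, -1L)), sprintf("+%d", seq_len(flank)))
}

# Length class used for impure repeats: "5", "6", ">6".
.impure_length_class <- function(len) {
  ifelse(len <= 5L, "5", ifelse(len == 6L, "6", ">6"))
}

.stopifnot_scalar_letter <- function(target) {
  if (!is.character(target) || length(target) != 1L || nchar(target) != 1L ||
      !(target %in% .AA20)) {
    stop("'target' must be a single standard amino-acid letter")
  }
}
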