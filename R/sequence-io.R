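#' Read a protein FASTA file
#'
#' Loads a proteome as a named [Biostrings::AAStringSet]. Sequences are
#' upper-cased; the header token before the first whitespace becomes the
#' protein id, except for UniProt-style headers ("db|ACCESSION|NAME") where
#' the accession field is extracted. Line wrapping and trailing whitespace
#' are tolerated.
#'
#' Sequences may contain the 20 standard amino-acid letters plus the
#' ambiguity letters X, B, Z, U and O; any other character is a hard error
#' reporting its position.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{AAStringSet}, one entry per FASTA record in file
#'   order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">sp|P00001|TEST", "MAAAAG"), f)
#' readProteome(f)
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  uni <- grepl("^[a-z]{2}\\|[^|]+\\|", ids)
  ids[uni] <- sub("^[a-z]{2}\\|([^|]+)\\|.*$", "\\1", ids[uni])
  if (any(ids == "")) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate protein id in FASTA: ", dup[1])
  seqs <- toupper(gsub("[ \t\r]", "", as.character(raw)))
  chars <- .seq_chars(seqs)
  for (k in seq_along(chars)) {
    bad <- which(!chars[[k]] %in% .AA_LEGAL)
    if (length(bad) > 0L)
      stop("illegal character '", chars[[k]][bad[1]], "' at position ",
           bad[1], " of record ", ids[k])
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a proteome to FASTA
#'
#' Writes sequences wrapped at 60 columns; reading the file back with
#' [readProteome()] reproduces ids, order and sequences exactly.
#'
#' @param proteome A named \code{AAStringSet} or character vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeProteome <- function(proteome, path) {
  seqs <- .as_seqvec(proteome)
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a per-protein annotation table
#'
#' Parses a TSV with header columns \code{id}, \code{location},
#' \code{peptide}. Empty cells become NA. Location labels must come from
#' \{Nucleus, Cytoplasm, Mitochondrion, Secreted, Other/Mixed\} and peptide
#' calls from \{mTP, SP, other\}; anything else is a hard error, as is a
#' duplicated id.
#'
#' @param path Path to the TSV file.
#' @return An \linkS4class{AnnotationTable}.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("", "NA"))
  need <- c("id", "location", "peptide")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns id, location, peptide")
  if (anyDuplicated(df$id))
    stop("duplicate id in annotation table: ",
         df$id[duplicated(df$id)][1])
  badloc <- setdiff(stats::na.omit(unique(df$location)), .LOCATION_LEVELS)
  if (length(badloc) > 0L)
    stop("unknown location label: ", badloc[1])
  badpep <- setdiff(stats::na.omit(unique(df$peptide)), .PEPTIDE_LEVELS)
  if (length(badpep) > 0L)
    stop("unknown peptide label: ", badpep[1])
  methods::new("AnnotationTable", id = df$id,
               location = as.character(df$location),
               peptide = as.character(df$peptide))
}

#' Write an annotation table to TSV
#'
#' @param annotations An \linkS4class{AnnotationTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotations <- function(annotations, path) {
  stopifnot(methods::is(annotations, "AnnotationTable"))
  df <- as.data.frame(annotations)
  df[is.na(df)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Proteome background amino-acid composition
#'
#' Frequency of each of the 20 standard letters over all sequences, used as
#' the denominator ("Bg") of every enrichment ratio. Ambiguity letters are
#' excluded from numerator and denominator.
#'
#' @param proteome A named \code{AAStringSet} or character vector of
#'   sequences.
#' @return A \linkS4class{BackgroundComposition}.
#' @examples
#' backgroundComposition(c(p1 = "AAXG"))  # A: 2/3, G: 1/3, X excluded
#' @export
backgroundComposition <- function(proteome) {
  seqs <- .as_seqvec(proteome)
  x <- Biostrings::AAStringSet(seqs)
  counts <- colSums(Biostrings::letterFrequency(x, letters = .AA20))
  names(counts) <- .AA20
  total <- sum(counts)
  if (total == 0)
    stop("proteome contains no standard amino-acid residues")
  methods::new("BackgroundComposition", freq = counts / total,
               totalResidues = total)
}
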