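# Input handling. A "sequence" argument may be a single character string, a
# character vector of records, a Biostrings DNAString/DNAStringSet, or the
# path of a FASTA file. Records are concatenated with a break between them;
# non-ACGT characters (N runs and the like) also act as breaks, so windows
# and contexts never span them.

.seqRecords <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "XString"))
    return(as.character(x))
  if (methods::is(x, "XStringSet"))
    return(as.character(x))
  if (is.character(x) && length(x) == 1L &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", x, ignore.case = TRUE) &&
      file.exists(x))
    return(as.character(Biostrings::readDNAStringSet(x)))
  if (is.character(x)) {
    if (length(x) < 1L) stop("empty sequence input")
    return(x)
  }
  stop("cannot interpret 'x' as a sequence (character, DNAStringSet or FASTA path)")
}

.seqCodes <- function(x) {
  cpp_encode_records(.seqRecords(x))
}

#' Read a FASTA file as sequence records
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet} returning plain
#' character records. Records are treated as independent fragments by all
#' polarmin operations (windows never span record boundaries).
#'
#' @param path FASTA file path.
#' @return Named character vector of records.
#' @export
readFastaRecords <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}

.checkWK <- function(w, k) {
  if (length(w) != 1L || is.na(w) || w < 2) stop("w must be a single integer >= 2")
  if (length(k) != 1L || is.na(k) || k < 1 || k > 31)
    stop("k must be a single integer in [1, 31]")
}

.checkSlackness <- function(s) {
  if (length(s) != 1L || is.na(s) || s < 0 || s >= 0.5)
    stop("slackness s must lie in [0, 1/2)")
}

# distance threshold of Definition-2 style spacing: "at least (1-s)w bases
# apart", rounded up so the integer rule never admits a pair the
# real-valued rule would reject
.spacingThreshold <- function(w, s) as.integer(ceiling((1 - s) * w))
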