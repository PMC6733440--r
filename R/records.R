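#' Construct a set of DNA sequence records
#'
#' The package's working container for FASTA data: a plain `data.frame`
#' with columns `id` (unique token, no whitespace), `desc` (free text,
#' may be empty) and `seq` (uppercase DNA over `A,C,G,T,N`). Most
#' functions in the package accept and return this shape.
#'
#' @param id character vector of record identifiers (first whitespace
#'   token of a FASTA header).
#' @param seq character vector of DNA sequences.
#' @param desc optional character vector of header descriptions.
#' @param lenient if `TRUE`, IUPAC ambiguity codes (and `U`) are mapped
#'   to `N`; if `FALSE` (default) any letter outside `A,C,G,T,N` is an
#'   error. `N` is the gap currency of this package, so everything
#'   unknown collapses onto it.
#' @return a `data.frame` with columns `id`, `desc`, `seq`.
#' @export
dna_records <- function(id, seq, desc = rep("", length(id)), lenient = FALSE) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  desc <- as.character(desc)
  if (length(id) != length(seq) || length(id) != length(desc))
    stop("id, seq and desc must have equal length")
  if (any(!nzchar(id)) || any(grepl("\\s", id)))
    stop("record ids must be non-empty tokens without whitespace")
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(seq)))
    stop("zero-length sequence for record(s): ",
         paste(id[!nzchar(seq)], collapse = ", "))
  seq <- sanitize_dna(seq, lenient = lenient, ids = id)
  data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
}

# Uppercase + alphabet policy. IUPAC ambiguity codes -> N when lenient.
sanitize_dna <- function(seq, lenient = FALSE, ids = NULL) {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    if (lenient) {
      # IUPAC nucleotide ambiguity codes plus U; anything else is an error
      seq[bad] <- chartr("URYSWKMBDHV", "NNNNNNNNNNN", seq[bad])
      still <- grepl("[^ACGTN]", seq)
      if (any(still))
        stop("illegal characters in sequence(s): ",
             paste(if (is.null(ids)) which(still) else ids[still], collapse = ", "))
    } else {
      stop("non-ACGTN characters in sequence(s): ",
           paste(if (is.null(ids)) which(bad) else ids[bad], collapse = ", "),
           " (use lenient = TRUE to map IUPAC codes to N)")
    }
  }
  seq
}

#' Reverse complement of DNA strings
#'
#' Standard Watson-Crick complement over `A,C,G,T` with `N` mapped to
#' `N`, then reversed. Vectorised over its input.
#'
#' @param seq character vector of DNA strings over `A,C,G,T,N`.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("ACGTN")  # "NACGT"
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq)))
    stop("reverse_complement: sequence contains letters outside ACGTN")
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
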