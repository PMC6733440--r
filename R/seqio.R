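#' Read a FASTA file into a record table
#'
#' Parses a (plain-text, uncompressed) FASTA file via
#' [Biostrings::readBStringSet()] and returns the package's record
#' container. Sequences are uppercased and multi-line bodies
#' concatenated; record order follows file order.
#'
#' @param path path to a FASTA file.
#' @param lenient map IUPAC ambiguity codes to `N` instead of erroring
#'   (see [dna_records()]).
#' @return a `data.frame` with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("no records in FASTA file: ", path)
  if (!startsWith(first, ">"))
    stop("malformed FASTA (first line must start with '>'): ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  dna_records(id = id, seq = as.character(set), desc = desc,
              lenient = lenient)
}

#' Write a record table as FASTA
#'
#' @param records record table as produced by [dna_records()].
#' @param path output path.
#' @param width positive line width for wrapping sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), width >= 1L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i]))
      paste(records$id[i], records$desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Build a byte-offset index of a FASTA file
#'
#' Emulates the exonerate `fastaindex` utility: one scan of the file
#' records, for every identifier, the byte offset of its header line and
#' its sequence length, so that [fetch_sequence()] can later seek
#' directly to a record instead of rescanning the file.
#'
#' @param path path to a FASTA file.
#' @param write_sidecar if `TRUE`, persist the index next to the FASTA
#'   as `<path>.gfidx`, a three-column tab-separated text file
#'   (id, byte offset of the header line, sequence length in bp).
#' @return an object of class `fasta_index`.
#' @export
build_index <- function(path, write_sidecar = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  ids <- character(0); offs <- numeric(0); lens <- numeric(0)
  pos <- 0
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) break
    nb <- nchar(line, type = "bytes") + 1L  # assumes \n line endings
    if (startsWith(line, ">")) {
      ids <- c(ids, sub("\\s.*$", "", substring(line, 2L)))
      offs <- c(offs, pos)
      lens <- c(lens, 0)
    } else if (length(lens)) {
      lens[length(lens)] <- lens[length(lens)] + nchar(trimws(line))
    }
    pos <- pos + nb
  }
  if (length(ids) == 0L) stop("no records in FASTA file: ", path)
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  idx <- structure(
    list(path = normalizePath(path),
         entries = data.frame(id = ids, offset = offs, length = lens,
                              stringsAsFactors = FALSE)),
    class = "fasta_index")
  if (write_sidecar) {
    utils::write.table(idx$entries, paste0(path, ".gfidx"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  idx
}

#' @export
print.fasta_index <- function(x, ...) {
  cat("FASTA index of", x$path, "-", nrow(x$entries), "records\n")
  invisible(x)
}

#' Fetch one record from an indexed FASTA file
#'
#' Emulates exonerate's `fastafetch`: seeks to the stored byte offset of
#' the record and reads only until the next header, so the cost is
#' proportional to the record, not the file.
#'
#' @param index a `fasta_index` from [build_index()].
#' @param id record identifier to fetch.
#' @param lenient see [read_fasta()].
#' @return a one-row record table (`id`, `desc`, `seq`).
#' @export
fetch_sequence <- function(index, id, lenient = FALSE) {
  stopifnot(inherits(index, "fasta_index"))
  hit <- match(id, index$entries$id)
  if (is.na(hit)) {
    near <- utils::head(index$entries$id[
      order(utils::adist(id, index$entries$id))], 3L)
    stop("id '", id, "' not in index; nearest: ",
         paste(near, collapse = ", "))
  }
  con <- file(index$path, open = "rb")
  on.exit(close(con))
  seek(con, where = index$entries$offset[hit], origin = "start")
  header <- readLines(con, n = 1L, warn = FALSE)
  if (!startsWith(header, ">"))
    stop("stale index: no header at stored offset for '", id, "'")
  body <- character(0)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L || startsWith(line, ">")) break
    body <- c(body, trimws(line))
  }
  hdr <- substring(header, 2L)
  dna_records(id = sub("\\s.*$", "", hdr),
              seq = paste(body, collapse = ""),
              desc = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
              lenient = lenient)
}

#' Parse a scaffold-to-read evidence map
#'
#' The fill engine only ever offers a scaffold the long reads that the
#' scaffolder itself used to build that scaffold. Two input dialects
#' carry that association:
#'
#' * a directory of per-scaffold files named `<scaffold_id>.*`, each
#'   either a FASTA (record ids are read ids) or a plain list of read
#'   ids, one per line — emulating the per-superscaffold
#'   "inner-scaffold-sequences" output of a long-read scaffolder run
#'   with evidence output enabled;
#' * a two-column tab-separated table `scaffold_id<TAB>read_id`
#'   (no header).
#'
#' Duplicate (scaffold, read) pairs are dropped keeping the first; a
#' read listed under two different scaffolds is kept under the first
#' scaffold and the cross-listing reported with a warning (such listings
#' can indicate scaffolding errors).
#'
#' @param path directory or TSV file.
#' @return an object of class `evidence_map`: a named list of character
#'   vectors of read ids, in input order, with attribute
#'   `cross_listed` (a data.frame of dropped cross-listings).
#' @export
parse_evidence <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    files <- files[!dir.exists(files)]
    if (length(files) == 0L)
      stop("evidence directory is empty: ", path,
           " (run the scaffolder with per-scaffold evidence output enabled)")
    scf <- sub("\\..*$", "", basename(files))
    pairs <- do.call(rbind, lapply(seq_along(files), function(i) {
      lines <- readLines(files[i], warn = FALSE)
      lines <- trimws(lines)
      lines <- lines[nzchar(lines)]
      ids <- if (any(startsWith(lines, ">")))
        sub("\\s.*$", "", substring(lines[startsWith(lines, ">")], 2L))
      else lines
      if (length(ids) == 0L) return(NULL)
      data.frame(scaffold = scf[i], read = ids, stringsAsFactors = FALSE)
    }))
  } else if (file.exists(path)) {
    pairs <- utils::read.table(path, sep = "\t", header = FALSE,
                               colClasses = "character",
                               col.names = c("scaffold", "read"))
  } else {
    stop("evidence path not found: ", path,
         " (the fill step requires the scaffolder's read-evidence output;",
         " re-run scaffolding with evidence reporting enabled)")
  }
  if (any(grepl("\\s", pairs$scaffold)) || any(grepl("\\s", pairs$read)))
    stop("evidence ids must be whitespace-free tokens")
  # dedupe exact pairs, first wins
  dup_pair <- duplicated(paste(pairs$scaffold, pairs$read, sep = "\r"))
  if (any(dup_pair)) {
    warning(sum(dup_pair), " duplicate (scaffold, read) pair(s) dropped")
    pairs <- pairs[!dup_pair, , drop = FALSE]
  }
  # a read under two scaffolds: first scaffold wins, rest logged
  dup_read <- duplicated(pairs$read)
  cross <- pairs[dup_read, , drop = FALSE]
  if (nrow(cross) > 0L) {
    warning("read(s) listed under multiple scaffolds (kept under first): ",
            paste(unique(cross$read), collapse = ", "))
    pairs <- pairs[!dup_read, , drop = FALSE]
  }
  em <- split(pairs$read, factor(pairs$scaffold, levels = unique(pairs$scaffold)))
  em <- lapply(em, as.character)
  structure(em, class = "evidence_map", cross_listed = cross)
}

#' @export
print.evidence_map <- function(x, ...) {
  cat("evidence map:", length(x), "scaffold(s),",
      sum(lengths(x)), "read listing(s)\n")
  invisible(x)
}
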