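#' Parse a PacBio-style read name into its molecular origin
#'
#' Subread names of the shape `movie/well/start_end` identify the
#' SMRT-cell well (ZMW) the read came from; all subreads sharing
#' `(movie, well)` derive from the same physical molecule and must
#' therefore anchor consistent genomic locations. Names that do not
#' follow the convention yield an "unknown" origin and are exempt from
#' the conflict guard. A name with `movie/well` but an unparsable range
#' still yields a usable origin (the range is not part of the conflict
#' key).
#'
#' @param name read identifier.
#' @return list with `known` (logical), `movie`, `well` (integer),
#'   `range` (integer length-2 vector or `NULL`).
#' @examples
#' parse_read_name("m1309_s1_p0/12345/0_4523")
#' @export
parse_read_name <- function(name) {
  parts <- strsplit(name, "/", fixed = TRUE)[[1]]
  if (length(parts) < 2L || !nzchar(parts[1]) ||
      !grepl("^[0-9]+$", parts[2]))
    return(list(known = FALSE, movie = NA_character_, well = NA_integer_,
                range = NULL))
  range <- NULL
  if (length(parts) >= 3L && grepl("^[0-9]+_[0-9]+$", parts[3])) {
    range <- as.integer(strsplit(parts[3], "_", fixed = TRUE)[[1]])
  }
  list(known = TRUE, movie = parts[1], well = as.integer(parts[2]),
       range = range)
}

#' Abort gap fills with conflicting same-well read origins
#'
#' If subreads from one `(movie, well)` key anchor two or more distinct
#' gaps, all of those fills are disallowed and one conflict report per
#' key is emitted: same-molecule subreads claiming disparate locations
#' indicate a scaffolding or alignment error, so none of the claims can
#' be trusted. Reads with unknown origins pass through unchecked, as do
#' multiple same-well fills of one and the same gap.
#'
#' @param assignments data.frame with columns `read_id`, `movie`,
#'   `well`, `gap_id` (any stable gap key; unknown origins encoded as
#'   `NA` movie). Helper [origin_assignments()] builds this from read
#'   names.
#' @return list with `allowed` (subset of `assignments`) and
#'   `conflicts` (data.frame with columns `movie`, `well`, `read_ids`,
#'   `gap_ids`, `action`).
#' @export
check_conflicts <- function(assignments) {
  empty <- data.frame(movie = character(0), well = integer(0),
                      read_ids = character(0), gap_ids = character(0),
                      action = character(0))
  if (nrow(assignments) == 0L)
    return(list(allowed = assignments, conflicts = empty))
  known <- !is.na(assignments$movie)
  key <- ifelse(known,
                paste(assignments$movie, assignments$well, sep = "/"),
                NA_character_)
  kr <- which(!is.na(key))
  ngaps <- tapply(assignments$gap_id[kr], key[kr],
                  function(g) length(unique(g)))
  bad_keys <- names(ngaps)[ngaps > 1L]
  drop <- !is.na(key) & key %in% bad_keys
  conflicts <- do.call(rbind, lapply(bad_keys, function(k) {
    rows <- assignments[!is.na(key) & key == k, , drop = FALSE]
    data.frame(movie = rows$movie[1], well = rows$well[1],
               read_ids = paste(unique(rows$read_id), collapse = ","),
               gap_ids = paste(unique(rows$gap_id), collapse = ","),
               action = "aborted")
  }))
  if (is.null(conflicts)) conflicts <- empty
  list(allowed = assignments[!drop, , drop = FALSE], conflicts = conflicts)
}

#' Build an assignment table from read names
#'
#' @param read_ids character vector of read names.
#' @param gap_ids parallel vector of gap keys.
#' @return data.frame suitable for [check_conflicts()].
#' @export
origin_assignments <- function(read_ids, gap_ids) {
  stopifnot(length(read_ids) == length(gap_ids))
  origins <- lapply(read_ids, parse_read_name)
  data.frame(
    read_id = read_ids,
    movie = vapply(origins, function(o) o$movie, character(1)),
    well = vapply(origins, function(o) o$well, integer(1)),
    gap_id = gap_ids,
    stringsAsFactors = FALSE)
}
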