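# Directory-level operations over a folder of entry files.

entry_files <- function(dir) {
  if (!dir.exists(dir)) {
    abort_validation(sprintf("No such directory: %s", dir))
  }
  list.files(dir, pattern = "\\.(star|mdb|nef|txt)$", full.names = TRUE)
}

#' Validate every entry file in a directory
#'
#' Attempts to read each file; unreadable or schema-violating files are
#' listed with their error message rather than aborting the scan.
#'
#' @param dir Directory of entry files (`.star`/`.mdb`/`.nef`/`.txt`).
#' @return A tibble with `file`, `ok`, `error` (NA when ok).
#' @export
db_validate <- function(dir) {
  files <- entry_files(dir)
  purrr::map_dfr(files, function(f) {
    err <- NA_character_
    ok <- TRUE
    tryCatch(read_entry(f), error = function(e) {
      ok <<- FALSE
      err <<- conditionMessage(e)
    })
    tibble::tibble(file = basename(f), ok = ok, error = err)
  })
}

#' Content statistics of an entry directory
#'
#' Counts metabolites (distinct InChIs), synonyms, ontology terms,
#' concentrations, samples, spectra, multiplets and peaks over every
#' readable entry, the usual content-summary row categories of a
#' metabolite annotation database.
#'
#' @param dir Directory of entry files.
#' @return A one-row tibble of counts (plus `n_files_unreadable`).
#' @export
db_stats <- function(dir) {
  files <- entry_files(dir)
  entries <- list()
  bad <- 0L
  for (f in files) {
    e <- tryCatch(read_entry(f), error = function(e) NULL)
    if (is.null(e)) bad <- bad + 1L else entries <- c(entries, list(e))
  }
  tibble::tibble(
    metabolites = length(unique(vapply(entries, function(e)
      e$metabolite$inchi, character(1)))),
    synonyms = sum(vapply(entries, function(e) nrow(e$synonyms), integer(1))),
    ontology = sum(vapply(entries, function(e) nrow(e$ontology), integer(1))),
    concentrations = sum(vapply(entries, function(e)
      nrow(e$concentrations), integer(1))),
    samples = sum(vapply(entries, function(e) nrow(e$samples), integer(1))),
    spectra = sum(vapply(entries, function(e) nrow(e$spectra), integer(1))),
    multiplets = sum(vapply(entries, function(e)
      nrow(e$multiplets), integer(1))),
    peaks = sum(vapply(entries, function(e) nrow(e$peaks), integer(1))),
    n_files_unreadable = bad)
}

#' Deduplicate an entry directory by InChI
#'
#' Reads every entry, merges duplicates with [merge_by_inchi()], and
#' writes the merged set to `out_dir` (one file per surviving entry).
#'
#' @param dir Input directory.
#' @param out_dir Output directory (created if needed).
#' @return The list of merged entries, invisibly.
#' @export
db_merge <- function(dir, out_dir) {
  files <- entry_files(dir)
  entries <- purrr::map(files, read_entry)
  merged <- merge_by_inchi(entries)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (e in merged) {
    write_entry(e, file.path(out_dir,
                             paste0(e$metabolite$entry_id, ".mdb.star")))
  }
  invisible(merged)
}
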