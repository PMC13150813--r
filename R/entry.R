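# Relational per-metabolite entry model: one entry = one metabolite,
# with metadata tables (synonyms, ontology terms, typical
# concentrations), samples, spectra, and the annotation needed to
# recreate each spectrum (peaks + multiplets, and/or a spin system
# stored as multiplet shifts plus a coupling table). Accession policy:
# HMDB-style accessions are unambiguous per metabolite and live on the
# metabolite table; BMRB-style accessions are ambiguous at the
# metabolite level and live on the sample table.

entry_schema <- function() {
  list(
    metabolite = c(entry_id = "c", name = "c", inchi = "c", smiles = "c",
                   hmdb_accession = "c"),
    synonyms = c(name = "c"),
    ontology = c(term = "c"),
    concentrations = c(biofluid = "c", value = "n", units = "c"),
    samples = c(sample_id = "c", ph = "n", solvent = "c",
                reference_compound = "c", temperature_k = "n",
                source_db = "c", source_accession = "c"),
    spectra = c(spectrum_id = "c", sample_id = "c", spectrometer_mhz = "n",
                source_kind = "c", verified = "l"),
    multiplets = c(multiplet_id = "c", spectrum_id = "c", center_ppm = "n",
                   atom_assignment = "c"),
    peaks = c(peak_id = "c", spectrum_id = "c", multiplet_id = "c",
              position_ppm = "n", height = "n", width_hz = "n",
              width_placeholder = "l"),
    couplings = c(spectrum_id = "c", atom_1 = "c", atom_2 = "c", j_hz = "n"))
}

empty_table <- function(spec) {
  cols <- lapply(spec, function(t) {
    switch(t, c = character(), n = numeric(), l = logical())
  })
  tibble::as_tibble(cols)
}

coerce_table <- function(df, spec, table, context = "entry") {
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    abort_validation(sprintf("%s: table `%s` lacks column(s) %s.", context,
                             table, paste(missing, collapse = ", ")))
  }
  out <- df[names(spec)]
  for (col in names(spec)) {
    out[[col]] <- switch(spec[[col]],
      c = as.character(out[[col]]),
      n = as.numeric(out[[col]]),
      l = as.logical(out[[col]]))
  }
  tibble::as_tibble(out)
}

#' Create a metabolite database entry
#'
#' An entry bundles one metabolite (identified by its InChI, the key
#' used for deduplication across sources) with its metadata and the NMR
#' annotation data needed to recreate its spectra. All components are
#' plain tibbles, so the entry can be inspected and manipulated with
#' ordinary dplyr verbs; see `entry_schema` in the package sources for
#' the exact columns.
#'
#' @param entry_id Unique entry identifier (e.g. `"MDB000001"`).
#' @param inchi Non-empty InChI string identifying the metabolite.
#' @param name Primary metabolite name.
#' @param smiles,hmdb_accession Optional chemical identifiers
#'   (metabolite-level accession).
#' @param synonyms,ontology,concentrations,samples,spectra,multiplets,peaks,couplings
#'   Data frames matching the entry schema; omitted tables default to
#'   empty. `samples` rows own `spectra` rows via `sample_id`; peaks,
#'   multiplets and couplings attach to spectra via `spectrum_id`.
#' @return A validated object of class `metabolite_entry` (a named list
#'   of tibbles).
#' @export
metabolite_entry <- function(entry_id, inchi, name,
                             smiles = NA_character_,
                             hmdb_accession = NA_character_,
                             synonyms = NULL, ontology = NULL,
                             concentrations = NULL, samples = NULL,
                             spectra = NULL, multiplets = NULL,
                             peaks = NULL, couplings = NULL) {
  schema <- entry_schema()
  entry <- list(
    metabolite = tibble::tibble(entry_id = as.character(entry_id),
                                name = as.character(name),
                                inchi = as.character(inchi),
                                smiles = as.character(smiles),
                                hmdb_accession = as.character(hmdb_accession)),
    synonyms = synonyms %||% empty_table(schema$synonyms),
    ontology = ontology %||% empty_table(schema$ontology),
    concentrations = concentrations %||% empty_table(schema$concentrations),
    samples = samples %||% empty_table(schema$samples),
    spectra = spectra %||% empty_table(schema$spectra),
    multiplets = multiplets %||% empty_table(schema$multiplets),
    peaks = peaks %||% empty_table(schema$peaks),
    couplings = couplings %||% empty_table(schema$couplings))
  for (tab in names(schema)) {
    entry[[tab]] <- coerce_table(entry[[tab]], schema[[tab]], tab,
                                 context = entry$metabolite$entry_id[1])
  }
  class(entry) <- "metabolite_entry"
  validate_entry(entry)
  entry
}

#' Validate a metabolite entry
#'
#' Checks the relational invariants: a non-empty InChI; every spectrum
#' owned by exactly one existing sample; every peak/multiplet/coupling
#' row referencing an existing spectrum; multiplet references from peaks
#' resolving; each spectrum usable (it has peaks, or a spin system given
#' as atom-assigned multiplets).
#'
#' @param entry A `metabolite_entry`.
#' @return The entry, invisibly; otherwise a validation error naming the
#'   offending table and row.
#' @export
validate_entry <- function(entry) {
  if (!inherits(entry, "metabolite_entry")) {
    abort_validation("`entry` must be a metabolite_entry.")
  }
  m <- entry$metabolite
  if (nrow(m) != 1L) {
    abort_validation("Entry must have exactly one metabolite row.")
  }
  if (is.na(m$inchi) || !nzchar(m$inchi)) {
    abort_validation(sprintf("Entry %s: `inchi` must be non-empty.",
                             m$entry_id))
  }
  if (anyDuplicated(entry$samples$sample_id)) {
    abort_validation(sprintf("Entry %s: duplicate sample_id.", m$entry_id))
  }
  if (anyDuplicated(entry$spectra$spectrum_id)) {
    abort_validation(sprintf("Entry %s: duplicate spectrum_id.", m$entry_id))
  }
  bad <- which(!entry$spectra$sample_id %in% entry$samples$sample_id)
  if (length(bad)) {
    abort_validation(sprintf(
      "Entry %s: spectra table row %d references unknown sample `%s`.",
      m$entry_id, bad[1], entry$spectra$sample_id[bad[1]]))
  }
  for (tab in c("multiplets", "peaks", "couplings")) {
    bad <- which(!entry[[tab]]$spectrum_id %in% entry$spectra$spectrum_id)
    if (length(bad)) {
      abort_validation(sprintf(
        "Entry %s: %s table row %d references unknown spectrum `%s`.",
        m$entry_id, tab, bad[1], entry[[tab]]$spectrum_id[bad[1]]))
    }
  }
  pk <- entry$peaks
  has_mult <- !is.na(pk$multiplet_id)
  if (any(has_mult)) {
    key <- paste(pk$spectrum_id, pk$multiplet_id)[has_mult]
    known <- paste(entry$multiplets$spectrum_id, entry$multiplets$multiplet_id)
    bad <- which(!key %in% known)
    if (length(bad)) {
      abort_validation(sprintf(
        "Entry %s: peaks table row %d references unknown multiplet `%s`.",
        m$entry_id, which(has_mult)[bad[1]], key[bad[1]]))
    }
  }
  for (sp in entry$spectra$spectrum_id) {
    has_peaks <- any(pk$spectrum_id == sp)
    mm <- entry$multiplets[entry$multiplets$spectrum_id == sp, ]
    has_ss <- nrow(mm) > 0 && any(!is.na(mm$atom_assignment))
    if (!has_peaks && !has_ss) {
      abort_validation(sprintf(
        "Entry %s: spectrum `%s` has neither peaks nor a spin system.",
        m$entry_id, sp))
    }
  }
  cp <- entry$couplings
  if (nrow(cp)) {
    atoms <- entry$multiplets$atom_assignment
    bad <- which(!(cp$atom_1 %in% atoms) | !(cp$atom_2 %in% atoms))
    if (length(bad)) {
      abort_validation(sprintf(
        "Entry %s: couplings table row %d references unknown atom(s).",
        m$entry_id, bad[1]))
    }
  }
  invisible(entry)
}

#' @export
print.metabolite_entry <- function(x, ...) {
  m <- x$metabolite
  cat(sprintf("<metabolite_entry %s: %s>\n", m$entry_id, m$name))
  cat(sprintf("  inchi: %s\n", m$inchi))
  counts <- vapply(x[setdiff(names(x), "metabolite")], nrow, integer(1))
  cat("  ", paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Spin system stored in an entry spectrum
#'
#' Reconstructs the [spin_system()] of a spectrum from the entry's
#' multiplet table (one atom-assigned multiplet per proton carrying its
#' chemical shift) and coupling table.
#'
#' @param entry A `metabolite_entry`.
#' @param spectrum_id Spectrum to use; default the first with a spin
#'   system.
#' @return A [spin_system()], or an error when none is stored.
#' @export
entry_spin_system <- function(entry, spectrum_id = NULL) {
  validate_entry(entry)
  mm <- entry$multiplets[!is.na(entry$multiplets$atom_assignment), ]
  if (is.null(spectrum_id)) {
    if (!nrow(mm)) {
      abort_validation("Entry stores no spin system.")
    }
    spectrum_id <- mm$spectrum_id[1]
  }
  mm <- mm[mm$spectrum_id == spectrum_id, ]
  if (!nrow(mm)) {
    abort_validation(sprintf("Spectrum `%s` stores no spin system.",
                             spectrum_id))
  }
  atoms <- mm$atom_assignment
  J <- matrix(0, nrow(mm), nrow(mm), dimnames = list(atoms, atoms))
  cp <- entry$couplings[entry$couplings$spectrum_id == spectrum_id, ]
  for (k in seq_len(nrow(cp))) {
    J[cp$atom_1[k], cp$atom_2[k]] <- cp$j_hz[k]
    J[cp$atom_2[k], cp$atom_1[k]] <- cp$j_hz[k]
  }
  spin_system(mm$center_ppm, J, atom_labels = atoms,
              entry_ref = entry$metabolite$entry_id)
}

#' Peak list of an entry spectrum
#'
#' Returns the stored annotated peak list of a spectrum, or, for
#' spin-system-only spectra, simulates one by quantum mechanics at the
#' requested field.
#'
#' @inheritParams entry_spin_system
#' @param spectrometer_mhz Field for spin-system simulation; defaults to
#'   the spectrum's own recorded frequency.
#' @param default_width_hz Width given to simulated peaks (default 1 Hz,
#'   the placeholder convention).
#' @return A [peak_list()].
#' @export
entry_peak_list <- function(entry, spectrum_id = NULL,
                            spectrometer_mhz = NULL, default_width_hz = 1) {
  validate_entry(entry)
  if (is.null(spectrum_id)) {
    if (!nrow(entry$spectra)) {
      abort_validation("Entry has no spectra.")
    }
    spectrum_id <- entry$spectra$spectrum_id[1]
  }
  sp <- entry$spectra[entry$spectra$spectrum_id == spectrum_id, ]
  if (!nrow(sp)) {
    abort_validation(sprintf("Unknown spectrum `%s`.", spectrum_id))
  }
  pk <- entry$peaks[entry$peaks$spectrum_id == spectrum_id, ]
  if (nrow(pk)) {
    return(peak_list(pk$position_ppm, pk$height, pk$width_hz,
                     pk$multiplet_id, source_kind = "annotated",
                     provenance = entry$metabolite$entry_id))
  }
  ss <- entry_spin_system(entry, spectrum_id)
  simulate_peaks(ss, spectrometer_mhz %||% sp$spectrometer_mhz,
                 default_width_hz = default_width_hz)
}

#' Fill missing peak widths with a placeholder
#'
#' Sources often archive peak lists without line widths; rendering
#' requires one, so missing widths receive a placeholder (1 Hz by
#' convention) and are flagged `width_placeholder` so later width
#' remediation knows which values are real measurements.
#'
#' @param entry A `metabolite_entry`.
#' @param default_width_hz Placeholder width (default 1).
#' @return The entry with every previously-missing width filled and
#'   flagged.
#' @export
apply_placeholder_widths <- function(entry, default_width_hz = 1) {
  validate_entry(entry)
  stopifnot_scalar_number(default_width_hz, "default_width_hz",
                          positive = TRUE)
  missing <- is.na(entry$peaks$width_hz)
  entry$peaks$width_hz[missing] <- default_width_hz
  entry$peaks$width_placeholder[missing] <- TRUE
  entry$peaks$width_placeholder[is.na(entry$peaks$width_placeholder)] <- FALSE
  entry
}

#' Merge entries that share an InChI
#'
#' Entries are deduplicated on their InChI: groups sharing one are
#' merged into a single entry carrying the union of synonyms (including
#' the losing primary names), ontology terms, concentrations, samples
#' and all attached spectra/annotation. The first entry's identifier,
#' primary name and metabolite-level accession win; sample-level
#' accessions travel with their samples. Identifier collisions between
#' merged entries are resolved by prefixing with the source entry id.
#'
#' @param entries List of `metabolite_entry` objects, each with a
#'   non-empty InChI.
#' @return A list with one entry per distinct InChI, in first-seen
#'   order.
#' @export
merge_by_inchi <- function(entries) {
  if (!length(entries)) {
    return(entries)
  }
  purrr::walk(entries, validate_entry)
  keys <- vapply(entries, function(e) e$metabolite$inchi, character(1))
  out <- list()
  for (key in unique(keys)) {
    group <- entries[keys == key]
    out <- c(out, list(merge_entry_group(group)))
  }
  out
}

merge_entry_group <- function(group) {
  base <- group[[1]]
  if (length(group) == 1L) {
    return(base)
  }
  for (other in group[-1]) {
    other <- disambiguate_ids(other, base)
    # losing primary name and accession become synonyms / stay sample-level
    extra_syn <- setdiff(c(other$metabolite$name, other$synonyms$name),
                         c(base$metabolite$name, base$synonyms$name))
    base$synonyms <- dplyr::bind_rows(base$synonyms,
                                      tibble::tibble(name = extra_syn))
    if (is.na(base$metabolite$hmdb_accession) &&
        !is.na(other$metabolite$hmdb_accession)) {
      base$metabolite$hmdb_accession <- other$metabolite$hmdb_accession
    }
    if (is.na(base$metabolite$smiles) && !is.na(other$metabolite$smiles)) {
      base$metabolite$smiles <- other$metabolite$smiles
    }
    base$ontology <- dplyr::distinct(dplyr::bind_rows(base$ontology,
                                                      other$ontology))
    base$concentrations <- dplyr::distinct(
      dplyr::bind_rows(base$concentrations, other$concentrations))
    for (tab in c("samples", "spectra", "multiplets", "peaks", "couplings")) {
      base[[tab]] <- dplyr::bind_rows(base[[tab]], other[[tab]])
    }
  }
  base$synonyms <- dplyr::distinct(base$synonyms) %>%
    dplyr::arrange(.data$name)
  validate_entry(base)
  base
}

# Prefix sample/spectrum ids of `other` that collide with ids already in
# `base`, carrying the rename through all referencing tables.
disambiguate_ids <- function(other, base) {
  pre <- other$metabolite$entry_id
  clash_s <- intersect(other$samples$sample_id, base$samples$sample_id)
  if (length(clash_s)) {
    new <- paste0(pre, ":", clash_s)
    map <- stats::setNames(new, clash_s)
    hit <- other$samples$sample_id %in% clash_s
    other$samples$sample_id[hit] <- map[other$samples$sample_id[hit]]
    hit <- other$spectra$sample_id %in% clash_s
    other$spectra$sample_id[hit] <- map[other$spectra$sample_id[hit]]
  }
  clash_p <- intersect(other$spectra$spectrum_id, base$spectra$spectrum_id)
  if (length(clash_p)) {
    new <- paste0(pre, ":", clash_p)
    map <- stats::setNames(new, clash_p)
    for (tab in c("spectra", "multiplets", "peaks", "couplings")) {
      hit <- other[[tab]]$spectrum_id %in% clash_p
      other[[tab]]$spectrum_id[hit] <- map[other[[tab]]$spectrum_id[hit]]
    }
  }
  other
}

#' Accessions attached to an entry
#'
#' Gathers the metabolite-level and sample-level source accessions into
#' one tidy table.
#'
#' @param entry A `metabolite_entry`.
#' @return A tibble with `source` and `accession`.
#' @export
entry_accessions <- function(entry) {
  validate_entry(entry)
  rows <- tibble::tibble(source = "hmdb",
                         accession = entry$metabolite$hmdb_accession)
  samp <- entry$samples
  if (nrow(samp)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      source = samp$source_db, accession = samp$source_accession))
  }
  rows[!is.na(rows$accession), ]
}
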