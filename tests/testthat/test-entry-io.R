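minimal_entry <- function(id = "MDB000001",
                          inchi = "InChI=1S/C3H7NO2/c1-2(4)3(5)6/h2H,4H2,1H3,(H,5,6)") {
  metabolite_entry(
    entry_id = id, inchi = inchi, name = "test metabolite",
    hmdb_accession = "HMDB0000001",
    samples = tibble::tibble(sample_id = "S1", ph = NA_real_,
                             solvent = "D2O", reference_compound = "DSS",
                             temperature_k = 298, source_db = "bmrb",
                             source_accession = "bmse000001"),
    spectra = tibble::tibble(spectrum_id = "SP1", sample_id = "S1",
                             spectrometer_mhz = 600,
                             source_kind = "annotated", verified = FALSE),
    peaks = tibble::tibble(peak_id = "P1", spectrum_id = "SP1",
                           multiplet_id = NA_character_,
                           position_ppm = 1.23456789, height = 1,
                           width_hz = NA_real_, width_placeholder = NA))
}

test_that("a minimal entry round-trips losslessly", {
  e <- minimal_entry()
  path <- withr::local_tempfile(fileext = ".mdb.star")
  write_entry(e, path)
  back <- read_entry(path)
  expect_equal(back$metabolite, e$metabolite)
  expect_equal(back$samples, e$samples)
  expect_equal(back$spectra, e$spectra)
  expect_equal(back$peaks, e$peaks)
  # missing pH survives as an explicit null, never imputed
  expect_true(is.na(back$samples$ph))
})

test_that("a full synthetic entry round-trips with deep equality", {
  e <- make_entry(synthetic_spec(seed = 5, n_spins = 4))
  e$ontology <- tibble::tibble(term = c("organic acid", "carboxylic acid"))
  e$concentrations <- tibble::tibble(biofluid = "urine", value = 12.5,
                                     units = "uM")
  path <- withr::local_tempfile(fileext = ".mdb.star")
  write_entry(e, path)
  back <- read_entry(path)
  for (tab in names(unclass(e))) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(e[[tab]]),
                 tolerance = 1e-9, label = tab)
  }
  # the stored spin system reconstructs exactly
  ss <- entry_spin_system(back)
  ss0 <- entry_spin_system(e)
  expect_equal(ss$shifts_ppm, ss0$shifts_ppm, tolerance = 1e-9)
  expect_equal(ss$couplings_hz, ss0$couplings_hz, tolerance = 1e-9)
})

test_that("write-read stabilizes after one cycle over random entries", {
  for (seed in c(2, 13, 31)) {
    e <- make_entry(synthetic_spec(seed = seed, n_spins = 3))
    p1 <- withr::local_tempfile(fileext = ".star")
    p2 <- withr::local_tempfile(fileext = ".star")
    write_entry(e, p1)
    r1 <- read_entry(p1)
    write_entry(r1, p2)
    r2 <- read_entry(p2)
    expect_identical(r1, r2)
  }
})

test_that("schema violations raise typed errors naming the problem", {
  e <- minimal_entry()
  path <- withr::local_tempfile(fileext = ".star")
  write_entry(e, path)
  lines <- readLines(path)
  # remove the metabolite saveframe entirely
  start <- grep("^save_mdb_metabolite$", lines)
  stop_ <- grep("^save_$", lines)[1]
  writeLines(lines[-(start:stop_)], path)
  expect_error(read_entry(path), regexp = "mdb_metabolite",
               class = "spinmatch_error_parse")
  expect_error(read_entry(file.path(tempdir(), "nope.star")),
               class = "spinmatch_error_validation")

  # relational breakage is caught by validation
  bad <- minimal_entry()
  bad$peaks$spectrum_id <- "SPX"
  expect_error(validate_entry(bad), regexp = "SPX",
               class = "spinmatch_error_validation")
})

test_that("placeholder widths are applied and flagged exactly where missing", {
  e <- minimal_entry()
  e$peaks <- tibble::tibble(
    peak_id = c("P1", "P2", "P3"), spectrum_id = "SP1",
    multiplet_id = NA_character_, position_ppm = c(1, 2, 3),
    height = 1, width_hz = c(2.4, NA, NA),
    width_placeholder = c(FALSE, NA, NA))
  out <- apply_placeholder_widths(e)
  expect_equal(out$peaks$width_hz, c(2.4, 1, 1))
  expect_equal(out$peaks$width_placeholder, c(FALSE, TRUE, TRUE))
  # idempotent when everything is present
  again <- apply_placeholder_widths(out)
  expect_identical(again$peaks, out$peaks)
})

test_that("spin-matrix XML parses, symmetrizes and rejects conflicts", {
  xml <- paste0(
    "<spin_system>",
    "<spin index='2'><shift>2.00</shift></spin>",
    "<spin index='1' label='Ha'><shift>1.00</shift></spin>",
    "<coupling index1='1' index2='2'>7.0</coupling>",
    "</spin_system>")
  ss <- parse_spin_matrix_xml(xml)
  expect_equal(ss$shifts_ppm, c(1, 2))
  expect_equal(ss$atom_labels, c("Ha", "H2"))
  expect_equal(ss$couplings_hz[1, 2], 7)
  expect_equal(ss$couplings_hz[2, 1], 7) # mirrored from one triangle
  expect_equal(diag(ss$couplings_hz), c(Ha = 0, H2 = 0))

  dup_ok <- sub("</spin_system>",
                "<coupling index1='2' index2='1'>7.0</coupling></spin_system>",
                xml)
  expect_equal(parse_spin_matrix_xml(dup_ok)$couplings_hz[1, 2], 7)

  conflict <- sub("</spin_system>",
                  "<coupling index1='2' index2='1'>8.0</coupling></spin_system>",
                  xml)
  expect_error(parse_spin_matrix_xml(conflict), regexp = "conflict",
               class = "spinmatch_error_parse")
  expect_error(parse_spin_matrix_xml("<spin_system/>"),
               class = "spinmatch_error_parse")
  expect_error(
    parse_spin_matrix_xml("<spin_system><spin index='1'/></spin_system>"),
    class = "spinmatch_error_parse")
  expect_error(
    parse_spin_matrix_xml(
      "<spin_system><spin><shift>1</shift></spin></spin_system>"),
    regexp = "index", class = "spinmatch_error_parse")
})

test_that("entries merge by InChI with set-union bookkeeping", {
  a <- minimal_entry("MDB000001", "InChI=1S/shared")
  b <- minimal_entry("MDB000002", "InChI=1S/shared")
  b$metabolite$name <- "another name"
  merged <- merge_by_inchi(list(a, b))
  expect_length(merged, 1L)
  m <- merged[[1]]
  expect_equal(m$metabolite$entry_id, "MDB000001")
  expect_equal(nrow(m$samples), 2L)
  # colliding sample ids are disambiguated, spectra follow their samples
  expect_setequal(m$spectra$sample_id, m$samples$sample_id)
  expect_true("another name" %in% m$synonyms$name)

  # disjoint InChIs pass through unchanged
  c2 <- minimal_entry("MDB000003", "InChI=1S/other")
  expect_length(merge_by_inchi(list(a, c2)), 2L)

  # 5 entries over 3 InChIs -> 3 outputs; synonyms match brute-force union
  keys <- c("K1", "K1", "K2", "K3", "K2")
  entries <- lapply(seq_along(keys), function(k) {
    e <- minimal_entry(sprintf("MDB%06d", k),
                       paste0("InChI=1S/", keys[k]))
    e$metabolite$name <- paste0("name-", k)
    e$synonyms <- tibble::tibble(name = paste0("syn-", k))
    e
  })
  out <- merge_by_inchi(entries)
  expect_length(out, 3L)
  got_k1 <- out[[which(vapply(out, function(e)
    e$metabolite$inchi, character(1)) == "InChI=1S/K1")]]
  expect_setequal(got_k1$synonyms$name, c("syn-1", "syn-2", "name-2"))

  # idempotent and order-insensitive up to ordering of synonyms
  again <- merge_by_inchi(out)
  expect_equal(length(again), 3L)
  expect_identical(again[[1]]$synonyms, out[[1]]$synonyms)
  rev_out <- merge_by_inchi(rev(entries))
  counts <- function(es) sort(vapply(es, function(e) nrow(e$samples),
                                     integer(1)))
  expect_equal(counts(rev_out), counts(out))
})

test_that("referential integrity holds after any read", {
  for (seed in c(3, 17)) {
    e <- make_entry(synthetic_spec(seed = seed, n_spins = 4))
    path <- withr::local_tempfile(fileext = ".star")
    write_entry(e, path)
    back <- read_entry(path)
    expect_true(all(back$spectra$sample_id %in% back$samples$sample_id))
    key <- paste(back$peaks$spectrum_id, back$peaks$multiplet_id)
    known <- paste(back$multiplets$spectrum_id, back$multiplets$multiplet_id)
    expect_true(all(is.na(back$peaks$multiplet_id) | key %in% known))
  }
})

test_that("entry tables export as delimited text", {
  e <- minimal_entry()
  dir <- withr::local_tempdir()
  export_tables(e, dir)
  files <- list.files(dir)
  expect_true("MDB000001_peaks.tsv" %in% files)
  got <- utils::read.delim(file.path(dir, "MDB000001_peaks.tsv"))
  expect_equal(got$position_ppm, e$peaks$position_ppm)
})

test_that("accessions live at the documented levels", {
  e <- minimal_entry()
  acc <- entry_accessions(e)
  expect_true(all(c("hmdb", "bmrb") %in% acc$source))
  expect_equal(acc$accession[acc$source == "hmdb"], "HMDB0000001")
  expect_equal(acc$accession[acc$source == "bmrb"], "bmse000001")
})
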