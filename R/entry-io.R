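# STAR-syntax exchange dialect for metabolite entries.
#
# One UTF-8 text file per metabolite, in a documented subset of STAR
# syntax (the syntax family underlying NMR exchange formats): a single
# `data_<entry_id>` block containing one saveframe per relational table
# (`save_mdb_metabolite`, `save_mdb_samples`, ...). Scalar fields are
# `_frame.tag value` pairs; tables are `loop_` blocks with explicit
# `_frame.column` headers, rows of whitespace-separated values, and a
# closing `stop_`. The null token is `.`; values containing whitespace
# are quoted. Numbers are written at 12 significant digits so a write /
# read cycle is exact to well beyond 9 significant digits.

star_frame_names <- c(
  metabolite = "mdb_metabolite", synonyms = "mdb_synonyms",
  ontology = "mdb_ontology", concentrations = "mdb_concentrations",
  samples = "mdb_samples", spectra = "mdb_spectra",
  multiplets = "mdb_multiplets", peaks = "mdb_peaks",
  couplings = "mdb_couplings")

star_quote <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) {
      return(".")
    }
    v <- as.character(v)
    if (!nzchar(v)) {
      return("\"\"")
    }
    if (grepl("\n", v)) {
      abort_validation("Field values must not contain newlines.")
    }
    if (grepl("[ \t\"']", v) || substr(v, 1, 1) %in% c("_", "#", "$")) {
      if (grepl("\"", v)) paste0("'", v, "'") else paste0("\"", v, "\"")
    } else {
      v
    }
  }, character(1), USE.NAMES = FALSE)
}

star_cell <- function(x, type) {
  if (type == "n") {
    format_number(x)
  } else if (type == "l") {
    ifelse(is.na(x), ".", ifelse(x, "true", "false"))
  } else {
    star_quote(x)
  }
}

#' Write / read a metabolite entry file
#'
#' Serializes one entry to the package's STAR-syntax dialect (see the
#' format description in the package vignette) and reads it back
#' losslessly: every field round-trips bit-exactly for strings and to at
#' least 9 significant digits for numbers.
#'
#' @param entry A validated [metabolite_entry()].
#' @param path File path (conventionally `<entry_id>.mdb.star`).
#' @return `write_entry()` returns `path` invisibly; `read_entry()`
#'   returns a `metabolite_entry`. Malformed files raise typed parse or
#'   validation errors naming the offending saveframe.
#' @export
write_entry <- function(entry, path) {
  validate_entry(entry)
  schema <- entry_schema()
  frames <- star_frame_names
  lines <- c(sprintf("data_%s", entry$metabolite$entry_id), "")
  # metabolite saveframe: scalar tags
  m <- entry$metabolite
  lines <- c(lines, sprintf("save_%s", frames[["metabolite"]]),
             sprintf("   _%s.sf_category   %s", frames[["metabolite"]],
                     frames[["metabolite"]]))
  for (col in names(schema$metabolite)) {
    lines <- c(lines, sprintf("   _%s.%s   %s", frames[["metabolite"]], col,
                              star_cell(m[[col]], schema$metabolite[[col]])))
  }
  lines <- c(lines, "save_", "")
  # table saveframes: one loop each
  for (tab in setdiff(names(schema), "metabolite")) {
    frame <- frames[[tab]]
    spec <- schema[[tab]]
    df <- entry[[tab]]
    lines <- c(lines, sprintf("save_%s", frame),
               sprintf("   _%s.sf_category   %s", frame, frame),
               "   loop_",
               sprintf("      _%s.%s", frame, names(spec)))
    if (nrow(df)) {
      cells <- vapply(names(spec), function(col) {
        star_cell(df[[col]], spec[[col]])
      }, character(nrow(df)))
      cells <- matrix(cells, nrow = nrow(df))
      lines <- c(lines, paste0("      ",
                               apply(cells, 1, paste, collapse = " ")))
    }
    lines <- c(lines, "   stop_", "save_", "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

star_tokenize <- function(lines) {
  body <- sub("(^|\\s)#.*$", "", lines)
  pattern <- "'[^']*'|\"[^\"]*\"|\\S+"
  toks <- unlist(regmatches(body, gregexpr(pattern, body)))
  toks
}

star_unquote <- function(tok) {
  if (nchar(tok) >= 2 &&
      ((startsWith(tok, "'") && endsWith(tok, "'")) ||
       (startsWith(tok, "\"") && endsWith(tok, "\"")))) {
    substr(tok, 2, nchar(tok) - 1)
  } else {
    tok
  }
}

# Parse a STAR-subset document into list(data_name, frames), where each
# frame has $tags (named character) and $loops (list of character
# matrices with column names).
star_parse <- function(lines) {
  toks <- star_tokenize(lines)
  data_name <- NULL
  frames <- list()
  i <- 1L
  n <- length(toks)
  current <- NULL
  current_name <- NULL
  while (i <= n) {
    tok <- toks[i]
    if (startsWith(tok, "data_")) {
      data_name <- sub("^data_", "", tok)
      i <- i + 1L
    } else if (tok == "save_") {
      if (is.null(current_name)) {
        abort_parse("Unmatched `save_` terminator.")
      }
      frames[[current_name]] <- current
      current <- NULL
      current_name <- NULL
      i <- i + 1L
    } else if (startsWith(tok, "save_")) {
      current_name <- sub("^save_", "", tok)
      current <- list(tags = character(), loops = list())
      i <- i + 1L
    } else if (tok == "loop_") {
      if (is.null(current)) {
        abort_parse("`loop_` outside a saveframe.")
      }
      i <- i + 1L
      cols <- character()
      while (i <= n && startsWith(toks[i], "_")) {
        cols <- c(cols, sub("^_[^.]*\\.", "", toks[i]))
        i <- i + 1L
      }
      if (!length(cols)) {
        abort_parse(sprintf("Saveframe `%s`: loop_ without columns.",
                            current_name))
      }
      vals <- character()
      while (i <= n && !toks[i] %in% c("stop_", "save_", "loop_")) {
        vals <- c(vals, toks[i])
        i <- i + 1L
      }
      if (i > n || toks[i] != "stop_") {
        abort_parse(sprintf("Saveframe `%s`: loop_ not closed by stop_.",
                            current_name))
      }
      i <- i + 1L
      if (length(vals) %% length(cols) != 0L) {
        abort_parse(sprintf(
          "Saveframe `%s`: loop has %d values for %d columns.",
          current_name, length(vals), length(cols)))
      }
      mat <- matrix(vapply(vals, star_unquote, character(1),
                           USE.NAMES = FALSE),
                    ncol = length(cols), byrow = TRUE)
      colnames(mat) <- cols
      current$loops <- c(current$loops, list(mat))
    } else if (startsWith(tok, "_")) {
      if (is.null(current)) {
        abort_parse("Tag outside a saveframe.")
      }
      if (i + 1L > n) {
        abort_parse(sprintf("Tag `%s` has no value.", tok))
      }
      tag <- sub("^_[^.]*\\.", "", tok)
      current$tags[[tag]] <- star_unquote(toks[i + 1L])
      i <- i + 2L
    } else {
      abort_parse(sprintf("Unexpected token `%s`.", tok))
    }
  }
  if (!is.null(current_name)) {
    abort_parse(sprintf("Saveframe `%s` not terminated.", current_name))
  }
  list(data_name = data_name, frames = frames)
}

star_column <- function(values, type) {
  values[values == "."] <- NA
  if (type == "n") {
    out <- suppressWarnings(as.numeric(values))
    if (any(is.na(out) & !is.na(values))) {
      abort_parse(sprintf("Non-numeric value `%s` in a numeric column.",
                          values[which(is.na(out) & !is.na(values))[1]]))
    }
    out
  } else if (type == "l") {
    out <- rep(NA, length(values))
    out[values %in% c("true", "True", "1")] <- TRUE
    out[values %in% c("false", "False", "0")] <- FALSE
    out
  } else {
    as.character(values)
  }
}

#' @rdname write_entry
#' @export
read_entry <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("No such entry file: %s", path))
  }
  doc <- star_parse(readLines(path, encoding = "UTF-8"))
  schema <- entry_schema()
  frames <- star_frame_names
  mf <- doc$frames[[frames[["metabolite"]]]]
  if (is.null(mf)) {
    abort_parse(sprintf("File %s lacks the `%s` saveframe.", path,
                        frames[["metabolite"]]))
  }
  meta <- lapply(names(schema$metabolite), function(col) {
    v <- mf$tags[[col]]
    if (is.null(v)) {
      abort_parse(sprintf("Saveframe `%s` lacks tag `%s`.",
                          frames[["metabolite"]], col))
    }
    star_column(v, schema$metabolite[[col]])
  })
  names(meta) <- names(schema$metabolite)
  tables <- list()
  for (tab in setdiff(names(schema), "metabolite")) {
    fr <- doc$frames[[frames[[tab]]]]
    spec <- schema[[tab]]
    if (is.null(fr) || !length(fr$loops)) {
      tables[[tab]] <- empty_table(spec)
      next
    }
    mat <- fr$loops[[1]]
    missing <- setdiff(names(spec), colnames(mat))
    if (length(missing)) {
      abort_parse(sprintf("Saveframe `%s` loop lacks column(s) %s.",
                          frames[[tab]], paste(missing, collapse = ", ")))
    }
    cols <- lapply(names(spec), function(col) {
      star_column(mat[, col], spec[[col]])
    })
    names(cols) <- names(spec)
    tables[[tab]] <- tibble::as_tibble(cols)
  }
  metabolite_entry(
    entry_id = meta$entry_id, inchi = meta$inchi, name = meta$name,
    smiles = meta$smiles, hmdb_accession = meta$hmdb_accession,
    synonyms = tables$synonyms, ontology = tables$ontology,
    concentrations = tables$concentrations, samples = tables$samples,
    spectra = tables$spectra, multiplets = tables$multiplets,
    peaks = tables$peaks, couplings = tables$couplings)
}

#' Export the tables of an entry as delimited text
#'
#' Writes every relational table of the entry as a tab-separated file
#' `<entry_id>_<table>.tsv` under `dir`, for quick inspection with
#' ordinary tools.
#'
#' @param entry A `metabolite_entry`.
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
export_tables <- function(entry, dir) {
  validate_entry(entry)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- entry$metabolite$entry_id
  paths <- character()
  for (tab in names(entry)) {
    p <- file.path(dir, sprintf("%s_%s.tsv", id, tab))
    utils::write.table(entry[[tab]], p, sep = "\t", quote = TRUE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
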