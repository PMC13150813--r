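#' Parse a spin-matrix XML document
#'
#' Reads a spin system from spin-matrix XML as used by spin-system
#' libraries: a `<spin_system>` element holding one `<spin>` element per
#' proton (attributes `index` and optionally `label`, with the chemical
#' shift in ppm as a `<shift>` child or `shift` attribute) and one
#' `<coupling>` element per coupled pair (attributes `index1`/`index2`,
#' value in Hz). Couplings may be listed once per pair (either triangle);
#' the matrix is symmetrized. Duplicate couplings must agree.
#'
#' @param document XML text, a file path to an XML file, or an
#'   `xml_document`.
#' @param entry_ref Optional accession recorded on the result.
#' @return A [spin_system()].
#' @examples
#' xml <- paste0(
#'   "<spin_system>",
#'   "<spin index='1'><shift>1.00</shift></spin>",
#'   "<spin index='2'><shift>2.00</shift></spin>",
#'   "<coupling index1='1' index2='2'>7.0</coupling>",
#'   "</spin_system>")
#' parse_spin_matrix_xml(xml)
#' @export
parse_spin_matrix_xml <- function(document, entry_ref = NULL) {
  doc <- if (inherits(document, "xml_document")) {
    document
  } else if (length(document) == 1L && !grepl("<", document, fixed = TRUE) &&
             file.exists(document)) {
    xml2::read_xml(document)
  } else {
    tryCatch(xml2::read_xml(paste(document, collapse = "\n")),
             error = function(e) {
               abort_parse(sprintf("Malformed XML: %s", conditionMessage(e)))
             })
  }
  spins <- xml2::xml_find_all(doc, ".//spin")
  if (!length(spins)) {
    abort_parse("Document contains no <spin> elements.")
  }
  idx <- xml2::xml_attr(spins, "index")
  if (any(is.na(idx))) {
    abort_parse("<spin> element missing its `index` attribute.")
  }
  idx <- suppressWarnings(as.integer(idx))
  if (any(is.na(idx)) || anyDuplicated(idx)) {
    abort_parse("<spin> indices must be unique integers.")
  }
  shift_txt <- vapply(seq_along(spins), function(k) {
    child <- xml2::xml_find_first(spins[[k]], "./shift")
    if (!inherits(child, "xml_missing")) {
      xml2::xml_text(child)
    } else {
      xml2::xml_attr(spins[[k]], "shift")
    }
  }, character(1))
  shifts <- suppressWarnings(as.numeric(shift_txt))
  if (any(is.na(shifts))) {
    bad <- idx[which(is.na(shifts))[1]]
    abort_parse(sprintf("<spin index='%s'>: non-numeric or missing shift.",
                        bad))
  }
  labels <- xml2::xml_attr(spins, "label")
  labels[is.na(labels)] <- paste0("H", idx[is.na(labels)])
  ord <- order(idx)
  n <- length(idx)
  rank <- match(idx, sort(idx))

  J <- matrix(0, n, n)
  seen <- matrix(FALSE, n, n)
  couplings <- xml2::xml_find_all(doc, ".//coupling")
  for (cp in couplings) {
    i <- suppressWarnings(as.integer(xml2::xml_attr(cp, "index1")))
    j <- suppressWarnings(as.integer(xml2::xml_attr(cp, "index2")))
    if (is.na(i) || is.na(j)) {
      abort_parse("<coupling> element missing `index1`/`index2`.")
    }
    if (!(i %in% idx) || !(j %in% idx) || i == j) {
      abort_parse(sprintf("<coupling index1='%d' index2='%d'>: invalid pair.",
                          i, j))
    }
    val <- suppressWarnings(as.numeric(xml2::xml_text(cp)))
    if (is.na(val)) {
      val <- suppressWarnings(as.numeric(xml2::xml_attr(cp, "value")))
    }
    if (is.na(val)) {
      abort_parse(sprintf(
        "<coupling index1='%d' index2='%d'>: non-numeric value.", i, j))
    }
    a <- rank[match(i, idx)]
    b <- rank[match(j, idx)]
    if (seen[a, b] && abs(J[a, b] - val) > 1e-9) {
      abort_parse(sprintf(
        "<coupling index1='%d' index2='%d'>: conflicting duplicate (%g vs %g).",
        i, j, J[a, b], val))
    }
    J[a, b] <- val
    J[b, a] <- val
    seen[a, b] <- TRUE
    seen[b, a] <- TRUE
  }
  spin_system(shifts[ord], J, atom_labels = labels[ord],
              entry_ref = entry_ref)
}
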