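# CSV input/output for leaf records.
#
# A record table carries a sample id, exactly one pigment representation —
# raw meter readings (spad, aci) or transformed units (srs, lba) — and
# optionally CIELab columns for either or both surfaces (L_D, a_D, b_D for
# adaxial; L_B, a_B, b_B for abaxial) and observed CMQ coordinates
# (qL, qa, qb). Files are UTF-8, comma-separated, decimal point, header row
# mandatory.

SURFACE_COLS <- list(adaxial = c("L_D", "a_D", "b_D"),
                     abaxial = c("L_B", "a_B", "b_B"))

#' Read a leaf record CSV
#'
#' Reads and validates a record table. The pigment representation is
#' detected from the columns present: `spad`/`aci` (raw readings, converted
#' to SR-S / Lb-A on read) or `srs`/`lba` (already transformed). A file
#' carrying both representations is rejected as ambiguous. Surface color
#' columns must be complete per surface (all three coordinates or none).
#' Row-level problems (non-finite numbers, lightness outside [0, 100]) are
#' collected and reported together with their row numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @param pigments `"auto"` (detect, default), `"raw"`, or `"transformed"` —
#'   which representation the file must carry.
#' @return A data frame with `srs` and `lba` columns attached (plus the raw
#'   `spad`/`aci` columns when present) and any surface / CMQ columns
#'   validated.
#' @export
read_leaf_records <- function(path, pigments = c("auto", "raw", "transformed")) {
  pigments <- match.arg(pigments)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("no records in ", path)

  has_raw <- all(c("spad", "aci") %in% names(d))
  has_trn <- all(c("srs", "lba") %in% names(d))
  if ((has_raw && has_trn) ||
      any(c("spad", "aci") %in% names(d)) && any(c("srs", "lba") %in% names(d))) {
    stop("ambiguous pigment representation: file carries both raw (spad/aci) and transformed (srs/lba) columns")
  }
  if (pigments == "raw" && !has_raw) stop("expected raw pigment columns spad, aci")
  if (pigments == "transformed" && !has_trn) stop("expected transformed pigment columns srs, lba")
  if (!has_raw && !has_trn) {
    stop("no pigment columns found: need spad/aci or srs/lba")
  }

  errs <- character(0)
  note <- function(rows, what) {
    if (length(rows)) {
      errs <<- c(errs, sprintf("row %d: %s", rows, what))
    }
  }

  num_cols <- intersect(c("spad", "aci", "srs", "lba", "qL", "qa", "qb",
                          unlist(SURFACE_COLS)), names(d))
  for (cl in num_cols) {
    if (!is.numeric(d[[cl]])) {
      suppressWarnings(v <- as.numeric(d[[cl]]))
      note(which(is.na(v) & !is.na(d[[cl]]) & d[[cl]] != ""),
           paste0("unparseable value in column ", cl))
      d[[cl]] <- v
    }
    note(which(is.na(d[[cl]])), paste0("missing value in column ", cl))
  }

  for (surf in names(SURFACE_COLS)) {
    cols <- SURFACE_COLS[[surf]]
    present <- cols %in% names(d)
    if (any(present) && !all(present)) {
      stop(surf, " surface columns are incomplete: need all of ",
           paste(cols, collapse = ", "))
    }
    if (all(present)) {
      note(which(d[[cols[1]]] < 0 | d[[cols[1]]] > 100),
           paste0(cols[1], " outside [0, 100]"))
    }
  }
  if ("qL" %in% names(d)) note(which(d$qL < 0 | d$qL > 100), "qL outside [0, 100]")
  if (has_raw) {
    note(which(d$spad < 0), "spad must be non-negative")
    note(which(d$aci <= 0), "aci must be strictly positive")
  }
  if (length(errs)) {
    stop("invalid records in ", path, ":\n  ", paste(errs, collapse = "\n  "))
  }

  if (has_raw) {
    d$srs <- spad_to_srs(d$spad)
    d$lba <- suppressWarnings(aci_to_lba(d$aci))
  }
  d
}

#' Write a leaf record CSV
#'
#' Writes records at full precision, UTF-8, comma-separated, with a header
#' row. Reading the file back with [read_leaf_records()] recovers the same
#' records (up to column order).
#'
#' @param records A data frame of leaf records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_leaf_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
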