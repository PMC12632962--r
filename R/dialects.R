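# Export dialects understood by the converter.  Vendors change export
# headers between versions, so each dialect is configuration -- a column
# map plus capability flags -- rather than hard-coded parsing logic.  The
# maps below document one widely seen layout per program (version noted);
# a user facing a different export can rename columns to match.
#
# Capabilities:
#   carries_uptake  - the export reports deuterium uptake directly; when
#                     FALSE uptake is recomputed from centroids using the
#                     zero-timepoint replicate-averaging rule.
#   carries_ptms    - the export annotates modifications.
#   carries_spectra - the export can include full isotopic envelopes.

.HXMS_DIALECTS <- list(
  dynamx = list(
    label = "DynamX state data (v3.0-style CSV)",
    carries_uptake = TRUE, carries_ptms = TRUE, carries_spectra = FALSE,
    time_unit = "min", fd_labels = c("MAX", "FD"),
    columns = c(start = "Start", end = "End", sequence = "Sequence",
                modification = "Modification", state = "State",
                time = "Exposure", replicate = "File", uptake = "Uptake")
  ),
  biopharma = list(
    label = "BioPharma Finder peptide results (v5-style CSV)",
    carries_uptake = TRUE, carries_ptms = FALSE, carries_spectra = FALSE,
    time_unit = "sec", fd_labels = c("FD", "Full-D"),
    columns = c(start = "Start", end = "End", sequence = "Sequence",
                state = "Protein State", time = "Exposure Time (s)",
                uptake = "D Uptake (Da)")
  ),
  workbench = list(
    label = "HDX Workbench peptide export (CSV)",
    carries_uptake = FALSE, carries_ptms = TRUE, carries_spectra = TRUE,
    time_unit = "sec", fd_labels = c("FD", "inf"),
    columns = c(start = "Start", end = "End", sequence = "Peptide",
                modification = "Modification", state = "Sample",
                time = "Timepoint", replicate = "Replicate",
                mod = "Population", centroid = "Centroid",
                envelope = "Envelope")
  ),
  hdexaminer = list(
    label = "HDExaminer peptide pool export (CSV)",
    carries_uptake = FALSE, carries_ptms = FALSE, carries_spectra = TRUE,
    time_unit = "sec", fd_labels = c("Full-D", "FD"),
    columns = c(start = "Start", end = "End", sequence = "Sequence",
                state = "Protein State", time = "Deut Time",
                replicate = "File", mod = "Population",
                envelope = "Envelope")
  ),
  custom = list(
    label = "self-contained custom CSV (metadata block + data block)",
    carries_uptake = TRUE, carries_ptms = TRUE, carries_spectra = TRUE,
    time_unit = "sec", fd_labels = c("inf", "Full-D", "FD"),
    columns = c(start = "START", end = "END", sequence = "SEQUENCE",
                mod = "MOD", rep = "REP", modification = "PTM_CONTENT",
                time = "TIME(SEC)", uptake = "UPTAKE",
                envelope = "ENVELOPE")
  )
)

#' Supported input dialects
#'
#' One row per supported HX/MS export dialect with its capability flags:
#' whether the export reports uptake directly (otherwise it is recomputed
#' from centroids), whether it annotates PTMs, and whether it can carry
#' full isotopic mass envelopes.
#'
#' @return A data frame with columns `name`, `label`, `carries_uptake`,
#'   `carries_ptms`, `carries_spectra`, `time_unit`.
#' @export
hxms_dialects <- function() {
  data.frame(
    name = names(.HXMS_DIALECTS),
    label = vapply(.HXMS_DIALECTS, `[[`, character(1), "label"),
    carries_uptake = vapply(.HXMS_DIALECTS, `[[`, logical(1),
                            "carries_uptake"),
    carries_ptms = vapply(.HXMS_DIALECTS, `[[`, logical(1), "carries_ptms"),
    carries_spectra = vapply(.HXMS_DIALECTS, `[[`, logical(1),
                             "carries_spectra"),
    time_unit = vapply(.HXMS_DIALECTS, `[[`, character(1), "time_unit"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

dialect_spec <- function(name) {
  if (!name %in% names(.HXMS_DIALECTS))
    stop(errorCondition(
      paste0("unknown dialect \"", name, "\"; supported: ",
             paste(names(.HXMS_DIALECTS), collapse = ", ")),
      class = c("hxms_schema_error", "error", "condition")))
  c(list(name = name), .HXMS_DIALECTS[[name]])
}

schema_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("hxms_schema_error", "error", "condition")))
}

# Read tabular text (path or inline text), auto-detecting comma vs tab
# separation from the header line and tolerating a UTF-8 BOM.
read_table_auto <- function(input, skip = 0L) {
  lines <- if (grepl("\n", input, fixed = TRUE)) {
    strsplit(input, "\r?\n")[[1]]
  } else {
    readLines(input, warn = FALSE)
  }
  if (length(lines) > 0L)
    lines[1] <- sub("^\\ufeff", "", lines[1])
  if (skip > 0L) lines <- lines[-seq_len(skip)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) schema_error("input contains no header row")
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                    header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    stringsAsFactors = FALSE)
}

parse_envelope_cell <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell)) return(NULL)
  as.numeric(strsplit(cell, ",", fixed = TRUE)[[1]])
}

parse_cell_num <- function(cells, column) {
  out <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(out) & nzchar(trimws(cells)))
  if (length(bad) > 0L)
    schema_error("column \"", column, "\", row ", bad[1],
                 ": cannot parse numeric cell \"", cells[bad[1]], "\"")
  out
}

# Map a replicate-identifier column to 0-based replicate numbers.  Integer
# identifiers are used as-is; other identifiers (run/file names) are
# numbered by first appearance.
map_replicates <- function(ids) {
  ints <- suppressWarnings(as.integer(ids))
  if (!anyNA(ints) && all(ints == as.numeric(ids))) return(ints)
  match(ids, unique(ids)) - 1L
}

#' Parse an HX/MS export into normalized rows
#'
#' Reads one of the supported export dialects (see [hxms_dialects()]) and
#' maps its columns to a normalized row model.  Times reported in minutes
#' by a dialect are converted to seconds; fully deuterated labels (e.g.
#' `"MAX"`, `"Full-D"`) become `Inf`.  Replicates are taken from the
#' dialect's run/file identifier column when it has one; otherwise rows of
#' each (peptide, state, time) group are numbered in input order and a
#' warning is raised.
#'
#' @param name Dialect name, one of `hxms_dialects()$name`.
#' @param input Path to the export file, or its text (string containing a
#'   newline).
#' @return A data frame with columns `start`, `end`, `sequence`, `state`,
#'   `mod`, `rep`, `time_sec`, `uptake`, `centroid`, `modification` and the
#'   list column `envelope` (`NULL` entries when absent).
#' @export
parse_dialect <- function(name, input) {
  sp <- dialect_spec(name)
  tab <- read_table_auto(input)
  missing_cols <- setdiff(unname(sp$columns), names(tab))
  if (length(missing_cols) > 0L)
    schema_error("dialect \"", name, "\": input is missing required ",
                 "column(s) ", paste0("\"", missing_cols, "\"",
                                      collapse = ", "),
                 "; expected header: ",
                 paste(sp$columns, collapse = ", "))
  if (nrow(tab) == 0L)
    schema_error("dialect \"", name, "\": no data rows after the header")

  col <- function(key) {
    if (key %in% names(sp$columns)) tab[[sp$columns[[key]]]] else NULL
  }
  n <- nrow(tab)

  time_raw <- trimws(col("time"))
  is_fd <- tolower(time_raw) %in% tolower(sp$fd_labels)
  time_num <- rep(NA_real_, n)
  time_num[!is_fd] <- parse_cell_num(time_raw[!is_fd], sp$columns[["time"]])
  if (sp$time_unit == "min") time_num <- time_num * 60
  time_num[is_fd] <- Inf

  state <- col("state")
  if (is.null(state)) state <- rep("", n)

  rep_ids <- col("replicate")
  rep_col <- col("rep")
  if (!is.null(rep_col)) {
    reps <- as.integer(parse_cell_num(rep_col, sp$columns[["rep"]]))
  } else if (!is.null(rep_ids)) {
    reps <- map_replicates(rep_ids)
  } else {
    reps <- rep(NA_integer_, n)   # numbered per group below
  }

  mod <- col("mod")
  if (is.null(mod)) mod <- rep("A", n)
  mod <- toupper(trimws(mod))
  mod[!nzchar(mod)] <- "A"

  modification <- col("modification")
  if (is.null(modification) || !sp$carries_ptms)
    modification <- rep("", n)
  modification <- trimws(modification)

  uptake <- if (!is.null(col("uptake"))) {
    parse_cell_num(col("uptake"), sp$columns[["uptake"]])
  } else rep(NA_real_, n)
  centroid <- if (!is.null(col("centroid"))) {
    parse_cell_num(col("centroid"), sp$columns[["centroid"]])
  } else rep(NA_real_, n)
  envelope <- if (!is.null(col("envelope"))) {
    lapply(col("envelope"), parse_envelope_cell)
  } else rep(list(NULL), n)

  rows <- data.frame(
    start = as.integer(parse_cell_num(col("start"), sp$columns[["start"]])),
    end = as.integer(parse_cell_num(col("end"), sp$columns[["end"]])),
    sequence = trimws(col("sequence")),
    state = trimws(state),
    mod = mod,
    rep = reps,
    time_sec = time_num,
    uptake = uptake,
    centroid = centroid,
    modification = modification,
    stringsAsFactors = FALSE
  )
  rows$envelope <- envelope

  if (anyNA(rows$rep)) {
    warning("dialect \"", name, "\" has no replicate identifier column; ",
            "numbering rows of each (peptide, state, time) group in ",
            "input order", call. = FALSE)
    grp <- paste(rows$start, rows$end, rows$state, rows$mod, rows$time_sec,
                 rows$modification)
    rows$rep <- stats::ave(seq_len(n), grp,
                           FUN = function(i) seq_along(i) - 1L)
    rows$rep <- as.integer(rows$rep)
  }
  rows
}

# Required-metadata keys accepted in the custom CSV metadata block, mapped
# to metadata field names.  Both the file-format titles and plain
# underscore spellings are accepted.
.CUSTOM_META_KEYS <- c(
  "PROTEIN_SEQUENCE" = "protein_sequence",
  "PROTEIN_NAME" = "protein_name",
  "PROTEIN_STATE" = "protein_state",
  "TEMPERATURE (K)" = "temperature_k",
  "TEMPERATURE_K" = "temperature_k",
  "pH(READ)" = "ph_read",
  "PH_READ" = "ph_read",
  "D2O_SATURATION" = "d2o_saturation"
)

#' Read the self-contained custom CSV layout
#'
#' The custom layout embeds the experimental metadata so that no separate
#' metadata input is needed: a block of `KEY,VALUE` rows (the metadata
#' titles, e.g. `D2O_SATURATION,0.91`) followed by a data block whose
#' header mirrors the record fields plus `SEQUENCE` and optional
#' `PTM_CONTENT` and `ENVELOPE` columns.
#'
#' @param input Path to the CSV, or its text.
#' @return A list of class `hxms_conversion_request` with elements
#'   `dialect` (`"custom"`), `metadata` (an [hxms_metadata()]) and `rows`
#'   (normalized rows as from [parse_dialect()]).
#' @export
read_custom_csv <- function(input) {
  lines <- if (grepl("\n", input, fixed = TRUE)) {
    strsplit(input, "\r?\n")[[1]]
  } else {
    readLines(input, warn = FALSE)
  }
  if (length(lines) > 0L) lines[1] <- sub("^\\ufeff", "", lines[1])
  header_at <- grep("^\"?START\"?,", lines)
  if (length(header_at) == 0L)
    schema_error("custom CSV: no data header starting with \"START\" found")
  header_at <- header_at[1]

  meta_kv <- list()
  remarks_title <- character(); remarks_body <- character()
  for (line in lines[seq_len(header_at - 1L)]) {
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    parts <- utils::read.table(text = line, sep = ",", header = FALSE,
                               colClasses = "character", quote = "\"",
                               stringsAsFactors = FALSE)
    key <- trimws(parts[[1]][1])
    value <- if (ncol(parts) >= 2L) trimws(parts[[2]][1]) else ""
    if (toupper(key) %in% toupper(names(.CUSTOM_META_KEYS))) {
      fld <- .CUSTOM_META_KEYS[[match(toupper(key),
                                      toupper(names(.CUSTOM_META_KEYS)))]]
      meta_kv[[fld]] <- value
    } else {
      remarks_title <- c(remarks_title, key)
      remarks_body <- c(remarks_body, value)
    }
  }
  missing_req <- setdiff(.META_REQUIRED, names(meta_kv))
  if (length(missing_req) > 0L)
    schema_error("custom CSV: missing required metadata key(s): ",
                 paste(.META_TITLES[missing_req], collapse = ", "),
                 " (required set: ",
                 paste(.META_TITLES[.META_REQUIRED], collapse = ", "), ")")

  num <- function(fld) {
    if (fld %in% names(meta_kv))
      suppressWarnings(as.numeric(meta_kv[[fld]])) else NA_real_
  }
  metadata <- hxms_metadata(
    protein_sequence = meta_kv[["protein_sequence"]],
    temperature_k = num("temperature_k"),
    ph_read = num("ph_read"),
    d2o_saturation = num("d2o_saturation"),
    protein_name = meta_kv[["protein_name"]],
    protein_state = meta_kv[["protein_state"]],
    remarks = if (length(remarks_title) > 0L)
      data.frame(title = remarks_title, body = remarks_body,
                 stringsAsFactors = FALSE) else NULL,
    .raw = unlist(meta_kv[intersect(names(meta_kv), names(.META_TITLES))])
  )

  rows <- parse_dialect("custom",
                        paste(c(lines[header_at:length(lines)], ""),
                              collapse = "\n"))
  structure(list(dialect = "custom", metadata = metadata, rows = rows),
            class = "hxms_conversion_request")
}
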