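#' @keywords internal
"_PACKAGE"

# One-letter amino-acid alphabet accepted in PROTEIN_SEQUENCE ("X" = unknown).
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

# File-format titles of the four required metadata fields, keyed by the
# R-side field name.  The titles are what appears on METADATA lines.
.META_TITLES <- c(
  protein_sequence = "PROTEIN_SEQUENCE",
  protein_name     = "PROTEIN_NAME",
  protein_state    = "PROTEIN_STATE",
  temperature_k    = "TEMPERATURE (K)",
  ph_read          = "pH(READ)",
  d2o_saturation   = "D2O_SATURATION"
)
.META_REQUIRED <- c("protein_sequence", "temperature_k", "ph_read",
                    "d2o_saturation")

# Canonical text rendering of a metadata value.  Numbers are rendered with
# as.character() so that e.g. 293.15 prints as "293.15"; strings pass
# through.  Readers keep the original file text instead (see $raw), so a
# read -> write cycle is byte-stable even for spellings like "6.0".
format_meta_value <- function(x) {
  if (is.character(x)) x else as.character(x)
}

#' Experimental metadata for an HXMS document
#'
#' Collects the experimental conditions stored in the metadata section of an
#' HXMS file: the protein sequence (one-letter codes), the labeling
#' temperature in Kelvin, the uncorrected pH-meter reading of the deuterated
#' buffer (pH read), and the D2O saturation of the labeling buffer as a
#' fraction in (0, 1].  These four are required before a file can be
#' written; name and state are optional labels, and free-form remarks are
#' carried as (title, body) pairs.
#'
#' Missing required values may be left `NA` while assembling a document;
#' [hxms_validate()] reports them and [write_hxms()] refuses to serialize
#' until they are supplied.
#'
#' @param protein_sequence Character scalar of one-letter amino-acid codes
#'   (the 20 standard codes plus `X`).
#' @param temperature_k Labeling temperature in Kelvin (> 0).
#' @param ph_read Uncorrected pH-meter reading of the labeling buffer.
#' @param d2o_saturation Deuterium fraction of the labeling buffer, in
#'   (0, 1].
#' @param protein_name,protein_state Optional free-text labels (e.g. state
#'   `"APO"`).
#' @param remarks A data frame with columns `title` and `body`, one row per
#'   REMARK line, or `NULL`.
#' @param .raw Named character vector of verbatim value strings, keyed by
#'   field name; used by the reader to preserve the original spelling of
#'   numeric values (e.g. `"6.0"`).  Normally left `NULL`.
#' @return An object of class `hxms_metadata`.
#' @examples
#' hxms_metadata("GSHMKTVEVNGADASDDN", temperature_k = 293.15,
#'               ph_read = 6.0, d2o_saturation = 0.91)
#' @export
hxms_metadata <- function(protein_sequence,
                          temperature_k = NA_real_,
                          ph_read = NA_real_,
                          d2o_saturation = NA_real_,
                          protein_name = NULL,
                          protein_state = NULL,
                          remarks = NULL,
                          .raw = NULL) {
  if (is.null(remarks)) {
    remarks <- data.frame(title = character(), body = character(),
                          stringsAsFactors = FALSE)
  } else {
    remarks <- data.frame(title = as.character(remarks$title),
                          body = as.character(remarks$body),
                          stringsAsFactors = FALSE)
  }
  md <- structure(
    list(
      protein_sequence = if (is.null(protein_sequence)) NA_character_
                         else as.character(protein_sequence),
      protein_name   = if (is.null(protein_name)) NA_character_
                       else as.character(protein_name),
      protein_state  = if (is.null(protein_state)) NA_character_
                       else as.character(protein_state),
      temperature_k  = as.numeric(temperature_k),
      ph_read        = as.numeric(ph_read),
      d2o_saturation = as.numeric(d2o_saturation),
      remarks        = remarks,
      raw            = character()
    ),
    class = "hxms_metadata"
  )
  raw <- character()
  for (fld in names(.META_TITLES)) {
    v <- md[[fld]]
    if (length(v) == 1L && !is.na(v)) raw[[fld]] <- format_meta_value(v)
  }
  if (!is.null(.raw)) raw[names(.raw)] <- .raw
  md$raw <- raw
  md
}

#' Build a table of HXMS timepoint records
#'
#' Each row is one TP line of the experimental-data section: a peptide span
#' (`start`..`end`, 1-based, inclusive of both ends), a distribution label
#' `mod` (`"A"` for a unimodal peptide, `"B"`, ... for additional modes of a
#' bimodal envelope), a replicate number (`0` for a single replicate), a
#' 4-digit PTM identifier (`"0000"` meaning unmodified), the D2O incubation
#' time in seconds (`Inf` for the fully deuterated control), the deuterium
#' uptake in Daltons relative to the 0 s timepoint, and optionally the full
#' isotopic mass envelope as a numeric vector of unit-sum peak intensities.
#'
#' @param start,end Peptide first and last residue positions (1-based,
#'   inclusive).
#' @param time_sec Incubation time in seconds; `Inf` marks the fully
#'   deuterated control.
#' @param uptake Deuterium uptake in Daltons relative to the 0 s timepoint.
#' @param mod Single uppercase distribution label, default `"A"`.
#' @param rep Replicate number, default `0`.
#' @param ptm_id 4-digit zero-padded PTM identifier, default `"0000"`.
#' @param envelope `NULL` for a centroid-only table, or a list with one
#'   numeric vector (or `NULL`) per record.
#' @param index Record serial numbers; defaults to `0, 1, 2, ...` in row
#'   order, which is what a valid file must contain.
#' @return A data frame with columns `index`, `mod`, `start`, `end`, `rep`,
#'   `ptm_id`, `time_sec`, `uptake` and the list column `envelope`.
#' @examples
#' hxms_records(start = 1, end = 10, time_sec = c(0, 60), uptake = c(0, 1.35))
#' @export
hxms_records <- function(start, end, time_sec, uptake,
                         mod = "A", rep = 0L, ptm_id = "0000",
                         envelope = NULL, index = NULL) {
  n <- max(length(start), length(end), length(time_sec), length(uptake))
  if (is.null(index)) index <- seq_len(n) - 1L
  df <- data.frame(
    index    = as.integer(index),
    mod      = rep_len(as.character(mod), n),
    start    = rep_len(as.integer(start), n),
    end      = rep_len(as.integer(end), n),
    rep      = rep_len(as.integer(rep), n),
    ptm_id   = rep_len(as.character(ptm_id), n),
    time_sec = rep_len(as.numeric(time_sec), n),
    uptake   = rep_len(as.numeric(uptake), n),
    stringsAsFactors = FALSE
  )
  if (is.null(envelope)) {
    df$envelope <- rep(list(NULL), n)
  } else {
    stopifnot(is.list(envelope), length(envelope) == n)
    df$envelope <- lapply(envelope, function(e) if (is.null(e)) NULL
                                                else as.numeric(e))
  }
  df
}

# Normalize a PTM dictionary to a named character vector (ptm_id -> content).
as_ptm_dict <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character())
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

#' Assemble an HXMS document
#'
#' An HXMS document has three sections, serialized in this order: the
#' experimental metadata, the timepoint records, and the PTM dictionary that
#' resolves each non-`"0000"` `ptm_id` to a textual description of the
#' modification (e.g. `"Phosphoryl STY (18)"`).
#'
#' A document is either centroid-level (no record carries an envelope) or
#' full-spectrum (every record does); mixed documents fail validation.
#'
#' @param metadata An [hxms_metadata()] object.
#' @param records A record table from [hxms_records()] (may have zero rows).
#' @param ptm_dict Named character vector mapping 4-digit PTM identifiers to
#'   descriptions; `"0000"` must not appear (it means "no PTM").
#' @return An object of class `hxms_file`.
#' @seealso [hxms_validate()], [read_hxms()], [write_hxms()]
#' @export
hxms_file <- function(metadata, records = hxms_records(
                        integer(), integer(), numeric(), numeric()),
                      ptm_dict = character()) {
  stopifnot(inherits(metadata, "hxms_metadata"), is.data.frame(records))
  structure(
    list(metadata = metadata, records = records,
         ptm_dict = as_ptm_dict(ptm_dict)),
    class = "hxms_file"
  )
}

#' Is a document full-spectrum?
#'
#' @param file An `hxms_file`.
#' @return `TRUE` if every record carries an envelope, `FALSE` if none does,
#'   `NA` for a mixed (invalid) document or an empty record table.
#' @export
hxms_is_full_spectrum <- function(file) {
  has <- !vapply(file$records$envelope, is.null, logical(1))
  if (length(has) == 0L) return(NA)
  if (all(has)) TRUE else if (!any(has)) FALSE else NA
}

# -- validation ---------------------------------------------------------------

new_violation <- function(severity, locator, message) {
  data.frame(severity = severity, locator = locator, message = message,
             stringsAsFactors = FALSE)
}

#' Validate an HXMS document
#'
#' Checks every structural invariant of the format and returns a report
#' rather than throwing: required metadata present and in range, sequence
#' alphabet, record spans inside the protein sequence, single-letter mode
#' labels, 4-digit PTM identifiers resolving in the dictionary, record
#' indices running 0, 1, 2, ... in file order, envelope non-negativity and
#' unit sum, and the centroid-vs-full-spectrum consistency of the whole
#' document.  Problems that break an invariant are `ERROR`s; suspicious but
#' legal situations (duplicate record keys, an envelope whose sum is off by
#' more than 1e-3 but at most 1e-2) are `WARNING`s.
#'
#' @param file An `hxms_file`.
#' @return A data frame of class `hxms_validation_report` with columns
#'   `severity` (`"ERROR"` or `"WARNING"`), `locator` (section or record
#'   position) and `message`, ordered by record position.  Zero rows means
#'   the document is valid.
#' @examples
#' md <- hxms_metadata("GSHMKTVEVNGADASDDN", 293.15, 6.0, 0.91)
#' f <- hxms_file(md, hxms_records(1, 10, c(0, 60), c(0, 1.35)))
#' hxms_validate(f)
#' @export
hxms_validate <- function(file) {
  stopifnot(inherits(file, "hxms_file"))
  md <- file$metadata
  rec <- file$records
  out <- list()
  add <- function(severity, locator, message) {
    out[[length(out) + 1L]] <<- new_violation(severity, locator, message)
  }

  # metadata
  for (fld in .META_REQUIRED) {
    v <- md[[fld]]
    if (length(v) != 1L || is.na(v)) {
      add("ERROR", "metadata",
          paste0("required metadata missing: ", .META_TITLES[[fld]]))
    }
  }
  seq_ok <- length(md$protein_sequence) == 1L && !is.na(md$protein_sequence)
  if (seq_ok) {
    if (!nzchar(md$protein_sequence)) {
      add("ERROR", "metadata", "PROTEIN_SEQUENCE is empty")
      seq_ok <- FALSE
    } else {
      bad <- setdiff(strsplit(md$protein_sequence, "")[[1]], .AA_ALPHABET)
      if (length(bad) > 0L) {
        add("ERROR", "metadata",
            paste0("PROTEIN_SEQUENCE contains illegal characters: ",
                   paste(unique(bad), collapse = ", ")))
        seq_ok <- FALSE
      }
    }
  }
  if (!is.na(md$temperature_k) && md$temperature_k <= 0)
    add("ERROR", "metadata", "TEMPERATURE (K) must be positive")
  if (!is.na(md$d2o_saturation) &&
      (md$d2o_saturation <= 0 || md$d2o_saturation > 1))
    add("ERROR", "metadata", "D2O_SATURATION must lie in (0, 1]")

  # records, in file order
  n_seq <- if (seq_ok) nchar(md$protein_sequence) else NA_integer_
  has_env <- !vapply(rec$envelope, is.null, logical(1))
  for (i in seq_len(nrow(rec))) {
    loc <- paste0("record ", i, " (INDEX ", rec$index[i], ")")
    if (rec$index[i] != i - 1L)
      add("ERROR", loc, paste0("INDEX must increase by 1 from 0; expected ",
                               i - 1L, ", found ", rec$index[i]))
    if (is.na(rec$start[i]) || is.na(rec$end[i]) ||
        rec$start[i] < 1L || rec$start[i] > rec$end[i]) {
      add("ERROR", loc, paste0("invalid span START=", rec$start[i],
                               " END=", rec$end[i]))
    } else if (!is.na(n_seq) && rec$end[i] > n_seq) {
      add("ERROR", loc, paste0("END=", rec$end[i],
                               " exceeds protein sequence length ", n_seq))
    }
    if (!grepl("^[A-Z]$", rec$mod[i]))
      add("ERROR", loc, paste0("MOD must be a single letter A-Z, found \"",
                               rec$mod[i], "\""))
    if (is.na(rec$rep[i]) || rec$rep[i] < 0L)
      add("ERROR", loc, "REP must be a non-negative integer")
    if (!grepl("^[0-9]{4}$", rec$ptm_id[i])) {
      add("ERROR", loc, paste0("PTM_ID must be exactly four decimal digits,",
                               " found \"", rec$ptm_id[i], "\""))
    } else if (rec$ptm_id[i] != "0000" &&
               !rec$ptm_id[i] %in% names(file$ptm_dict)) {
      add("ERROR", loc, paste0("PTM_ID \"", rec$ptm_id[i],
                               "\" has no entry in the PTM dictionary"))
    }
    if (is.na(rec$time_sec[i]) || rec$time_sec[i] < 0)
      add("ERROR", loc, "TIME(SEC) must be non-negative or inf")
    if (is.na(rec$uptake[i]))
      add("ERROR", loc, "UPTAKE is missing")
    if (has_env[i]) {
      e <- rec$envelope[[i]]
      if (length(e) < 1L || any(e < 0) || anyNA(e)) {
        add("ERROR", loc, "ENVELOPE must contain non-negative intensities")
      } else {
        dev <- abs(sum(e) - 1)
        if (dev > 1e-2) {
          add("ERROR", loc, sprintf(
            "ENVELOPE sum %.6f deviates from 1 by more than 0.01", sum(e)))
        } else if (dev > 1e-3) {
          add("WARNING", loc, sprintf(
            "ENVELOPE sum %.6f deviates from 1 by more than 0.001", sum(e)))
        }
      }
    }
  }

  # duplicate (start, end, time, rep, mod) keys: legal but suspicious
  if (nrow(rec) > 1L) {
    key <- paste(rec$start, rec$end, rec$time_sec, rec$rep, rec$mod,
                 rec$ptm_id)
    dup <- which(duplicated(key))
    for (i in dup)
      add("WARNING", paste0("record ", i, " (INDEX ", rec$index[i], ")"),
          "duplicate (START, END, TIME, REP, MOD) combination")
  }

  # PTM dictionary
  if ("0000" %in% names(file$ptm_dict))
    add("ERROR", "ptm 0000",
        "PTM_ID 0000 denotes \"no PTM\" and must not be a dictionary entry")
  bad_ids <- names(file$ptm_dict)[!grepl("^[0-9]{4}$", names(file$ptm_dict))]
  for (id in bad_ids)
    add("ERROR", paste0("ptm ", id),
        "PTM dictionary keys must be four decimal digits")
  dup_ids <- names(file$ptm_dict)[duplicated(names(file$ptm_dict))]
  for (id in dup_ids)
    add("ERROR", paste0("ptm ", id), "duplicate PTM_ID in dictionary")

  # whole-file mode consistency
  if (any(has_env) && !all(has_env))
    add("ERROR", "file",
        "mixed centroid and full-spectrum records in one file")

  report <- if (length(out) == 0L) {
    new_violation(character(), character(), character())
  } else {
    do.call(rbind, out)
  }
  rownames(report) <- NULL
  class(report) <- c("hxms_validation_report", "data.frame")
  report
}

#' @export
print.hxms_validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("HXMS validation: no violations\n")
  } else {
    cat("HXMS validation:", sum(x$severity == "ERROR"), "error(s),",
        sum(x$severity == "WARNING"), "warning(s)\n")
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$locator[i],
                  x$message[i]))
  }
  invisible(x)
}

#' Extract the peptide sequence covered by a record
#'
#' Returns the substring of the protein sequence spanned by a record's
#' `start`..`end` positions (1-based, inclusive of both ends), so its length
#' is `end - start + 1`.
#'
#' @param file An `hxms_file` whose metadata carries the protein sequence.
#' @param record Either a row number into `file$records`, or any list-like
#'   object with `start`, `end` and (optionally, for error messages)
#'   `index` elements.
#' @return Character scalar.
#' @examples
#' md <- hxms_metadata("GSHMKTVEVNGADASDDN", 293.15, 6.0, 0.91)
#' f <- hxms_file(md, hxms_records(1, 10, 0, 0))
#' peptide_sequence(f, 1)  # "GSHMKTVEVN"
#' @export
peptide_sequence <- function(file, record) {
  stopifnot(inherits(file, "hxms_file"))
  if (is.numeric(record) && length(record) == 1L)
    record <- file$records[record, ]
  start <- record$start
  end <- record$end
  idx <- if (!is.null(record$index)) record$index else NA_integer_
  seqlen <- nchar(file$metadata$protein_sequence)
  if (is.na(start) || is.na(end) || start < 1L || start > end ||
      end > seqlen) {
    stop("record INDEX ", idx, ": span START=", start, " END=", end,
         " is invalid for a sequence of length ", seqlen, call. = FALSE)
  }
  substr(file$metadata$protein_sequence, start, end)
}

#' @export
print.hxms_metadata <- function(x, ...) {
  cat("HXMS metadata\n")
  for (fld in names(.META_TITLES)) {
    v <- x[[fld]]
    if (length(v) == 1L && !is.na(v))
      cat(sprintf("  %-18s %s\n", .META_TITLES[[fld]], format_meta_value(v)))
  }
  if (nrow(x$remarks) > 0L)
    cat("  remarks:", nrow(x$remarks), "\n")
  invisible(x)
}

#' @export
print.hxms_file <- function(x, ...) {
  mode <- hxms_is_full_spectrum(x)
  cat("HXMS document:", nrow(x$records), "timepoint record(s),",
      length(x$ptm_dict), "PTM entrie(s),",
      if (isTRUE(mode)) "full-spectrum" else if (isFALSE(mode)) "centroid"
      else "empty or mixed", "\n")
  print(x$metadata)
  invisible(x)
}
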