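# Fixed-width layout of the experimental-data and PTM sections.  Data lines
# are left-justified and space-padded to these widths (PDB-style); the
# ENVELOPE and CONTENT fields are unbounded and terminate the line.

#' Field layout of HXMS data lines
#'
#' Returns the fixed character widths of the serialized record and PTM
#' lines.  `width` is `NA` for the unbounded trailing fields (ENVELOPE,
#' CONTENT); `offset` is the 0-based character position at which each field
#' starts on a written line.
#'
#' @return A data frame with columns `section`, `name`, `width`, `offset`.
#' @export
hxms_field_layout <- function() {
  tp <- data.frame(
    section = "TP",
    name = c("TITLE", "INDEX", "MOD", "START", "END", "REP", "PTM_ID",
             "TIME(SEC)", "UPTAKE", "ENVELOPE"),
    width = c(12L, 8L, 7L, 7L, 7L, 5L, 8L, 16L, 9L, NA_integer_),
    stringsAsFactors = FALSE
  )
  ptm <- data.frame(
    section = "PTM",
    name = c("TITLE_PTM", "PTM_ID", "CONTENT"),
    width = c(12L, 8L, NA_integer_),
    stringsAsFactors = FALSE
  )
  layout <- rbind(tp, ptm)
  off <- unlist(lapply(split(layout$width, layout$section), function(w) {
    cumsum(c(0L, w[-length(w)]))
  })[unique(layout$section)])
  layout$offset <- as.integer(off)
  layout
}

#' Format an incubation time for serialization
#'
#' Times are written in scientific notation with six fractional digits and a
#' two-digit exponent (e.g. `"0.000000e+00"`, `"6.000000e+01"`); the fully
#' deuterated control is written as `"inf"`.
#'
#' @param t Non-negative time in seconds, or `Inf`.
#' @return Character scalar.
#' @examples
#' format_hxms_time(0)    # "0.000000e+00"
#' format_hxms_time(Inf)  # "inf"
#' @export
format_hxms_time <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1L, !is.na(t))
  if (t < 0) stop("time must be non-negative, got ", t, call. = FALSE)
  if (is.infinite(t)) "inf" else sprintf("%.6e", t)
}

pad_field <- function(value, width, name) {
  if (nchar(value) > width)
    stop("field ", name, ": rendering \"", value, "\" exceeds its width of ",
         width, " characters", call. = FALSE)
  sprintf("%-*s", width, value)
}

# Envelopes are printed to 3 decimals; naive per-peak rounding would make
# the printed intensities sum to 0.999 or 1.001, so the peaks are
# quantized onto the 0.001 grid by largest remainder, keeping the written
# envelope at exactly 1.000 as in every worked example of the format.
format_envelope <- function(e) {
  scaled <- 1000 * e / sum(e)
  counts <- round(scaled)
  deficit <- 1000 - sum(counts)
  if (deficit != 0) {
    resid <- scaled - counts
    ord <- order(resid, decreasing = deficit > 0)
    idx <- ord[seq_len(abs(deficit))]
    counts[idx] <- counts[idx] + sign(deficit)
  }
  paste(sprintf("%.3f", counts / 1000), collapse = ",")
}

#' Serialize an HXMS document
#'
#' Writes the three sections in order.  Metadata and remark lines are
#' tab-delimited (`TAG<TAB>TITLE<TAB>VALUE`); record and PTM lines are
#' fixed-width, left-justified and space-padded to the widths in
#' [hxms_field_layout()], with the envelope appended as comma-separated
#' intensities printed to three decimals (quantized by largest remainder
#' so the printed peaks sum to exactly 1.000).  Uptake is printed to two
#' decimals.  Serialization refuses documents with ERROR-level validation
#' problems, so a written file always reads back as a valid document.
#'
#' @param file An `hxms_file`.
#' @param path Output file path, or `NULL` to return the text instead.
#' @return The serialized text, invisibly when `path` is given.
#' @seealso [read_hxms()]
#' @export
write_hxms <- function(file, path = NULL) {
  report <- hxms_validate(file)
  if (any(report$severity == "ERROR")) {
    print(report)
    stop("cannot serialize: document has ERROR-level validation problems",
         call. = FALSE)
  }
  md <- file$metadata
  lines <- character()
  for (fld in names(.META_TITLES)) {
    v <- md[[fld]]
    if (length(v) == 1L && !is.na(v)) {
      value <- if (fld %in% names(md$raw)) md$raw[[fld]]
               else format_meta_value(v)
      lines <- c(lines,
                 paste("METADATA", .META_TITLES[[fld]], value, sep = "\t"))
    }
  }
  if (nrow(md$remarks) > 0L)
    lines <- c(lines, paste("REMARK", md$remarks$title, md$remarks$body,
                            sep = "\t"))

  rec <- file$records
  for (i in seq_len(nrow(rec))) {
    line <- paste0(
      pad_field("TP", 12L, "TITLE"),
      pad_field(as.character(rec$index[i]), 8L, "INDEX"),
      pad_field(rec$mod[i], 7L, "MOD"),
      pad_field(as.character(rec$start[i]), 7L, "START"),
      pad_field(as.character(rec$end[i]), 7L, "END"),
      pad_field(as.character(rec$rep[i]), 5L, "REP"),
      pad_field(rec$ptm_id[i], 8L, "PTM_ID"),
      pad_field(format_hxms_time(rec$time_sec[i]), 16L, "TIME(SEC)"),
      pad_field(sprintf("%.2f", rec$uptake[i]), 9L, "UPTAKE")
    )
    e <- rec$envelope[[i]]
    if (!is.null(e)) line <- paste0(line, format_envelope(e))
    lines <- c(lines, line)
  }

  for (id in names(file$ptm_dict)) {
    lines <- c(lines, paste0(
      pad_field("PTM", 12L, "TITLE_PTM"),
      pad_field(id, 8L, "PTM_ID"),
      file$ptm_dict[[id]]
    ))
  }

  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  con <- base::file(path, open = "wb")
  on.exit(close(con))
  writeChar(text, con, eos = NULL)
  invisible(text)
}

parse_time_token <- function(token, lineno) {
  if (tolower(token) %in% c("inf", "infinity")) return(Inf)
  t <- suppressWarnings(as.numeric(token))
  if (is.na(t))
    stop("line ", lineno, ": TIME(SEC) token \"", token,
         "\" is neither a scientific-notation real nor \"inf\"",
         call. = FALSE)
  t
}

#' Parse an HXMS document
#'
#' A tolerant reader: record and PTM lines are accepted both in the
#' fixed-width form the writer emits and in tab-delimited form; blank lines
#' and lines starting with `#` are ignored.  A validation report, including
#' any reader warnings (unknown metadata titles, out-of-order sections), is
#' attached to the result and can be retrieved with [hxms_validation()].
#'
#' @param source Path to a `.hxms` file, or the document text itself (a
#'   string containing a newline is treated as text).
#' @return An `hxms_file`.
#' @seealso [write_hxms()], [hxms_validate()]
#' @export
read_hxms <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (grepl("\n", source, fixed = TRUE)) {
    lines <- strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- readLines(source, warn = FALSE)
  }

  meta_values <- character()   # field name -> raw string
  remarks_title <- character(); remarks_body <- character()
  reader_notes <- list()
  rec_rows <- list()
  ptm_ids <- character(); ptm_content <- character()
  title_to_field <- stats::setNames(names(.META_TITLES), .META_TITLES)
  section_rank <- c(meta = 1L, tp = 2L, ptm = 3L)
  max_rank <- 0L

  note <- function(severity, locator, message) {
    reader_notes[[length(reader_notes) + 1L]] <<-
      new_violation(severity, locator, message)
  }
  seen <- function(what, lineno) {
    r <- section_rank[[what]]
    if (r < max_rank)
      note("WARNING", paste0("line ", lineno),
           "sections appear out of order (metadata, records, PTM expected)")
    max_rank <<- max(max_rank, r)
  }

  for (lineno in seq_along(lines)) {
    line <- lines[[lineno]]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    tag <- sub("[ \t].*$", "", line)

    if (tag %in% c("METADATA", "REMARK")) {
      seen("meta", lineno)
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3L)
        stop("line ", lineno, ": ", tag,
             " line must be TAG<TAB>TITLE<TAB>VALUE", call. = FALSE)
      title <- parts[2]
      value <- paste(parts[-(1:2)], collapse = "\t")
      if (tag == "REMARK") {
        remarks_title <- c(remarks_title, title)
        remarks_body <- c(remarks_body, value)
      } else if (title %in% names(title_to_field)) {
        meta_values[[title_to_field[[title]]]] <- value
      } else {
        note("WARNING", paste0("line ", lineno),
             paste0("unknown METADATA title \"", title,
                    "\" stored as remark"))
        remarks_title <- c(remarks_title, title)
        remarks_body <- c(remarks_body, value)
      }
    } else if (tag == "TP") {
      seen("tp", lineno)
      tokens <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(tokens) < 9L || length(tokens) > 10L)
        stop("line ", lineno, ": TP line must have 9 fixed fields plus an ",
             "optional envelope; found ", length(tokens), " tokens",
             call. = FALSE)
      num <- function(k, name) {
        x <- suppressWarnings(as.numeric(tokens[k]))
        if (is.na(x))
          stop("line ", lineno, ": cannot parse ", name, " token \"",
               tokens[k], "\"", call. = FALSE)
        x
      }
      env <- if (length(tokens) == 10L) {
        as.numeric(strsplit(tokens[10], ",", fixed = TRUE)[[1]])
      } else NULL
      rec_rows[[length(rec_rows) + 1L]] <- list(
        index = as.integer(num(2, "INDEX")),
        mod = tokens[3],
        start = as.integer(num(4, "START")),
        end = as.integer(num(5, "END")),
        rep = as.integer(num(6, "REP")),
        ptm_id = tokens[7],
        time_sec = parse_time_token(tokens[8], lineno),
        uptake = num(9, "UPTAKE"),
        envelope = env
      )
    } else if (tag == "PTM") {
      seen("ptm", lineno)
      if (grepl("\t", line, fixed = TRUE)) {
        parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3L)
          stop("line ", lineno, ": PTM line must be PTM<TAB>ID<TAB>CONTENT",
               call. = FALSE)
        id <- trimws(parts[2])
        content <- paste(parts[-(1:2)], collapse = "\t")
      } else {
        # fixed width: TITLE_PTM (12) + PTM_ID (8) + unbounded CONTENT
        id <- trimws(substr(line, 13L, 20L))
        content <- trimws(substr(line, 21L, nchar(line)))
      }
      ptm_ids <- c(ptm_ids, id)
      ptm_content <- c(ptm_content, content)
    } else {
      stop("line ", lineno, ": unknown tag \"", tag, "\" (expected ",
           "METADATA, REMARK, TP or PTM)", call. = FALSE)
    }
  }

  as_num <- function(fld) {
    if (fld %in% names(meta_values))
      suppressWarnings(as.numeric(meta_values[[fld]])) else NA_real_
  }
  md <- hxms_metadata(
    protein_sequence = if ("protein_sequence" %in% names(meta_values))
      meta_values[["protein_sequence"]] else NA_character_,
    temperature_k  = as_num("temperature_k"),
    ph_read        = as_num("ph_read"),
    d2o_saturation = as_num("d2o_saturation"),
    protein_name   = if ("protein_name" %in% names(meta_values))
      meta_values[["protein_name"]] else NULL,
    protein_state  = if ("protein_state" %in% names(meta_values))
      meta_values[["protein_state"]] else NULL,
    remarks = if (length(remarks_title) > 0L)
      data.frame(title = remarks_title, body = remarks_body,
                 stringsAsFactors = FALSE) else NULL,
    .raw = meta_values
  )

  records <- if (length(rec_rows) == 0L) {
    hxms_records(integer(), integer(), numeric(), numeric())
  } else {
    hxms_records(
      start    = vapply(rec_rows, `[[`, integer(1), "start"),
      end      = vapply(rec_rows, `[[`, integer(1), "end"),
      time_sec = vapply(rec_rows, `[[`, numeric(1), "time_sec"),
      uptake   = vapply(rec_rows, `[[`, numeric(1), "uptake"),
      mod      = vapply(rec_rows, `[[`, character(1), "mod"),
      rep      = vapply(rec_rows, `[[`, integer(1), "rep"),
      ptm_id   = vapply(rec_rows, `[[`, character(1), "ptm_id"),
      envelope = lapply(rec_rows, `[[`, "envelope"),
      index    = vapply(rec_rows, `[[`, integer(1), "index")
    )
  }

  f <- hxms_file(md, records,
                 ptm_dict = stats::setNames(ptm_content, ptm_ids))
  report <- hxms_validate(f)
  if (length(reader_notes) > 0L) {
    report <- rbind(do.call(rbind, reader_notes), report)
    class(report) <- c("hxms_validation_report", "data.frame")
  }
  attr(f, "validation") <- report
  f
}

#' Retrieve the validation report attached by the reader
#'
#' @param file An `hxms_file` returned by [read_hxms()].
#' @return An `hxms_validation_report`, or `NULL` if none is attached.
#' @export
hxms_validation <- function(file) attr(file, "validation", exact = TRUE)
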