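# Conversion of normalized dialect rows into HXMS documents.

capability_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("hxms_capability_error", "error",
                                "condition")))
}

validation_error <- function(msg, report) {
  stop(errorCondition(msg, report = report,
                      class = c("hxms_validation_error", "error",
                                "condition")))
}

# Fill rows$centroid from envelopes where absent, then compute uptake by
# the zero-timepoint rule: each replicate with its own 0 s point is
# referenced to it; replicates without one use the mean of the zero
# centroids of the replicates that have one.  Modes of a bimodal peptide
# lacking any zero of their own (zero-time samples are typically unimodal)
# are referenced to the mode-"A" zero of the same replicate.
recompute_uptake_rows <- function(rows) {
  need_c <- is.na(rows$centroid)
  if (any(need_c)) {
    no_env <- need_c & vapply(rows$envelope, is.null, logical(1))
    if (any(no_env))
      schema_error("cannot recompute uptake: row ", which(no_env)[1],
                   " has neither a centroid nor an envelope")
    rows$centroid[need_c] <- vapply(rows$envelope[need_c],
                                    envelope_centroid, numeric(1))
  }
  rows$uptake <- NA_real_
  pep_key <- paste(rows$start, rows$end, rows$modification)
  for (pk in unique(pep_key)) {
    in_pep <- which(pep_key == pk)
    mods <- unique(rows$mod[in_pep])
    mods <- c(intersect("A", mods), setdiff(sort(mods), "A"))
    zr_by_mod <- list()
    for (m in mods) {
      in_mod <- in_pep[rows$mod[in_pep] == m]
      series <- lapply(split(in_mod, rows$rep[in_mod]), function(i) {
        centroid_series(rows$start[i[1]], rows$end[i[1]],
                        time_sec = rows$time_sec[i],
                        centroid = rows$centroid[i],
                        mod = m, rep = rows$rep[i[1]])
      })
      zr <- tryCatch(zero_reference(unname(series)), error = function(e) NULL)
      if (is.null(zr)) {
        zr_a <- zr_by_mod[["A"]]
        if (is.null(zr_a))
          stop("no replicate has a 0 s timepoint for peptide ",
               rows$start[in_mod[1]], "-", rows$end[in_mod[1]],
               call. = FALSE)
        reps_m <- as.character(sort(unique(rows$rep[in_mod])))
        zr <- stats::setNames(
          ifelse(reps_m %in% names(zr_a), zr_a[reps_m], mean(zr_a)), reps_m)
      }
      zr_by_mod[[m]] <- zr
      rows$uptake[in_mod] <- rows$centroid[in_mod] -
        zr[as.character(rows$rep[in_mod])]
    }
  }
  rows
}

build_hxms_from_rows <- function(rows, metadata, state, full_spectrum) {
  ord <- order(rows$start, rows$end, rows$time_sec, rows$rep, rows$mod)
  rows <- rows[ord, , drop = FALSE]

  # PTM dictionary: distinct modification strings, ids assigned in
  # first-appearance order over the sorted records
  mods <- rows$modification
  distinct <- unique(mods[nzchar(mods)])
  ptm_dict <- stats::setNames(distinct, sprintf("%04d", seq_along(distinct)))
  ptm_id <- rep("0000", nrow(rows))
  has_mod <- nzchar(mods)
  ptm_id[has_mod] <- names(ptm_dict)[match(mods[has_mod], ptm_dict)]

  md <- metadata
  if (nzchar(state)) {
    md$protein_state <- state
    md$raw[["protein_state"]] <- state
  }

  # sequence consistency: the export's peptide sequence should match the
  # protein-sequence substring it claims to span
  if (!is.na(md$protein_sequence)) {
    claim <- substr(rep(md$protein_sequence, nrow(rows)),
                    rows$start, rows$end)
    bad <- nzchar(rows$sequence) & rows$sequence != claim
    if (any(bad))
      warning(sum(bad), " row(s) have a peptide sequence that disagrees ",
              "with the protein sequence over their span (first: ",
              rows$sequence[which(bad)[1]], " vs ", claim[which(bad)[1]],
              ")", call. = FALSE)
  }

  f <- hxms_file(
    md,
    hxms_records(
      start = rows$start, end = rows$end, time_sec = rows$time_sec,
      uptake = rows$uptake, mod = rows$mod, rep = rows$rep,
      ptm_id = ptm_id,
      envelope = if (full_spectrum) rows$envelope else NULL
    ),
    ptm_dict = ptm_dict
  )
  report <- hxms_validate(f)
  if (any(report$severity == "ERROR"))
    validation_error(
      paste0("converted document fails validation: ",
             paste(report$message[report$severity == "ERROR"],
                   collapse = "; ")),
      report)
  f
}

#' Convert an HX/MS export to an HXMS document
#'
#' Parses the input under the named dialect's column map, recomputes
#' deuterium uptake from centroids where the dialect does not report it
#' directly (HDX Workbench and HDExaminer exports; using the
#' zero-timepoint replicate-averaging rule of [zero_reference()]), builds
#' the PTM dictionary from the distinct modification annotations, sorts
#' records by (start, end, time, replicate, mode) with file-wide indices
#' 0, 1, 2, ..., and validates the result.
#'
#' @param input Path to the export file, or its text.
#' @param dialect Dialect name (see [hxms_dialects()]); `"custom"` inputs
#'   embed their own metadata.
#' @param metadata An [hxms_metadata()] with the experimental conditions
#'   (exports do not carry temperature/pH/D2O).  Ignored for `"custom"`
#'   inputs, which are self-contained.
#' @param state_filter Keep only rows of this protein state.  When omitted
#'   and the input contains several states, one document per state is
#'   returned as a named list.
#' @param output_mode `"centroid"` (drop envelopes) or `"full_spectrum"`
#'   (keep them; only available for dialects that carry spectra).
#' @return An `hxms_file`, or a named list of them (one per state) when the
#'   input has several states and no `state_filter` is given.
#' @export
convert_hxms <- function(input, dialect,
                         metadata = NULL,
                         state_filter = NULL,
                         output_mode = c("centroid", "full_spectrum")) {
  output_mode <- match.arg(output_mode)
  if (inherits(input, "hxms_conversion_request")) {
    req <- input
    dialect <- req$dialect
    sp <- dialect_spec(dialect)
    rows <- req$rows
    metadata <- req$metadata
  } else if (identical(dialect, "custom")) {
    req <- read_custom_csv(input)
    sp <- dialect_spec("custom")
    rows <- req$rows
    metadata <- req$metadata
  } else {
    sp <- dialect_spec(dialect)
    if (is.null(metadata))
      schema_error("dialect \"", dialect, "\": experimental metadata ",
                   "(sequence, temperature, pH read, D2O saturation) must ",
                   "be supplied; exports do not contain it")
    rows <- parse_dialect(dialect, input)
  }

  full_spectrum <- output_mode == "full_spectrum"
  if (full_spectrum && !sp$carries_spectra)
    capability_error("dialect \"", dialect, "\" does not carry full ",
                     "isotopic spectra; only centroid output is possible")
  if (full_spectrum && any(vapply(rows$envelope, is.null, logical(1))))
    capability_error("full-spectrum output requested but ",
                     sum(vapply(rows$envelope, is.null, logical(1))),
                     " row(s) have no envelope")

  states <- unique(rows$state)
  if (!is.null(state_filter)) {
    rows <- rows[rows$state == state_filter, , drop = FALSE]
    if (nrow(rows) == 0L)
      schema_error("state filter \"", state_filter, "\" matches no rows; ",
                   "states present: ",
                   paste(unique(states), collapse = ", "))
    states <- state_filter
  }

  need_recompute <- !sp$carries_uptake || anyNA(rows$uptake)
  one_state <- function(st) {
    sub <- rows[rows$state == st, , drop = FALSE]
    if (need_recompute) sub <- recompute_uptake_rows(sub)
    build_hxms_from_rows(sub, metadata, st, full_spectrum)
  }

  if (length(states) == 1L) {
    one_state(states)
  } else {
    stats::setNames(lapply(states, one_state), states)
  }
}
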