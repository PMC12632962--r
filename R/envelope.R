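# Envelope normalization, centroid extraction and deuterium-uptake
# computation.  Peak spacing is treated as exactly 1 Da in index units:
# exports provide per-peptide, charge-deconvoluted spectra, so the envelope
# is a unitless list of relative intensities over consecutive isotope peaks.

#' Normalize an isotopic mass envelope to unit sum
#'
#' @param raw Numeric vector of non-negative peak intensities, at least one
#'   of them positive.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' normalize_envelope(c(2, 1, 1))  # 0.50 0.25 0.25
#' @export
normalize_envelope <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1L)
  if (anyNA(raw) || any(raw < 0))
    stop("envelope intensities must be non-negative", call. = FALSE)
  total <- sum(raw)
  if (total <= 0)
    stop("envelope must contain at least one positive intensity",
         call. = FALSE)
  raw / total
}

#' Centroid of an isotopic mass envelope
#'
#' The intensity-weighted first moment over peak indices 0, 1, 2, ...,
#' i.e. the mean mass offset in Daltons from the first reported peak
#' (1 Da isotope spacing assumed).  For a unit-sum envelope this is
#' `sum(i * p_i)`; un-normalized input is divided by its total first.
#'
#' @param e Numeric vector of non-negative peak intensities.
#' @return Centroid in Daltons relative to the first peak, in
#'   `[0, length(e) - 1]`.
#' @examples
#' envelope_centroid(c(0, 1))  # 1
#' @export
envelope_centroid <- function(e) {
  stopifnot(is.numeric(e), length(e) >= 1L)
  if (anyNA(e) || any(e < 0))
    stop("envelope intensities must be non-negative", call. = FALSE)
  total <- sum(e)
  if (total <= 0)
    stop("envelope must contain at least one positive intensity",
         call. = FALSE)
  sum((seq_along(e) - 1) * e) / total
}

#' A per-peptide, per-replicate centroid time series
#'
#' Bundles the centroids of one peptide/mode/replicate/PTM combination over
#' the experimental time course, the unit on which deuterium uptake is
#' defined (centroid at time t minus centroid at time 0).
#'
#' @param start,end Peptide span (1-based, inclusive).
#' @param time_sec,centroid Paired numeric vectors; one centroid per time.
#'   `Inf` marks the fully deuterated control.
#' @param mod Distribution label, default `"A"`.
#' @param rep Replicate number, default `0`.
#' @param ptm_id 4-digit PTM identifier, default `"0000"`.
#' @return An object of class `centroid_series` with elements `key` and
#'   `points` (a data frame sorted by time).
#' @export
centroid_series <- function(start, end, time_sec, centroid,
                            mod = "A", rep = 0L, ptm_id = "0000") {
  stopifnot(length(time_sec) == length(centroid), length(time_sec) >= 1L)
  if (anyDuplicated(time_sec))
    stop("centroid series has more than one point at the same time",
         call. = FALSE)
  ord <- order(time_sec)
  structure(
    list(
      key = list(start = as.integer(start), end = as.integer(end),
                 mod = as.character(mod), rep = as.integer(rep),
                 ptm_id = as.character(ptm_id)),
      points = data.frame(time_sec = as.numeric(time_sec)[ord],
                          centroid = as.numeric(centroid)[ord])
    ),
    class = "centroid_series"
  )
}

series_key_label <- function(s) {
  sprintf("peptide %d-%d mod %s rep %d ptm %s", s$key$start, s$key$end,
          s$key$mod, s$key$rep, s$key$ptm_id)
}

#' Compute deuterium uptake from a centroid series
#'
#' Uptake at time t is the centroid at t minus the zero-timepoint centroid
#' of the same peptide and replicate, so the 0 s record itself always has
#' uptake exactly 0.  If the series lacks a 0 s point, a zero-centroid
#' reference must be supplied (typically from [zero_reference()], which
#' averages the zero centroids of the replicates that do have one).
#'
#' @param series A [centroid_series()].
#' @param zero_centroid Optional externally supplied zero-timepoint
#'   centroid; when `NULL` the series' own 0 s point is used.
#' @return A data frame with columns `time_sec` and `uptake`, in time order.
#' @examples
#' s <- centroid_series(1, 10, time_sec = c(0, 60), centroid = c(0.75, 2.10))
#' compute_uptake(s)  # uptake 0.00 then 1.35
#' @export
compute_uptake <- function(series, zero_centroid = NULL) {
  stopifnot(inherits(series, "centroid_series"))
  pts <- series$points
  if (is.null(zero_centroid)) {
    at_zero <- which(pts$time_sec == 0)
    if (length(at_zero) == 0L)
      stop("no 0 s timepoint and no zero-centroid reference for ",
           series_key_label(series), call. = FALSE)
    zero_centroid <- pts$centroid[at_zero[1]]
  }
  data.frame(time_sec = pts$time_sec,
             uptake = pts$centroid - zero_centroid)
}

#' Zero-timepoint reference centroids across replicates
#'
#' For one peptide measured in several replicates, each replicate that has
#' its own 0 s timepoint is referenced to it; a replicate missing the 0 s
#' sample is referenced to the arithmetic mean of the zero centroids of the
#' replicates that have one.
#'
#' @param series_list List of [centroid_series()] objects sharing
#'   (start, end, mod, ptm_id) and differing in `rep`.
#' @return Named numeric vector mapping replicate number to its
#'   zero-reference centroid.
#' @examples
#' a <- centroid_series(1, 10, c(0, 60), c(0.70, 2.0), rep = 0)
#' b <- centroid_series(1, 10, c(0, 60), c(0.80, 2.1), rep = 1)
#' c <- centroid_series(1, 10, 60, 2.2, rep = 2)
#' zero_reference(list(a, b, c))  # rep 2 gets mean(0.70, 0.80) = 0.75
#' @export
zero_reference <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  reps <- vapply(series_list, function(s) s$key$rep, integer(1))
  own <- vapply(series_list, function(s) {
    at_zero <- which(s$points$time_sec == 0)
    if (length(at_zero) == 0L) NA_real_ else s$points$centroid[at_zero[1]]
  }, numeric(1))
  if (all(is.na(own)))
    stop("no replicate has a 0 s timepoint for ",
         series_key_label(series_list[[1]]), call. = FALSE)
  fallback <- mean(own[!is.na(own)])
  own[is.na(own)] <- fallback
  stats::setNames(own, as.character(reps))
}
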