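# Synthetic HX/MS experiments and dialect export files, with ground truth.
#
# The exchange model is deliberately the simplest one with a closed-form
# centroid: every exchangeable site of a peptide is deuterated
# independently with probability p(t) = s * (1 - exp(-k t)) (s = D2O
# saturation; p(Inf) = s for the fully deuterated control), so the
# isotopic envelope is Binomial(n_sites, p) and its centroid is exactly
# n_sites * p.  That gives an analytic oracle for the envelope math;
# physical realism (site-specific intrinsic rates, back-exchange) is not
# the goal.
#
# All ground-truth quantities in this file are computed with plain loops,
# independently of the envelope/uptake code they are used to test.

run_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Define a synthetic HX/MS experiment
#'
#' Fixes the study conditions for a simulated exchange experiment on a
#' small model protein: peptide spans, the D2O incubation time course
#' (always including 0 s and the fully deuterated `Inf` control),
#' replicates, per-peptide exchange rate constants, optional hard cases
#' (a bimodal peptide, a PTM-bearing peptide, a replicate missing its 0 s
#' sample), and the intensity noise level.
#'
#' The number of exchangeable sites of a peptide is its length minus the
#' two fast-exchanging N-terminal residues and any prolines after them.
#'
#' @param protein_sequence One-letter protein sequence.
#' @param peptides List of `c(start, end)` spans.
#' @param timepoints_sec Incubation times in seconds, including `0` and
#'   `Inf`.
#' @param n_replicates Number of experimental replicates.
#' @param rates Per-peptide exchange rate constants (1/s) for the main
#'   (mode A) population; recycled over peptides.
#' @param rate_b Rate constant for the minor (mode B) population of a
#'   bimodal peptide.
#' @param bimodal `NULL`, or `list(peptide =, times =)` marking which
#'   peptide shows a second mode and at which times.
#' @param ptms `NULL`, or a list of `list(peptide =, content =)` PTM
#'   annotations (e.g. `content = "Phosphoryl STY (18)"`).
#' @param missing_zero_rep `NULL`, or the replicate number whose 0 s rows
#'   are omitted from emitted files (exercises the replicate-averaging
#'   zero-reference rule).
#' @param noise_sd Gaussian intensity noise (envelopes are truncated at 0
#'   and renormalized).
#' @param temperature_k,ph_read,d2o_saturation,protein_name,protein_state
#'   Experimental metadata for the emitted documents.
#' @param seed RNG seed; the same experiment always emits byte-identical
#'   files.
#' @return An object of class `synthetic_experiment`.
#' @export
synthetic_experiment <- function(
    protein_sequence = "GSHMKTVEVNGADASDDN",
    peptides = list(c(1L, 10L), c(5L, 14L), c(9L, 18L)),
    timepoints_sec = c(0, 60, 600, Inf),
    n_replicates = 2L,
    rates = c(0.05, 0.005, 5e-4),
    rate_b = 0.5,
    bimodal = NULL,
    ptms = NULL,
    missing_zero_rep = NULL,
    noise_sd = 0.005,
    temperature_k = 293.15,
    ph_read = 6.0,
    d2o_saturation = 0.91,
    protein_name = "synthetic model protein",
    protein_state = "APO",
    seed = 42L) {
  stopifnot(length(peptides) >= 1L, n_replicates >= 1L,
            0 %in% timepoints_sec, noise_sd >= 0,
            d2o_saturation > 0, d2o_saturation <= 1)
  for (p in peptides)
    stopifnot(p[1] >= 1L, p[1] <= p[2], p[2] <= nchar(protein_sequence))
  structure(
    list(protein_sequence = protein_sequence, peptides = peptides,
         timepoints_sec = sort(timepoints_sec), n_replicates = n_replicates,
         rates = rep_len(rates, length(peptides)), rate_b = rate_b,
         bimodal = bimodal, ptms = ptms,
         missing_zero_rep = missing_zero_rep, noise_sd = noise_sd,
         temperature_k = temperature_k, ph_read = ph_read,
         d2o_saturation = d2o_saturation, protein_name = protein_name,
         protein_state = protein_state, seed = seed),
    class = "synthetic_experiment"
  )
}

exchangeable_sites <- function(peptide_seq) {
  if (nchar(peptide_seq) <= 2L) return(1L)
  tail_seq <- substr(peptide_seq, 3L, nchar(peptide_seq))
  n <- nchar(tail_seq) - sum(strsplit(tail_seq, "")[[1]] == "P")
  max(1L, n)
}

#' Simulate an isotopic mass envelope
#'
#' Intensities proportional to the Binomial(`n_sites`, `p_exchanged`) mass
#' function, optionally perturbed by Gaussian noise truncated at zero, then
#' renormalized to unit sum.  The expected centroid of the noise-free
#' envelope is exactly `n_sites * p_exchanged`.
#'
#' Noise is drawn from the current RNG stream; seed the session (or use
#' the `seed` carried by a [synthetic_experiment()]) for reproducibility.
#'
#' @param n_sites Number of exchangeable sites (envelope has
#'   `n_sites + 1` peaks).
#' @param p_exchanged Per-site deuteration probability in `[0, 1]`.
#' @param noise_sd Standard deviation of the intensity noise.
#' @return A unit-sum numeric vector of length `n_sites + 1`.
#' @export
simulate_envelope <- function(n_sites, p_exchanged, noise_sd = 0) {
  stopifnot(n_sites >= 1L, p_exchanged >= 0, p_exchanged <= 1,
            noise_sd >= 0)
  probs <- stats::dbinom(0:n_sites, n_sites, p_exchanged)
  if (noise_sd > 0) {
    noisy <- pmax(0, probs + stats::rnorm(n_sites + 1L, 0, noise_sd))
    if (sum(noisy) > 0) probs <- noisy
  }
  probs / sum(probs)
}

# intensity-weighted first moment by explicit accumulation (oracle; kept
# independent of envelope_centroid on purpose)
centroid_loop <- function(e) {
  s <- 0; tot <- 0
  for (j in seq_along(e)) {
    s <- s + (j - 1) * e[j]
    tot <- tot + e[j]
  }
  s / tot
}

round_chr <- function(x, digits) as.numeric(sprintf(paste0("%.", digits, "f"), x))

# Generate the underlying model rows of an experiment in a canonical order
# (peptide, time, replicate, mode).  Envelope intensities are rounded to
# the 6 decimals that the emitted CSV cells carry, so downstream truth is
# computed on exactly the numbers a converter will see.
model_rows <- function(exp) {
  rows <- list()
  for (ip in seq_along(exp$peptides)) {
    span <- exp$peptides[[ip]]
    pep_seq <- substr(exp$protein_sequence, span[1], span[2])
    n_sites <- exchangeable_sites(pep_seq)
    modification <- ""
    if (!is.null(exp$ptms)) {
      for (pt in exp$ptms)
        if (pt$peptide == ip) modification <- pt$content
    }
    for (t in exp$timepoints_sec) {
      modes <- "A"
      if (!is.null(exp$bimodal) && exp$bimodal$peptide == ip &&
          t %in% exp$bimodal$times)
        modes <- c("A", "B")
      for (r in seq_len(exp$n_replicates) - 1L) {
        for (m in modes) {
          k <- if (m == "A") exp$rates[ip] else exp$rate_b
          p <- if (is.infinite(t)) exp$d2o_saturation
               else exp$d2o_saturation * (1 - exp(-k * t))
          env <- simulate_envelope(n_sites, p, exp$noise_sd)
          env6 <- round_chr(env, 6L)
          rows[[length(rows) + 1L]] <- list(
            peptide = ip, start = span[1], end = span[2],
            sequence = pep_seq, mod = m, rep = r, time_sec = t,
            modification = modification, envelope = env6,
            centroid = centroid_loop(env6)
          )
        }
      }
    }
  }
  # drop the 0 s rows of the designated missing-zero replicate
  if (!is.null(exp$missing_zero_rep)) {
    keep <- vapply(rows, function(x) {
      !(x$rep == exp$missing_zero_rep && x$time_sec == 0)
    }, logical(1))
    rows <- rows[keep]
  }
  rows
}

# Zero-reference centroids by the replicate-averaging rule, plain loops
# only: per (peptide, modification, mode), each replicate with a 0 s row
# uses its own zero centroid; replicates without one use the mean of those
# that have one; a mode with no zero at all falls back to mode A's map.
truth_uptake <- function(rows) {
  key_of <- function(x) paste(x$start, x$end, x$modification)
  zero_map <- list()   # key -> mode -> rep (chr) -> zero centroid
  for (x in rows) {
    if (x$time_sec == 0) {
      k <- key_of(x)
      if (is.null(zero_map[[k]])) zero_map[[k]] <- list()
      if (is.null(zero_map[[k]][[x$mod]])) zero_map[[k]][[x$mod]] <- c()
      zero_map[[k]][[x$mod]][[as.character(x$rep)]] <- x$centroid
    }
  }
  uptakes <- numeric(length(rows))
  for (i in seq_along(rows)) {
    x <- rows[[i]]
    k <- key_of(x)
    zmode <- zero_map[[k]][[x$mod]]
    if (is.null(zmode)) zmode <- zero_map[[k]][["A"]]
    if (is.null(zmode))
      stop("fixture truth: no 0 s sample for peptide ", x$start, "-",
           x$end, call. = FALSE)
    z <- zmode[[as.character(x$rep)]]
    if (is.null(z)) {
      tot <- 0; cnt <- 0
      for (v in zmode) { tot <- tot + v; cnt <- cnt + 1 }
      z <- tot / cnt
    }
    uptakes[i] <- x$centroid - z
  }
  uptakes
}

csv_text <- function(df) {
  tc <- textConnection("out_lines", "w", local = TRUE)
  utils::write.csv(df, tc, row.names = FALSE, quote = TRUE)
  close(tc)
  paste0(paste(out_lines, collapse = "\n"), "\n")
}

fmt_envelope_cell <- function(e) paste(sprintf("%.6f", e), collapse = ",")

#' Emit a synthetic export file in a given dialect, with ground truth
#'
#' Simulates the experiment (deterministically from its seed), writes a
#' CSV in the dialect's column layout, and independently assembles the
#' HXMS document that a correct conversion of that CSV must produce.  The
#' ground-truth uptake values are computed with plain-loop arithmetic,
#' never by calling the envelope/uptake code under test.
#'
#' Dialect capabilities are respected: dialects without spectra get no
#' envelope column (and a centroid-level truth document), dialects without
#' PTM support silently lose the modification annotations, and dialects
#' that report uptake directly get an uptake column holding the
#' ground-truth values printed to 4 decimals.
#'
#' @param exp A [synthetic_experiment()].
#' @param dialect Dialect name (see [hxms_dialects()]).
#' @param dir If given, the CSV (and the truth document as `.hxms`) are
#'   written there.
#' @return A list with elements `text` (CSV text), `truth` (the expected
#'   `hxms_file`), `metadata`, `dialect`, and `path`/`truth_path` when
#'   `dir` was given.
#' @export
emit_dialect_file <- function(exp, dialect, dir = NULL) {
  stopifnot(inherits(exp, "synthetic_experiment"))
  sp <- dialect_spec(dialect)
  if (!is.null(exp$bimodal) && !"mod" %in% names(sp$columns))
    capability_error("dialect \"", dialect, "\" has no population/mode ",
                     "column and cannot express a bimodal experiment")
  rows <- run_with_seed(exp$seed, model_rows(exp))
  uptake <- truth_uptake(rows)

  # replicate labels as the dialect will expose them
  n <- length(rows)
  rep_model <- vapply(rows, `[[`, integer(1), "rep")
  if (dialect %in% c("dynamx", "hdexaminer")) {
    # run/file identifier strings, numbered by first appearance
    ids <- sprintf("run_%02d.raw", rep_model)
    seen <- character(); lab <- integer(n)
    for (i in seq_len(n)) {
      if (!ids[i] %in% seen) seen <- c(seen, ids[i])
      lab[i] <- match(ids[i], seen) - 1L
    }
    rep_label <- lab
    rep_ids <- ids
  } else if (dialect == "biopharma") {
    # no replicate column: rows of each (peptide, state, mode, time)
    # group are numbered in input order
    grp <- vapply(rows, function(x) paste(x$start, x$end, x$mod,
                                          x$time_sec, x$modification),
                  character(1))
    counter <- list(); lab <- integer(n)
    for (i in seq_len(n)) {
      g <- grp[i]
      cur <- if (is.null(counter[[g]])) 0L else counter[[g]]
      lab[i] <- cur
      counter[[g]] <- cur + 1L
    }
    rep_label <- lab
    rep_ids <- NULL
  } else {
    rep_label <- rep_model
    rep_ids <- as.character(rep_model)
  }

  start <- vapply(rows, `[[`, integer(1), "start")
  end <- vapply(rows, `[[`, integer(1), "end")
  pep_seq <- vapply(rows, `[[`, character(1), "sequence")
  mod <- vapply(rows, `[[`, character(1), "mod")
  time_sec <- vapply(rows, `[[`, numeric(1), "time_sec")
  modification <- vapply(rows, `[[`, character(1), "modification")
  centroid <- vapply(rows, `[[`, numeric(1), "centroid")
  envelopes <- lapply(rows, `[[`, "envelope")
  is_fd <- is.infinite(time_sec)

  if (!sp$carries_ptms) modification <- rep("", n)
  uptake_vis <- round_chr(uptake, 4L)

  # dialect CSV -------------------------------------------------------------
  if (dialect == "dynamx") {
    minutes <- sprintf("%.6g", time_sec / 60)
    minutes[is_fd] <- "MAX"
    time_truth <- ifelse(is_fd, Inf, suppressWarnings(as.numeric(minutes)) * 60)
    df <- data.frame(
      Protein = exp$protein_name, Start = start, End = end,
      Sequence = pep_seq, Modification = modification,
      State = exp$protein_state, Exposure = minutes, File = rep_ids,
      Uptake = sprintf("%.4f", uptake), check.names = FALSE,
      stringsAsFactors = FALSE)
  } else if (dialect == "biopharma") {
    secs <- sprintf("%.10g", time_sec)
    secs[is_fd] <- "FD"
    time_truth <- ifelse(is_fd, Inf, suppressWarnings(as.numeric(secs)))
    df <- data.frame(
      Sequence = pep_seq, Start = start, End = end,
      `Protein State` = exp$protein_state,
      `Exposure Time (s)` = secs,
      `D Uptake (Da)` = sprintf("%.4f", uptake), check.names = FALSE,
      stringsAsFactors = FALSE)
  } else if (dialect == "workbench") {
    secs <- sprintf("%.10g", time_sec)
    secs[is_fd] <- "FD"
    time_truth <- ifelse(is_fd, Inf, suppressWarnings(as.numeric(secs)))
    cent_chr <- sprintf("%.6f", centroid)
    centroid <- as.numeric(cent_chr)          # what the converter will see
    uptake <- truth_uptake(Map(function(x, ctr) {
      x$centroid <- ctr; x
    }, rows, centroid))
    df <- data.frame(
      Peptide = pep_seq, Start = start, End = end,
      Modification = modification, Sample = exp$protein_state,
      Timepoint = secs, Replicate = rep_ids, Population = mod,
      Centroid = cent_chr,
      Envelope = vapply(envelopes, fmt_envelope_cell, character(1)),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else if (dialect == "hdexaminer") {
    secs <- sprintf("%.10g", time_sec)
    secs[is_fd] <- "Full-D"
    time_truth <- ifelse(is_fd, Inf, suppressWarnings(as.numeric(secs)))
    df <- data.frame(
      `Protein State` = exp$protein_state, Sequence = pep_seq,
      Start = start, End = end, `Deut Time` = secs, File = rep_ids,
      Population = mod,
      Envelope = vapply(envelopes, fmt_envelope_cell, character(1)),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else if (dialect == "custom") {
    secs <- sprintf("%.10g", time_sec)
    secs[is_fd] <- "inf"
    time_truth <- ifelse(is_fd, Inf, suppressWarnings(as.numeric(secs)))
    df <- data.frame(
      START = start, END = end, SEQUENCE = pep_seq, MOD = mod,
      REP = rep_label, PTM_CONTENT = modification,
      `TIME(SEC)` = secs, UPTAKE = sprintf("%.4f", uptake),
      ENVELOPE = vapply(envelopes, fmt_envelope_cell, character(1)),
      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    capability_error("no fixture emitter for dialect \"", dialect, "\"")
  }

  text <- csv_text(df)
  if (dialect == "custom") {
    meta_block <- paste0(
      "PROTEIN_SEQUENCE,", exp$protein_sequence, "\n",
      "PROTEIN_NAME,", exp$protein_name, "\n",
      "PROTEIN_STATE,", exp$protein_state, "\n",
      "\"TEMPERATURE (K)\",", format_meta_value(exp$temperature_k), "\n",
      "pH(READ),", format_meta_value(exp$ph_read), "\n",
      "D2O_SATURATION,", format_meta_value(exp$d2o_saturation), "\n")
    text <- paste0(meta_block, text)
  }

  # ground-truth document ----------------------------------------------------
  metadata <- hxms_metadata(
    protein_sequence = exp$protein_sequence,
    temperature_k = exp$temperature_k, ph_read = exp$ph_read,
    d2o_saturation = exp$d2o_saturation,
    protein_name = exp$protein_name, protein_state = exp$protein_state)

  truth_uptake_vals <- if (sp$carries_uptake) {
    # converter copies the printed 4-decimal uptake column
    uptake_vis
  } else {
    # converter recomputes from the same printed centroids/envelopes
    uptake
  }
  ord <- order(start, end, time_sec, rep_label, mod)
  distinct_mod <- character()
  for (i in ord) {
    m <- modification[i]
    if (nzchar(m) && !m %in% distinct_mod)
      distinct_mod <- c(distinct_mod, m)
  }
  ptm_dict <- stats::setNames(distinct_mod,
                              sprintf("%04d", seq_along(distinct_mod)))
  ptm_id <- rep("0000", n)
  for (i in seq_len(n)) {
    if (nzchar(modification[i]))
      ptm_id[i] <- names(ptm_dict)[match(modification[i], ptm_dict)]
  }
  truth <- hxms_file(
    metadata,
    hxms_records(
      start = start[ord], end = end[ord], time_sec = time_truth[ord],
      uptake = truth_uptake_vals[ord], mod = mod[ord],
      rep = rep_label[ord], ptm_id = ptm_id[ord],
      envelope = if (sp$carries_spectra) envelopes[ord] else NULL
    ),
    ptm_dict = ptm_dict
  )

  out <- list(dialect = dialect, text = text, truth = truth,
              metadata = metadata)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$path <- file.path(dir, paste0("synthetic_", dialect, ".csv"))
    writeLines(sub("\n$", "", text), out$path)
    out$truth_path <- file.path(dir,
                                paste0("synthetic_", dialect, "_truth.hxms"))
    write_hxms(truth, out$truth_path)
  }
  out
}
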