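# Shared builders for the suite.  All fixtures are generated in code.

strip_validation <- function(f) {
  attr(f, "validation") <- NULL
  f
}

EXAMPLE_SEQ <- "GSHMKTVEVNGADASDDN"

minimal_metadata <- function(...) {
  hxms_metadata(EXAMPLE_SEQ, temperature_k = 293.15, ph_read = 6.0,
                d2o_saturation = 0.91, ...)
}

minimal_file <- function(...) {
  hxms_file(minimal_metadata(...),
            hxms_records(start = 1, end = 10, time_sec = c(0, 60),
                         uptake = c(0, 1.35)))
}

# fixed-point numerics that survive serialization at k decimals
rand_fixed <- function(n, lo, hi, digits) {
  as.numeric(sprintf(paste0("%.", digits, "f"), stats::runif(n, lo, hi)))
}

# A random valid document whose values sit exactly on the serialization
# grid (uptake 2 decimals, envelope intensities multiples of 0.001), so
# read(write(f)) reproduces f exactly.  Uses the current RNG stream.
random_valid_file <- function() {
  len <- sample(12:30, 1)
  seq_aa <- paste(sample(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]],
                         len, replace = TRUE), collapse = "")
  md <- hxms_metadata(
    seq_aa,
    temperature_k = rand_fixed(1, 274, 310, 2),
    ph_read = rand_fixed(1, 5, 9, 2),
    d2o_saturation = rand_fixed(1, 0.5, 1, 2),
    protein_name = if (stats::runif(1) < 0.5) "generated protein" else NULL,
    protein_state = if (stats::runif(1) < 0.5) "APO" else NULL,
    remarks = if (stats::runif(1) < 0.3)
      data.frame(title = "NOTE", body = "property-generated document")
      else NULL)
  n <- sample(1:8, 1)
  start <- sample(seq_len(len - 5L), n, replace = TRUE)
  end <- pmin(start + sample(3:8, n, replace = TRUE), len)
  with_ptm <- stats::runif(1) < 0.4
  ptm_dict <- if (with_ptm) c("0001" = "Phosphoryl STY (18)") else character()
  full <- stats::runif(1) < 0.5
  envelope <- if (full) {
    lapply(seq_len(n), function(i) {
      k <- sample(3:9, 1)
      as.vector(stats::rmultinom(1, 1000, stats::runif(k) + 0.1)) / 1000
    })
  } else NULL
  hxms_file(
    md,
    hxms_records(
      start = start, end = end,
      time_sec = sample(c(0, 60, 600, 3600, Inf), n, replace = TRUE),
      uptake = rand_fixed(n, -0.25, 6, 2),
      mod = sample(c("A", "A", "B"), n, replace = TRUE),
      rep = sample(0:2, n, replace = TRUE),
      ptm_id = if (with_ptm) sample(c("0000", "0001"), n, replace = TRUE)
               else "0000",
      envelope = envelope),
    ptm_dict = ptm_dict)
}
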