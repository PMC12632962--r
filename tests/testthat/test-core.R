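test_that("a minimal valid document produces an empty report", {
  report <- hxms_validate(minimal_file())
  expect_s3_class(report, "hxms_validation_report")
  expect_equal(nrow(report), 0L)
})

test_that("missing required metadata is reported by its file-format title", {
  md <- hxms_metadata(EXAMPLE_SEQ, temperature_k = NA, ph_read = 6.0,
                      d2o_saturation = 0.91)
  report <- hxms_validate(hxms_file(md))
  expect_equal(nrow(report), 1L)
  expect_equal(report$severity, "ERROR")
  expect_equal(report$message, "required metadata missing: TEMPERATURE (K)")
})

test_that("record indices must increase by exactly 1 from 0", {
  f <- minimal_file()
  f$records <- hxms_records(start = 1, end = 10, time_sec = c(0, 60, 600),
                            uptake = c(0, 1, 2), index = c(0L, 1L, 3L))
  f$metadata <- minimal_metadata()
  report <- hxms_validate(f)
  expect_equal(nrow(report), 1L)
  expect_match(report$locator, "record 3")
  expect_match(report$message, "INDEX")
})

test_that("a PTM_ID without a dictionary entry is a dangling reference", {
  f <- minimal_file()
  f$records$ptm_id[2] <- "0007"
  report <- hxms_validate(f)
  expect_equal(sum(report$severity == "ERROR"), 1L)
  expect_match(report$message[1], "0007")
  expect_match(report$message[1], "PTM dictionary")
})

test_that("every single-field corruption of a valid file adds a violation", {
  base <- minimal_file()
  expect_equal(nrow(hxms_validate(base)), 0L)

  corruptions <- list(
    temperature_negative = function(f) {
      f$metadata$temperature_k <- -1
      f
    },
    d2o_above_one = function(f) {
      f$metadata$d2o_saturation <- 1.5
      f
    },
    d2o_zero = function(f) {
      f$metadata$d2o_saturation <- 0
      f
    },
    sequence_illegal_char = function(f) {
      f$metadata$protein_sequence <- "GSHMZ"
      f
    },
    sequence_missing = function(f) {
      f$metadata$protein_sequence <- NA_character_
      f
    },
    span_past_sequence_end = function(f) {
      f$records$end[1] <- 99L
      f
    },
    span_reversed = function(f) {
      f$records$start[2] <- 11L
      f
    },
    mod_lowercase = function(f) {
      f$records$mod[1] <- "a"
      f
    },
    mod_two_letters = function(f) {
      f$records$mod[1] <- "AB"
      f
    },
    rep_negative = function(f) {
      f$records$rep[1] <- -1L
      f
    },
    ptm_id_short = function(f) {
      f$records$ptm_id[1] <- "12"
      f
    },
    time_negative = function(f) {
      f$records$time_sec[1] <- -5
      f
    },
    index_gap = function(f) {
      f$records$index[2] <- 5L
      f
    },
    mixed_envelopes = function(f) {
      f$records$envelope[[1]] <- c(0.5, 0.5)
      f
    },
    ptm_dict_reserved_id = function(f) {
      f$ptm_dict <- c("0000" = "illegal entry")
      f
    },
    envelope_sum_off = function(f) {
      f$records$envelope <- list(c(0.5, 0.4), c(0.5, 0.4))
      f
    }
  )
  for (name in names(corruptions)) {
    broken <- corruptions[[name]](base)
    report <- hxms_validate(broken)
    expect_gte(sum(report$severity == "ERROR"), 1L)
  }
})

test_that("duplicate record keys are a warning, not an error", {
  f <- minimal_file()
  f$records <- hxms_records(start = 1, end = 10, time_sec = c(60, 60),
                            uptake = c(1.0, 1.1))
  report <- hxms_validate(f)
  expect_equal(sum(report$severity == "ERROR"), 0L)
  expect_equal(sum(report$severity == "WARNING"), 1L)
  expect_match(report$message[report$severity == "WARNING"], "duplicate")
})

test_that("an envelope sum slightly off unity warns instead of erroring", {
  f <- minimal_file()
  f$records$envelope <- list(c(0.6, 0.403), c(0.6, 0.403))  # sum 1.003
  report <- hxms_validate(f)
  expect_equal(sum(report$severity == "ERROR"), 0L)
  expect_gte(sum(report$severity == "WARNING"), 1L)
})

test_that("peptide_sequence honours inclusive 1-based spans", {
  f <- minimal_file()
  expect_equal(peptide_sequence(f, 1), "GSHMKTVEVN")
  f$records$start[1] <- 1L
  f$records$end[1] <- 1L
  expect_equal(peptide_sequence(f, 1), "G")
})

test_that("peptide_sequence rejects out-of-range spans naming the record", {
  f <- minimal_file()
  f$records$start[1] <- 5L
  f$records$end[1] <- 4L
  expect_error(peptide_sequence(f, 1), "INDEX 0")
  f$records$start[1] <- 1L
  f$records$end[1] <- 100L
  expect_error(peptide_sequence(f, 1), "span")
})

test_that("peptide length equals end - start + 1 over random spans", {
  set.seed(101)
  md <- minimal_metadata()
  len <- nchar(EXAMPLE_SEQ)
  for (i in 1:50) {
    start <- sample.int(len, 1)
    end <- start + sample.int(len - start + 1, 1) - 1L
    f <- hxms_file(md, hxms_records(start, end, 0, 0))
    expect_equal(nchar(peptide_sequence(f, 1)), end - start + 1)
  }
})
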