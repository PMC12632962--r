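dialect_names <- function() hxms_dialects()$name

spectra_dialects <- function() {
  d <- hxms_dialects()
  d$name[d$carries_spectra]
}

test_that("every dialect fixture converts to its ground-truth document", {
  exp <- synthetic_experiment()
  for (d in dialect_names()) {
    fx <- emit_dialect_file(exp, d)
    mode <- if (d %in% spectra_dialects()) "full_spectrum" else "centroid"
    got <- suppressWarnings(
      convert_hxms(fx$text, d, metadata = fx$metadata, output_mode = mode))
    expect_equal(got, fx$truth, tolerance = 1e-9)
    expect_equal(nrow(hxms_validate(got)[
      hxms_validate(got)$severity == "ERROR", ]), 0L)
  }
})

test_that("row enumeration drives the record count and indices", {
  exp <- synthetic_experiment(peptides = list(c(1L, 10L), c(9L, 18L)),
                              timepoints_sec = c(0, 60, Inf),
                              n_replicates = 1L)
  fx <- emit_dialect_file(exp, "dynamx")
  f <- convert_hxms(fx$text, "dynamx", metadata = fx$metadata)
  expect_equal(nrow(f$records), 6L)
  expect_equal(f$records$index, 0:5)
  expect_equal(f$records$time_sec, rep(c(0, 60, Inf), 2))
})

test_that("recomputed uptake honours the missing-zero replicate-averaging rule", {
  exp <- synthetic_experiment(n_replicates = 3L, missing_zero_rep = 2L)
  fx <- emit_dialect_file(exp, "workbench")
  got <- convert_hxms(fx$text, "workbench", metadata = fx$metadata,
                      output_mode = "full_spectrum")
  expect_equal(got, fx$truth, tolerance = 1e-9)
  rec <- got$records
  expect_equal(sum(rec$rep == 2 & rec$time_sec == 0), 0L)
  # replicates that do have a zero point sit at uptake exactly 0 there
  expect_true(all(rec$uptake[rec$time_sec == 0] == 0))
})

test_that("PTM annotations build the dictionary in first-appearance order", {
  exp <- synthetic_experiment(
    ptms = list(list(peptide = 1L, content = "Phosphoryl STY (18)"),
                list(peptide = 3L, content = "Acetyl K (12)")))
  fx <- emit_dialect_file(exp, "dynamx")
  f <- convert_hxms(fx$text, "dynamx", metadata = fx$metadata)
  expect_equal(f$ptm_dict,
               c("0001" = "Phosphoryl STY (18)", "0002" = "Acetyl K (12)"))
  rec <- f$records
  expect_true(all(rec$ptm_id[rec$start == 1] == "0001"))
  expect_true(all(rec$ptm_id[rec$start == 9] == "0002"))
  expect_true(all(rec$ptm_id[rec$start == 5] == "0000"))
  # dialects that cannot carry PTMs drop them silently
  fx2 <- emit_dialect_file(exp, "hdexaminer")
  f2 <- convert_hxms(fx2$text, "hdexaminer", metadata = fx2$metadata)
  expect_length(f2$ptm_dict, 0L)
  expect_true(all(f2$records$ptm_id == "0000"))
})

test_that("minute-based exposures convert to seconds and MAX to inf", {
  csv <- paste(
    "Protein,Start,End,Sequence,Modification,State,Exposure,File,Uptake",
    "p,1,10,GSHMKTVEVN,,APO,0,r1.raw,0.0",
    "p,1,10,GSHMKTVEVN,,APO,0.5,r1.raw,0.8",
    "p,1,10,GSHMKTVEVN,,APO,MAX,r1.raw,3.1",
    sep = "\n")
  rows <- parse_dialect("dynamx", paste0(csv, "\n"))
  expect_equal(rows$time_sec, c(0, 30, Inf))
  expect_equal(rows$rep, c(0L, 0L, 0L))
})

test_that("schema problems are reported as such", {
  expect_error(parse_dialect("dynamx", "Start,End\n1,10\n"),
               class = "hxms_schema_error")
  expect_error(parse_dialect("nope", "x\n1\n"),
               class = "hxms_schema_error")
  csv <- paste(
    "Protein,Start,End,Sequence,Modification,State,Exposure,File,Uptake",
    "p,1,ten,GSHMKTVEVN,,APO,0,r1.raw,0.0", sep = "\n")
  expect_error(parse_dialect("dynamx", paste0(csv, "\n")), "row 1")
  expect_error(parse_dialect("dynamx",
                             "Protein,Start,End,Sequence,Modification,State,Exposure,File,Uptake\n"),
               "no data rows")
})

test_that("state filtering selects rows or splits multi-state input", {
  csv <- paste(
    "Protein,Start,End,Sequence,Modification,State,Exposure,File,Uptake",
    "p,1,10,GSHMKTVEVN,,APO,0,r1.raw,0.0",
    "p,1,10,GSHMKTVEVN,,APO,1,r1.raw,1.2",
    "p,1,10,GSHMKTVEVN,,HOLO,0,r1.raw,0.0",
    "p,1,10,GSHMKTVEVN,,HOLO,1,r1.raw,0.8",
    sep = "\n")
  md <- hxms_metadata("GSHMKTVEVNGADASDDN", 293.15, 6.0, 0.91)
  apo <- convert_hxms(paste0(csv, "\n"), "dynamx", metadata = md,
                      state_filter = "APO")
  expect_s3_class(apo, "hxms_file")
  expect_equal(apo$metadata$protein_state, "APO")
  expect_equal(nrow(apo$records), 2L)
  both <- convert_hxms(paste0(csv, "\n"), "dynamx", metadata = md)
  expect_named(both, c("APO", "HOLO"))
  expect_equal(both$HOLO$records$uptake, c(0.0, 0.8))
  expect_error(convert_hxms(paste0(csv, "\n"), "dynamx", metadata = md,
                            state_filter = "BOUND"),
               class = "hxms_schema_error")
})

test_that("spectrum output from a centroid-only dialect is a capability error", {
  exp <- synthetic_experiment()
  fx <- emit_dialect_file(exp, "dynamx")
  expect_error(convert_hxms(fx$text, "dynamx", metadata = fx$metadata,
                            output_mode = "full_spectrum"),
               class = "hxms_capability_error")
})

test_that("the custom CSV is self-contained", {
  exp <- synthetic_experiment()
  fx <- emit_dialect_file(exp, "custom")
  req <- read_custom_csv(fx$text)
  expect_s3_class(req, "hxms_conversion_request")
  expect_equal(req$metadata$d2o_saturation, 0.91)
  expect_equal(req$metadata$temperature_k, 293.15)
  expect_equal(req$metadata$protein_sequence, exp$protein_sequence)
  f <- convert_hxms(fx$text, "custom", output_mode = "full_spectrum")
  expect_equal(f, fx$truth, tolerance = 1e-9)
  expect_false(is.null(f$records$envelope[[1]]))
})

test_that("custom CSVs without required metadata keys list the required set", {
  txt <- paste("PROTEIN_SEQUENCE,GSHMKTVEVNGADASDDN",
               "START,END,SEQUENCE,MOD,REP,PTM_CONTENT,TIME(SEC),UPTAKE,ENVELOPE",
               "1,10,GSHMKTVEVN,A,0,,0,0.0,", sep = "\n")
  err <- tryCatch(read_custom_csv(paste0(txt, "\n")), error = identity)
  expect_s3_class(err, "hxms_schema_error")
  expect_match(conditionMessage(err), "TEMPERATURE \\(K\\)")
  expect_match(conditionMessage(err), "D2O_SATURATION")
})

test_that("a peptide sequence disagreeing with its span raises a warning", {
  csv <- paste(
    "Protein,Start,End,Sequence,Modification,State,Exposure,File,Uptake",
    "p,1,10,WRONGPEPTI,,APO,0,r1.raw,0.0", sep = "\n")
  md <- hxms_metadata("GSHMKTVEVNGADASDDN", 293.15, 6.0, 0.91)
  expect_warning(convert_hxms(paste0(csv, "\n"), "dynamx", metadata = md),
                 "disagrees")
})

test_that("conversion content is idempotent through a write-read cycle", {
  exp <- synthetic_experiment()
  for (d in dialect_names()) {
    fx <- emit_dialect_file(exp, d)
    f <- suppressWarnings(convert_hxms(fx$text, d, metadata = fx$metadata))
    g <- read_hxms(write_hxms(f))
    tuple <- function(x) x$records[, c("start", "end", "mod", "rep",
                                       "time_sec")]
    expect_equal(tuple(g), tuple(f))
    # uptake survives to serialization precision (2 decimals)
    expect_equal(g$records$uptake, as.numeric(sprintf("%.2f",
                                                      f$records$uptake)))
  }
})

test_that("centroid-mode uptakes equal full-spectrum centroid differences", {
  exp <- synthetic_experiment(missing_zero_rep = 1L)
  for (d in spectra_dialects()) {
    fx <- emit_dialect_file(exp, d)
    cen <- convert_hxms(fx$text, d, metadata = fx$metadata,
                        output_mode = "centroid")
    ful <- convert_hxms(fx$text, d, metadata = fx$metadata,
                        output_mode = "full_spectrum")
    expect_equal(cen$records$uptake, ful$records$uptake, tolerance = 1e-6)
    expect_true(all(vapply(cen$records$envelope, is.null, logical(1))))
  }
})

test_that("fixture emission is byte-deterministic in its seed", {
  exp <- synthetic_experiment(seed = 7L)
  for (d in c("dynamx", "hdexaminer")) {
    a <- emit_dialect_file(exp, d)
    b <- emit_dialect_file(exp, d)
    expect_identical(a$text, b$text)
    expect_identical(write_hxms(a$truth), write_hxms(b$truth))
  }
  other <- emit_dialect_file(synthetic_experiment(seed = 8L), "dynamx")
  expect_false(identical(other$text, emit_dialect_file(exp, "dynamx")$text))
})
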