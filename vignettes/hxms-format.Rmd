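---
title: "The HXMS format: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The HXMS format: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hxmsr)
```

## What the format stores and why

Hydrogen-deuterium exchange mass spectrometry follows the replacement of
backbone amide hydrogens by deuterium over an incubation time course.
For each proteolytic peptide the instrument yields an isotopic mass
envelope — relative intensities over consecutive isotope peaks — which
shifts to higher mass as deuterium is incorporated. Most analysis
software reduces this to a single centroid per timepoint, losing the
shape information needed to resolve sub-populations and to do
quantitative ensemble analysis.

An HXMS document keeps the whole picture in one human-readable text
file, in three sections, always in this order:

* a **metadata** section of tab-delimited lines
  (`METADATA<TAB>TITLE<TAB>VALUE`, or `REMARK` for free-form notes)
  carrying the protein sequence, optional name and state, and the three
  numbers without which exchange data cannot be interpreted or
  back-exchange-corrected later: labeling temperature in Kelvin, the
  uncorrected pH-meter reading of the deuterated buffer, and the D2O
  saturation as a fraction in (0, 1];
* an **experimental data** section of fixed-width `TP` lines, one per
  peptide x distribution mode x replicate x timepoint, with character
  widths 12 (TITLE), 8 (INDEX), 7 (MOD), 7 (START), 7 (END), 5 (REP),
  8 (PTM_ID), 16 (TIME(SEC)) and 9 (UPTAKE), the envelope following
  unbounded as comma-separated intensities;
* a **PTM dictionary** section of `PTM` lines mapping each 4-digit
  identifier used in the records to a textual description
  (`"0000"` is reserved for "no PTM" and never appears as an entry).

Spans are 1-based and inclusive of both ends, so a record with START 1
and END 10 covers the first ten residues and
`peptide_sequence()` returns a string of length `end - start + 1`.
Record indices run 0, 1, 2, … in file order. Times are serialized in
scientific notation with six fractional digits (`0.000000e+00`); the
fully deuterated control, which downstream tools need for back-exchange
correction, is the distinguished time `inf`. A document is either
centroid-level (no envelopes) or full-spectrum (all envelopes); mixed
documents are rejected because consumers could not tell which records to
trust for shape analysis.

### Decisions where the format description is open

Two details are under-determined by the format's written description and
are fixed here as documented conventions:

* **INDEX scope.** Indices are file-wide serials, not per-peptide
  counters, and every physical line — including each mode of a bimodal
  peptide — gets its own index. This makes the index a stable record
  locator for validators and error messages.
* **Envelope precision.** The envelope field's width specification is
  ambiguous ("4 per peak" could count characters or digits). We print
  three decimals per peak, which matches every worked example
  (`0.527,0.298,...`), and parse at full precision on input.

## Envelope arithmetic

Peak spacing is treated as exactly 1 Da in index units; charge-state
deconvolution is assumed done upstream, which is how the supported
programs export per-peptide spectra. The centroid is the
intensity-weighted first moment over peak indices 0, 1, 2, …

```{r}
envelope_centroid(c(0.527, 0.298, 0.116, 0.036, 0.000, 0.023, 0.000))
```

and deuterium uptake at time *t* is `centroid(t) - centroid(0)`,
computed per peptide and replicate, so uptake at 0 s is exactly zero and
negative uptake (back-exchange noise) is representable. Uptake is held
at full precision in memory and rounded to two decimals only at
serialization, so chained computations never accumulate rounding.

When a replicate lacks its own 0 s sample — common when a run is lost —
`zero_reference()` substitutes the arithmetic mean of the zero centroids
of the replicates that do have one:

```{r}
a <- centroid_series(1, 10, c(0, 60), c(0.70, 2.0), rep = 0)
b <- centroid_series(1, 10, c(0, 60), c(0.80, 2.1), rep = 1)
d <- centroid_series(1, 10, 60, 2.2, rep = 2)
zero_reference(list(a, b, d))
```

Modes of a bimodal peptide raise one more question the format leaves
open: zero-time samples are typically unimodal, so a mode-`B` series has
no zero of its own. Our convention — documented, not mandated by the
format — is to reference such modes to the mode-`A` zero of the same
replicate (or the replicate-averaged mode-`A` zero). This is the
physically sensible choice because at 0 s the two sub-populations have
not yet diverged.

## Serialization choices

Writing is strict, reading liberal. The writer emits fixed-width,
left-justified, space-padded data lines (the metadata section is
tab-delimited, following the format's two different line grammars) and
refuses any document with ERROR-level validation problems, so a written
file always re-reads as a valid document. The reader also accepts
tab-delimited data lines, ignores blank lines and `#` comments, accepts
out-of-order sections with a warning, and attaches a validation report
rather than throwing on content problems; only structurally
uninterpretable input (unknown tags, unparseable time tokens) is a parse
error, reported with its line number.

Three numeric details matter for bit-exact round trips:

* **Envelope quantization.** Printed envelopes must sum to 1.000 at
  their own precision, as in the worked examples. Rounding each peak
  independently to three decimals frequently produces 0.999 or 1.001,
  so the writer quantizes peaks onto the 0.001 grid by largest
  remainder before printing.
* **Metadata spelling.** Values read from a file keep their verbatim
  text (`"6.0"` stays `"6.0"`, not `"6"`), so read-then-write is
  byte-identical even where R's default numeric formatting would differ.
* **Validation bands.** An envelope sum within 1e-3 of unity is
  accepted silently; a deviation in (1e-3, 1e-2] is a WARNING
  (suspicious but plausibly un-normalized input); beyond 1e-2 it is an
  ERROR. Duplicate (START, END, TIME, REP, MOD) combinations are a
  WARNING, since the format does not forbid them.

## Converters

`convert_hxms()` turns exports from four analysis programs, plus a
self-contained custom CSV, into validated documents. Column schemas are
shipped as per-dialect configuration (`hxms_dialects()`), not hard-coded
parsing logic, because vendors change export headers between versions;
the maps in this package are documented conventions, versioned with the
package, and a user facing a different export version can rename columns
to match. Capabilities differ by dialect:

| dialect      | uptake            | PTMs | spectra |
|--------------|-------------------|------|---------|
| dynamx       | reported directly | yes  | no      |
| biopharma    | reported directly | no   | no      |
| workbench    | recomputed        | yes  | yes     |
| hdexaminer   | recomputed        | no   | yes     |
| custom       | reported directly | yes  | yes     |

For the dialects that do not report uptake, the converter recomputes it
from centroids (taken from the export's centroid column, or from the
envelope's first moment when only spectra are present) using the
zero-reference rule above. DynamX-style exposures are minutes and are
converted to seconds; labels like `MAX` and `Full-D` map to `inf`.
Replicates come from a run/file identifier column where the dialect has
one (string identifiers are numbered by first appearance); a dialect
without one numbers the rows of each (peptide, state, time) group in
input order and warns, since that inference is fragile. Distinct
modification strings become PTM dictionary entries `0001`, `0002`, … in
first-appearance order over the sorted records, making the assignment a
pure function of the input bytes. Multi-state exports yield one document
per state; records are sorted by (start, end, time, replicate, mode).

Two schema decisions go beyond what the real programs document: the
HDX Workbench-style map carries an explicit `Population` column (as the
HDExaminer-style map does) so bimodal peptides can be expressed, and the
custom CSV embeds its metadata as `KEY,VALUE` rows above the data header
so a single file is a complete conversion request.

## The synthetic-data generator

`synthetic_experiment()` fixes the study conditions for all tests and
demos. Its defaults describe a small but complete experiment: the
18-residue model sequence `GSHMKTVEVNGADASDDN` covered by three
overlapping peptides (1–10, 5–14, 9–18); a time course of 0 s, 60 s,
600 s and the fully deuterated control; two replicates; labeling at
293.15 K, pH(read) 6.0, 91% D2O — the worked-example conditions of the
format; per-peptide rate constants 0.05, 0.005 and 5e-4 s⁻¹ so that the
time course spans nearly-complete, partial and barely-started exchange;
and intensity noise with standard deviation 0.005, the scale of a clean
spectrum. Optional hard cases cover everything the format supports: a
replicate missing its 0 s sample, a bimodal peptide (minor-population
rate 0.5 s⁻¹), and PTM annotations.

Envelopes follow a binomial model: each of a peptide's exchangeable
sites (its length minus the two fast-exchanging N-terminal residues and
any prolines) is deuterated independently with probability
`p(t) = s·(1 − e^{−kt})`, with `p = s` for the fully deuterated control,
where `s` is the D2O saturation. The model was chosen because its
centroid has the closed form `n·p`, giving an analytic oracle for the
envelope arithmetic:

```{r}
envelope_centroid(simulate_envelope(4, 0.5))  # exactly n * p = 2
```

What the generator deliberately does **not** emulate: site-specific
intrinsic exchange rates and their sequence dependence, EX1/EX2
kinetic regimes beyond a fixed two-population mixture, back-exchange
during workup, charge-state or mass-accuracy effects, and peak-picking
artifacts. Passing tests therefore demonstrate that the format, the
arithmetic and the converters are correct on well-formed data with
realistic shapes — not that any upstream peak assignment is.

Ground truth for fixture files is computed with plain loops, separately
from the library code under test, on exactly the string-rounded numbers
the emitted CSV carries (envelopes at six decimals, direct uptake at
four); converter output must reproduce it to 1e-9. The same experiment
object always emits byte-identical files (the generator seeds a private
RNG stream and restores the session's), so every test is reproducible.

## Problem sizes and limitations

The shipped suites use the default 24-record experiment and variants
with three replicates, a 200-document read/write round-trip property
run, and a binomial centroid grid over n = 1…30 and p = 0, 0.1, …, 1 —
sizes chosen to exercise every code path while keeping the whole suite
near ten seconds.

Known limitations: raw instrument files (mzML or vendor formats) are out
of scope — input starts at the exported peptide tables; back-exchange
correction is not performed (the format stores the `inf` control records
so downstream tools can do it); protection-factor inference and other
downstream analyses are consumers of HXMS files, not part of this
package; and the dialect maps target one export layout per program
rather than bit-faithful emulation of every vendor version.
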