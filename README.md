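# hxmsr

Tools for the **HXMS** text format for hydrogen-deuterium exchange mass
spectrometry (HX/MS) data.

HX/MS measures how fast a protein's backbone amide hydrogens exchange for
deuterium in D2O, reporting on conformation and stability. In practice the
field stores results in mutually incompatible, mostly centroid-level
exports from whichever analysis program the lab uses, which makes data
hard to share and throws away the full isotopic mass envelopes that
quantitative methods need. The HXMS format addresses this with a single
lightweight, human-readable file holding three sections:

1. **Metadata** — protein sequence, name and state, labeling temperature
   (K), pH(read) of the deuterated buffer, D2O saturation, plus free-form
   remarks;
2. **Timepoint records** — one fixed-width `TP` line per peptide /
   distribution mode / replicate / timepoint, with the peptide span
   (1-based, inclusive), a 4-digit PTM identifier, the incubation time in
   scientific notation (`inf` for the fully deuterated control), the
   deuterium uptake, and optionally the full isotopic envelope as
   unit-sum peak intensities;
3. **PTM dictionary** — `PTM` lines resolving each identifier to a
   description such as `Phosphoryl STY (18)`.

The quantities at the core of the format are the envelope **centroid**
(the intensity-weighted first moment over isotope peaks *i* = 0, 1, 2, …,
in Daltons from the first reported peak),

    c = Σᵢ i·pᵢ / Σᵢ pᵢ

and the **deuterium uptake** of a peptide at time *t*, defined per
peptide and replicate as the centroid shift from the zero timepoint:

    D(t) = c(t) − c(0)

so the 0 s record itself always carries uptake 0.00. A replicate missing
its 0 s sample is referenced to the arithmetic mean of the zero centroids
of the replicates that have one.

The package provides:

- a validated in-memory document model (`hxms_metadata()`,
  `hxms_records()`, `hxms_file()`, `hxms_validate()`);
- a bit-exact fixed-width writer and tolerant reader (`write_hxms()`,
  `read_hxms()`);
- envelope/centroid/uptake math (`normalize_envelope()`,
  `envelope_centroid()`, `compute_uptake()`, `zero_reference()`);
- converters for five export dialects — DynamX-, HDExaminer-,
  HDX Workbench- and BioPharma Finder-style CSVs plus a self-contained
  custom CSV (`convert_hxms()`, `hxms_dialects()`, `read_custom_csv()`);
- a deterministic synthetic-experiment generator with independent ground
  truth (`synthetic_experiment()`, `emit_dialect_file()`,
  `simulate_envelope()`);
- a command-line interface (`hxms_cli()`; installed script `exec/hxms`)
  with `convert`, `validate`, `info` and `demo` subcommands.

## Worked example

```r
library(hxmsr)

doc <- read_hxms(system.file("extdata", "example.hxms", package = "hxmsr"))
head(doc$records[, c("index", "mod", "start", "end", "rep",
                     "ptm_id", "time_sec", "uptake")], 4)
#>   index mod start end rep ptm_id time_sec uptake
#> 1     0   A     1  10   0   0000        0   0.00
#> 2     1   A     1  10   1   0000        0   0.00
#> 3     2   A     1  10   0   0000       60   6.72
#> 4     3   A     1  10   1   0000       60   6.82
```

Records 1–2 are the 0 s reference measurements of peptide 1–10 in two
replicates (uptake exactly 0.00 by definition); records 3–4 show that
after 60 s in D2O the same peptide has taken up ~6.7–6.8 Da of deuterium.
The file is full-spectrum, so each record also carries its envelope:

```r
envelope_centroid(doc$records$envelope[[3]])
#> [1] 6.863842
compute_uptake(centroid_series(1, 10, time_sec = c(0, 60),
                               centroid = c(0.75, 2.10)))
#>   time_sec uptake
#> 1        0   0.00
#> 2       60   1.35
```

Converting an export and validating it from the shell:

```sh
hxms demo --dir demo                      # synthetic exports, all dialects
hxms convert --format workbench --input demo/synthetic_workbench.csv \
     --output demo/apo.hxms --mode spectrum \
     --sequence GSHMKTVEVNGADASDDN --temperature-k 293.15 \
     --ph-read 6.0 --d2o-saturation 0.91
hxms validate --input demo/apo.hxms       # "no violations", exit 0
hxms info     --input demo/apo.hxms
```

A blank custom-CSV template to fill with your own data is shipped at
`inst/extdata/custom_template.csv`; once populated it converts with
`hxms convert --format custom --input my_data.csv --output my_data.hxms`
and needs no metadata flags.

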