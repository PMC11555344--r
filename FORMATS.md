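# pifnet external file formats

All coordinates **inside** the package (function arguments and return values)
are **0-based, half-open** `[start, end)`, BED-style. Files on disk follow the
convention native to each format; 1-based formats are converted on read and
restored on write. Chromosome names are normalised to the `chr` dialect on
read (`1 -> chr1`, `MT -> chrM`) by `normalize_chrom()`.

## FASTA — `read_fasta()` / `write_fasta()`

Plain (optionally multi-line) FASTA. On read, sequences are uppercased and
each record is named by the **first whitespace-delimited word** of its header,
matching aligner behaviour. Any IUPAC letter is retained; only `A`, `C`, `G`,
`T` can match the restriction site, so `N` never produces a cut. On write,
sequences are wrapped at `width` (default 70) columns.

## Hi-C interaction files — `read_interaction_file()`

One valid read pair per line, nine whitespace-separated columns, no header:

```
read_name  strand1  chr1  pos1  frag1  strand2  chr2  pos2  frag2
```

* `pos1`/`pos2` are **1-based** on disk; converted to 0-based on read.
* `frag1`/`frag2` are ignored: fragment membership is always re-derived from
  the in-silico digestion map so the digestion and network stages agree.
* Strands are carried through but not interpreted.
* A malformed line (wrong column count, non-numeric or non-positive position)
  raises an error that names the file and the 1-based line number.
* Each file represents one sequencing replicate of one cell line; the
  `replicate_id` and `cell_line_id` labels are attached to every record and
  drive the network validity rule.
* The `has_duplicates` attribute flags repeated read names; deduplication
  (first occurrence per read name within a replicate) happens in the network
  module, not at read time.

## BED — `read_bed()` / `write_bed()`

BED3 or BED6 (`chrom start end [name score strand]`), tab-separated,
`#` comments skipped. 0-based half-open on disk, unchanged on read. `write_bed`
emits BED3 unless a non-trivial strand column is present (then BED6), with
optional extra columns appended.

## narrowPeak — `read_narrowpeak()`

Strict 10-column ENCODE narrowPeak (`BED6 + signalValue pValue qValue peak`).
Coordinates 0-based half-open on disk.

## Somatic SNV table — `read_snv_table()` / `write_snv_table()`

Tab-separated with a header:

```
sample  chrom  pos  ref  alt  [cancer_type]
```

* `pos` is **1-based** on disk; converted to 0-based on read and back on
  write.
* Only single-nucleotide substitutions are accepted: `ref` and `alt` must each
  be one of `A/C/G/T` and must differ. Indels or multi-base alleles raise an
  error.
* `cancer_type` is optional (defaults to `NA`); it feeds the cancer-type
  specificity analysis.

## Matrix tables — `read_matrix_table()` / `write_matrix_table()`

Tab-separated numeric matrices (expression counts, CNA, methylation beta
values) with a header row of sample identifiers; the first column holds row
names (gene, probe or region identifiers; header configurable on write,
default `gene_id`). Read back as a numeric `matrix` with dimnames preserved
(`check.names = FALSE`, so sample names are not mangled).

## PWM file — `write_pwm_file()` / `read_pwm_file()`

A text exchange format for position weight matrices:

```
>TF1 motif_label
A: 0.97 0.01 ...
C: 0.01 0.97 ...
G: 0.01 0.01 ...
T: 0.01 0.01 ...
```

One block per motif; header line `>tf_name motif_label` followed by exactly
four base rows (probabilities per position, columns = motif positions). Each
column must sum to 1 within tolerance.

## Interval convention helpers

* `intervals(chrom, start, end, strand)` validates and builds the canonical
  interval data.frame (`end > start >= 0`, strand in `+`/`-`/`.`).
* `overlap_fraction(a, b)` returns per-row overlap length divided by the
  length of `b` (0 across chromosomes).
* `fragment_id()` renders the canonical `"chrom:start-end"` fragment
  identifier used across all modules.
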