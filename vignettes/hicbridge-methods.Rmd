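---
title: "hicbridge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hicbridge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package models

Hi-C experiments measure pairwise contact frequencies between genomic
loci. After binning at a fixed resolution, the data form a symmetric,
extremely sparse matrix of counts over genomic bins — far too large to
hold densely (a 1 kb binning of the human genome implies on the order of
10^13 matrix cells). Two binary container families dominate practice:
the Cooler family (`.cool`, `.mcool`, `.scool`), which lays the sparse
upper triangle out in an HDF5 file with a compressed-sparse-row (CSR)
index, and `.hic`, which partitions each chromosome pair into a grid of
zlib-compressed blocks addressed by a master index in the file footer.

hicbridge reads and writes both families natively and presents one query
interface over them, so that code written against a `contact_file` never
needs to know which container is underneath. The toolkit layer supplies
the operations a practitioner chains together around storage: ingesting
read-pair text into matrices, merging replicates, coarsening to new
resolutions, converting between containers, iterative-correction (ICE)
balancing, and distance-decay expected profiles for observed/expected
(O/E) views.

# Coordinate and storage conventions

* Coordinates are **0-based, half-open** everywhere, including region
  strings on the command line (`chr1:0-10,000,000` covers the first ten
  megabases). The convention matches the Cooler ecosystem; region
  strings are taken literally rather than guessing a 1-based intent, and
  this choice is documented rather than configurable.
* Global bin ids are assigned 0-based, chromosome by chromosome in
  reference order; the last bin of each chromosome may be truncated.
* Matrices are **symmetric-upper**: only pixels with `bin1_id <=
  bin2_id` are stored; lower-triangle views are materialized only in
  dense output. Pixels are canonicalized at ingestion.
* Counts are tagged integer or real per file and promote to real under
  any normalization. Integer counts are stored as HDF5 32-bit integers
  and `.hic` int16 block values where they fit (falling back to float32
  blocks otherwise); real counts round-trip exactly as float32 in `.hic`
  blocks and double precision in Cooler.
* Cooler balancing vectors are multiplicative (`count * w1 * w2`);
  `.hic` vectors (VC, KR, SCALE) are divisive (`count / (w1 * w2)`).
  Divisive vectors imported into Cooler files keep their convention and
  are tagged with a per-column `divisive_weights` attribute — a local,
  documented convention, since the Cooler schema itself has no tag for
  this.

# The `.hic` implementation

Version 8 files are written: header, per-chromosome-pair matrix records
whose blocks sit on a fixed 256x256-bin grid (format-legal; readers must
honor the counts declared in each record rather than assume a grid),
zlib level-6 block compression, a footer holding the master index, one
expected-value vector per resolution (the implicit NONE normalization),
and optional stored normalization vectors. The list-of-rows record
encoding is always used; int16 values are chosen per block whenever
every count is a whole number below 2^15. The "All" pseudo-chromosome
is neither written nor exposed on read.

Version 9 files are read best-effort: the header and footer width
changes (64-bit chromosome lengths and sizes, float32 expected and
normalization vectors) and the per-block integer-position flags are
implemented, but the v9 diagonal block numbering for intra-chromosomal
matrices is not; the v9 read path instead decompresses every indexed
block of the queried pair and filters. That is correct but not
minimal-I/O, which is acceptable at the scales this package targets.
Files that are neither version 8 nor 9 fail loudly on open; nothing is
silently misread.

# Query semantics

`fetch()` resolves ranges to bin spans and returns a lazy selector.
Symmetric queries (one range, or two identical ranges) return only
upper-triangle pixels. Asymmetric queries return every stored pixel
whose canonical or mirrored orientation intersects the query rectangle;
if the first range follows the second in genome order the query is
transposed internally and answered canonically, with a `transposed`
flag on the selector. Dense tiles mirror symmetric queries across the
diagonal, leave absent pixels at zero, and mark rows/columns of masked
bins NaN under normalization; a configurable element limit (2^26 by
default) guards against accidentally materializing huge tiles.
Streaming traversal (`selector_chunks()`) partitions the result set
exactly — a direct phase over the first span's rows, then a mirror
phase that skips already-emitted pixels — holding one row window in
memory at a time; `selector_stats()` and the CLI `dump` are built on it.

O/E uses the per-distance expected profile: for the `.hic` backend the
stored vector, for Cooler backends a profile computed on the fly and
cached. The expected value at chromosome-local distance `d` is the
pooled mean count over all chromosomes, and a per-chromosome scale
factor rescales the pooled profile so O/E averages to one within each
chromosome. Distances beyond the stored profile clamp to its last
entry, because real `.hic` vectors are routinely shorter than the
longest chromosome.

# ICE balancing

Balancing iterates `m_i = sum_j A_ij w_i w_j` over the symmetrized
matrix, divides `m` by its mean over unmasked bins, updates `w_i <-
w_i / m_i`, and stops when the variance of the rescaled marginals drops
below the tolerance or the iteration cap is reached; a final rescale
makes the mean balanced marginal exactly one. Pre-filters mask bins
with fewer nonzero entries than `min_nnz`, bins whose marginal is zero
after dropping the first `ignore_diags` diagonals, and bins whose log
marginal lies more than `mad_max` median-absolute-deviations below the
median (skipped when the MAD is zero, e.g. for constant marginals).
Defaults — tolerance 1e-5, 500 iterations, `min_nnz` 10, `mad_max` 5,
`ignore_diags` 2 — follow common ICE practice and are all exposed on
the CLI. Summation is performed over pixels in sorted order with no
parallel reduction, so results are bit-reproducible, and `gw`, `cis`
(per-chromosome) and `trans` (inter-chromosomal) modes select the pixel
subset.

One numerical relationship is worth stating explicitly: the stop rule
bounds the *variance* of the rescaled marginals, so the coefficient of
variation of the final balanced marginals scales like the square root
of that variance (empirically about `0.5 * sqrt(tol)` on the synthetic
matrices used in the tests). A CV bound of the form `CV < 10 * tol` is
therefore only guaranteed for tolerances above 1/400, and the test
suite exercises it at `tol = 5e-3`, where the variance stop rule covers
the bound analytically. At the default 1e-5 the achieved CV is on the
order of 1e-3, which is what the square-root relationship predicts.

KR balancing is intentionally not implemented; KR vectors stored in
`.hic` files are read (divisively) and copied on conversion, never
recomputed.

# Out-of-core toolkit operations

`load_pixels()` ingests 4DN pairs, bedGraph2 or COO text. Unsorted
input is buffered to a capacity, sorted, aggregated and spilled as a
run; all runs are k-way merged with on-the-fly aggregation of equal
keys. The merge advances by a "safe key" — the smallest last-buffered
key over unexhausted inputs — so any chunk capacity yields identical
output, which the tests assert for capacities spaning four orders of
magnitude. Temporary runs carry a process-unique prefix and are removed
on success and on failure. Pre-sorted input takes a verified single
pass, and a record that breaks the order is reported by number.

Coarsening maps each pixel by chromosome-local integer division of its
bin index, so aggregation can never cross a chromosome boundary, and
sums collisions; totals are conserved exactly. Zoomify builds each
ladder target from the largest already-computed divisor — equivalent to
coarsening from base because integer aggregation is associative — and
the default ladder takes `{1,2,5} x 10^k` multiples of the base up to
10 Mbp (a documented choice; for a base that divides none of those
values the ladder is just the base). Conversion is a pure stream
translation per resolution, importing stored `.hic` normalization
vectors as divisive Cooler columns in one direction and writing `.hic`
v8 with the NONE normalization only in the other; merging files with
different references is an error, never a silent union.

# The synthetic-data generator

All tests and the acceptance script run on seeded synthetic data; no
downloads are involved. The generator emulates the two first-order
features of real Hi-C: a cis/trans mixture (a pair is intra-chromosomal
with probability `p_cis`, default 0.7) and a power-law distance decay —
cis distances in bins follow `P(s) ~ (1 + s)^-alpha` (default `alpha =
1`), the `1 + s` shift avoiding the singularity at distance zero while
keeping self-interactions possible. Chromosomes are chosen
proportionally to length; trans ends are uniform on distinct
chromosomes. The default desk-scale profile — 3 chromosomes of 1-5 Mbp,
10 kb bins, 1e5 pairs — keeps every test in seconds while populating
thousands of matrix bins; the format and query tests use a 3e4-pair
variant of the same profile, and the ICE-versus-dense-oracle checks use
two-chromosome matrices capped at 100 bins so the dense reference stays
trivial.

What the generator does **not** emulate: TADs, loops, compartments,
mappability structure, copy-number variation, or polymer physics of any
kind. Passing tests therefore demonstrate storage, query, algebraic and
convergence correctness — they do not validate biological
interpretation on real data, and feature-calling behavior downstream of
this package is out of its scope either way.

# Problem sizes and determinism

The default test run builds matrices of at most a few thousand nonzero
pixels and ~100-200 bins, answers 1000 randomized queries against both
backends plus a brute-force text-dump oracle, and completes in a few
minutes on one CPU. Every random draw is behind an explicit seed
(generators save and restore the RNG state), so identical invocations
are bit-reproducible; the CLI has no randomized code paths at all.

# Known limitations

* Remote files are not supported in either backend; asymmetric Cooler
  matrices and fragment-resolution (`FRAG`) `.hic` matrices are out of
  scope.
* `.hic` version 9 cannot be written, and v9 reads trade I/O minimality
  for correctness as described above.
* Cooler integer datasets use 32-bit ids and counts; matrices
  approaching 2^31 bins or per-cell counts would need the 64-bit
  layout used by very large production files.
* Whole files are parsed into memory for `.hic` reads; this is ample at
  desk scale but not engineered for multi-gigabyte inputs.
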