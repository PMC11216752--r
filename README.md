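# hicbridge

Hi-C experiments quantify pairwise 3D contacts across whole genomes.
After binning at a chosen resolution the data form a huge, sparse,
symmetric count matrix — at 1 kb resolution a human genome matrix has
roughly 9.5 trillion cells — stored in practice in one of two binary
container families: the HDF5-based **Cooler** family (`.cool` single
resolution, `.mcool` multi-resolution, `.scool` single-cell) or the
block-compressed **`.hic`** format. The two are mutually unintelligible,
which forces analysts either to keep duplicate code paths or to convert
through fragile intermediate text.

hicbridge is an R toolkit that treats both families as one. It provides:

* native readers **and writers** for the Cooler schema (format v3, CSR
  `bin1_offset`/`chrom_offset` indexes) and for `.hic` (version 8
  read/write, version 9 best-effort read);
* a uniform query interface: `open_contacts()` auto-detects the backend
  and `fetch()` answers 2-D genomic range queries through a lazy pixel
  selector with raw, balanced, expected, or observed/expected (O/E)
  counts and sparse (`selector_to_coo()`) or dense
  (`selector_to_dense()`) output;
* toolkit operations: 4DN-pairs/bedGraph2/COO ingestion with
  out-of-core sorted aggregation (`load_pixels()`), k-way file merging
  (`merge_files()`), coarsening and multi-resolution zoomify ladders
  (`zoomify()`), and lossless conversion between containers
  (`convert()`);
* **ICE matrix balancing** (`ice_balance()`, `balance_cooler()`): the
  iterative correction that finds per-bin multiplicative weights `w`
  such that the balanced matrix `A_ij w_i w_j` has uniform marginals,
  with standard `min_nnz` / MAD-max / ignored-diagonal bin filters;
* per-distance expected profiles and per-chromosome scale factors
  (`compute_expected()`) driving the O/E transform;
* a seeded synthetic-data generator (`sim_params()`,
  `simulate_pairs()`, `build_fixture_set()`) producing contact maps
  with a `(1+s)^-alpha` distance decay in every supported format, so
  the entire test surface runs offline;
* a CLI (`hic_cli()`, or the `exec/hicbridge` Rscript) with
  `dump`, `load`, `convert`, `merge`, `zoomify`, `balance` and
  `validate` subcommands.

## Worked example

```r
library(hicbridge)

# a seeded synthetic contact map: 2 chromosomes, 10 kb bins, 20k pairs
p <- sim_params(seed = 7, n_chroms = 2, chrom_range = c(2e5, 4e5),
                bin_size = 1e4, n_pairs = 2e4)
m <- simulate_matrix(p)
m$table
#> <bin table: 2 chromosomes, bin size 10000 bp, 68 bins>

f <- "demo.cool"
create_cooler(f, m$table, m$pixels)
#> <cooler demo.cool: 10000 bp, 68 bins, nnz 2335>

cf <- open_contacts(f)              # backend auto-detected; .hic works too
sel <- fetch(cf, "chrS1:0-50,000")  # symmetric 5-bin query
head(as.data.frame(sel), 3)
#>   bin1_id bin2_id count
#> 1       0       0    48
#> 2       0       1    26
#> 3       0       2    21

unlist(selector_stats(fetch(cf)))   # genome-wide pass; sum == simulated pairs
#>   nnz   sum   min   max
#>  2335 20000     1   520

balance_cooler(f, ice_params(min_nnz = 2))
#> <ICE result 'weight': converged after 6 iterations (variance 2.27e-06), 0 masked>

head(selector_pixels(fetch(open_contacts(f), "chrS1:0-50,000",
                           normalization = "weight")), 3)
#>   bin1_id bin2_id      count
#> 1       0       0 0.11785969
#> 2       0       1 0.05861736
#> 3       0       2 0.04962541
```

The raw counts are interaction frequencies per bin pair; after
balancing, counts are rescaled so every (unmasked) bin's marginal is 1,
which removes coverage biases before comparative analysis. The same
matrix written with `write_hic_v8()` and opened with
`open_contacts(path, 10000)` answers every one of these queries
identically — that equivalence is the package's central invariant.

From a shell, the equivalent of the dump above:

```sh
exec/hicbridge dump demo.cool --range chrS1:0-50,000 --join   # bedGraph2
exec/hicbridge convert demo.cool demo.hic                     # to .hic v8
```

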