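# lesionlad

Inference of tumor-initiation dynamics from segregating DNA lesions.

A pulse of a DNA-damaging mutagen (an experimental carcinogen, or
chemotherapy) leaves lesions on both strands of every chromosome of an
exposed stem cell. Unrepaired lesions persist over several cell cycles
and, because chromosome strands segregate randomly at mitosis, the number
of lesion-bearing strands in any one descendant halves per division.
Repeated error-prone replication over a persistent lesion creates
*multiallelic variants* (MAVs: two different alternate alleles at one
site) and, on single-cell phylogenies, *phylogeny violating variants*
(PVVs: the same mutation on branches incompatible with a single origin).
The fraction of the genome carrying MAVs in a grown clone is proportional
to 2^-n, where n — the **LAD**, Lesion-to-Ancestor Divisions — is the
number of divisions between the pulse and the clone's most recent common
ancestor (MRCA).

`lesionlad` is for researchers studying early clonal expansion in
mutagen-exposed systems (chemically induced mouse tumors,
post-chemotherapy metastases, blood-colony phylogenies). It implements:

* a discrete-generation branching-process simulator of tumor initiation
  with per-generation lesion repair (total rate *r*, mutagenic part *u*),
  error-free translesion replication (rate *eps*), driver fitness
  *s = b − d*, genealogy tracking, and clonal competition (C++ core);
* a matching analytic LAD distribution `lad_pmf(s, r, u, eps)` (dynamic
  program over the driver-locus duplex states coupled to the branching
  process);
* a three-state hidden Markov model that estimates per-tumor LAD from the
  genomic distribution of MAVs via the 2^-n dilution law, accounting for
  mitotic recombination (`build_segments()`, `decode_lesion_states()`,
  `estimate_lad()`);
* cohort-level fitting with exact Poisson bands to infer the minimum
  driver selection coefficient (`lad_distribution()`, `fit_grid()`);
* a chromosome-count bound on LAD for sparse-MAV samples
  (`simulate_chrom_counts()`, `lad_bound()`);
* MAV enrichment, pair-spectrum and phasing statistics for bulk tumors
  (`expected_independent_mavs()`, `mav_spectrum_similarity()`,
  `phasing_trend_test()`);
* lesion-footprint detection on single-cell phylogenies — MAVs, PVVs,
  and the Watson-Crick strand-asymmetry anticorrelation that identifies
  sister cells one division below a pulse (`read_tree()`,
  `detect_footprints()`, `wc_anticorrelation()`,
  `lesion_node_statistics()`);
* synthetic-data generators with full ground truth for every stage
  (`gen_tumor_cohort()`, `gen_metastatic_sample()`,
  `gen_pulsed_phylogeny()`).

See the methods vignette (`vignettes/lesion-segregation-methods.Rmd`) for
the model, assumptions, and design decisions.

## Worked example

The analytic LAD distribution at the single-driver reference parameters:

```r
library(lesionlad)
lad_pmf(s = 0.6, r = 0.2, u = 0.05, eps = 0.15, n_max = 8)
#> Analytic LAD distribution (single driver)
#>   s = 0.6, r = 0.2, u = 0.05, eps = 0.15
#>   P(formed) = 0.648, truncation mass beyond n_max = 0.000648
#>      0      1      2      3      4      5      6      7      8
#> 0.0809 0.5163 0.2409 0.0982 0.0388 0.0153 0.0061 0.0024 0.0010
```

Read: under a driver conferring a 60% per-generation growth advantage,
more than half of tumors fix their MRCA at the very first post-pulse
division (LAD 1), and ~8% in the exposed cell itself (LAD 0, possible
only through mutagenic repair *u*).

Estimating LAD per tumor from generated mutation tables:

```r
co  <- gen_tumor_cohort(n_tumors = 5, seed = 42)
kar <- karyotype_synthetic()
for (i in 1:5) {
  m   <- co$tumors[[i]]
  tab <- data.frame(chrom = m$chrom, pos0 = m$pos - 1L,
                    ref = m$ref, alt = m$alt)
  tr  <- build_segments(normalize_mutations(tab, kar), kar)
  est <- estimate_lad(tr, decode_lesion_states(tr))
  cat(sprintf("tumor %d: true LAD %d, estimated %d (f_hat = %.3f)\n",
              i, co$truth$per_tumor$lad[i], est$n_hat, est$f_hat))
}
#> tumor 1: true LAD 1, estimated 1 (f_hat = 0.500)
#> tumor 2: true LAD 3, estimated 3 (f_hat = 0.127)
#> tumor 3: true LAD 1, estimated 1 (f_hat = 0.500)
#> tumor 4: true LAD 3, estimated 3 (f_hat = 0.107)
#> tumor 5: true LAD 2, estimated 2 (f_hat = 0.236)
```

`f_hat` is the estimated fraction of retained lesion strands (out of the
four strands of a homolog pair); `n_hat = round(-log2 f_hat)`.

Bounding LAD for a sparse sample — a phylogeny node carrying 67
lesion-marked sites (MAVs + PVVs) spread over 22 distinct chromosomes of
a female karyotype:

```r
lad_bound(observed_chroms = 22, M = 67,
          karyotype = karyotype_human("female"), reps = 4000, seed = 7)
#> LAD bound from 67 sites on 22 distinct chromosomes
#>   consistent LADs: 1
#>   point estimate: 1  upper bound: 1
```

So many distinct lesion-bearing chromosomes are only compatible with a
single division between the pulse and that branching point.

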