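---
title: "Promoter hexamer enrichment with a resampling null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter hexamer enrichment with a resampling null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(0)
```

## The question the package answers

When a transcription factor is overexpressed and a set of genes responds —
say, the 100 most strongly up-regulated genes under osmotic or salt stress —
the natural regulatory question is *which short DNA words are
over-represented in those genes' promoters*. Candidate words that recur more
often than chance are candidate cis-acting elements: binding sites through
which the factor (or its downstream network) may act, to be confirmed by
binding assays such as yeast one-hybrid.

`promhex` implements this analysis for hexamers. It is exhaustive rather
than motif-database-driven: every one of the $4^6 = 4096$ DNA words of
length 6, from `AAAAAA` to `TTTTTT`, is scored, and known elements (DRE,
ABRE, ARR1AT, MYBST1, ...) are attached as annotations afterwards. Working
at $k = 6$ keeps the word space exhaustive yet small enough that a
genome-scale background saturates every word's null distribution; the
machinery accepts other `k` but is tuned and tested for hexamers.

## The model

**Promoters.** A gene's promoter is the 1-kb window immediately upstream of
its transcription start: positions $-1000 \ldots -1$ relative to the
gene-feature 5' end, read 5'→3' relative to the gene (minus-strand genes are
reverse-complemented). Internally all coordinates are 0-based half-open
(BED-compatible); the $-1 \ldots -1000$ convention is translated once, at
extraction. Windows clipped at a chromosome edge are kept, shortened and
flagged, rather than dropped — dropping them would bias the background
composition.

**Counting.** Overlapping occurrences are counted with a width-6 window
sliding in steps of 1; a clean 1000-bp promoter therefore contributes
exactly $1000 - 6 + 1 = 995$ windows. Windows containing an N (masked or
ambiguous base) are excluded from both the counts and the valid-window
denominator, so masking cancels rather than distorts. Counting is
single-strand by default because promoters are already gene-oriented; the
element scanner has a `both_strands` switch.

**The resampling null ("standardized promoters").** Instead of an analytic
composition model, the expected frequency of each hexamer comes from the
background promoter universe itself: `n_replicates = 1000` independent
random subsets of `sample_size = 100` promoters are drawn (each subset
without replacement; a promoter may recur across subsets), and each
hexamer's total count per subset is recorded. The per-hexamer mean
$\mu_m$ and sample standard deviation $s_m$ (denominator $n-1$) across the
1000 replicate totals define the null frequency *per 100 promoters* and its
spread.

**The Z-score.** A focal set of $G$ promoters with aggregate count $c_m$ is
standardized to the same scale, $f_m = c_m \cdot 100 / G$ (so focal sets
need not contain exactly 100 genes), and scored as

$$ Z_m = \frac{f_m - \mu_m}{s_m}. $$

Hexamers with $s_m = 0$ get an undefined Z (never $\pm\infty$) and are
excluded from ranking. Ranks run by descending Z with lexicographic
tie-break. No multiple-testing correction is applied — the method's output
is the ranking, conventionally the top 10 — though an approximate two-sided
normal p-value column is emitted for convenience and labeled as such.

**Contrasts.** Two focal sets scored against nulls with the same
`sample_size` can be aligned motif-by-motif: `compare_enrichment()` reports
$\Delta = Z_y - Z_x$ where both are defined and partitions top-10 membership
into shared and condition-specific motifs, the numeric content of the
classic three-panel comparison (stress A vs control, stress B vs control,
stress A vs stress B).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_len` | 1000 bp | promoter length upstream of the TSS |
| `sample_size` | 100 promoters | replicate size; also the standardization unit |
| `n_replicates` | 1000 | resampled subsets behind the null |
| `seed` | required | governs every draw; no hidden RNG state |
| `max_genes` | caller's choice | head of the ranked gene list (typically 100) |
| `k` | 6 | word length; 4096 hexamers |

The defaults are the conventional settings for this analysis. With 1000
replicates, the Monte-Carlo standard error of each null mean is roughly
$s_m/\sqrt{1000} \approx 0.16$ counts for a uniform background — small
against typical effect sizes (a motif planted once per promoter in a
100-gene set shifts its count by ~100 against a null sd of ~5).

Randomness contract: replicate $r$'s draw is a pure function of
`(seed, r)` (a fixed affine reseeding per replicate), so nulls are
bit-reproducible, and the caller's RNG state is saved and restored around
every seeded operation.

## A worked example on synthetic data

The generator builds a seeded background universe and focal sets with
planted motifs, giving ground truth for every pipeline stage. Sizes here are
reduced for a fast vignette; the package's validation suite runs the full
study scale (5000 background promoters of 1000 bp, 1000 replicates, 10-seed
panels).

```{r example}
library(promhex)

cfg <- synth_config(n_background = 600, promoter_len = 1000, seed = 11)
bg  <- generate_background(cfg)

nullm <- build_null(bg$promoters, sample_size = 100, n_replicates = 300,
                    seed = 11)
nullm

# plant the novel element CGTCCA once per promoter in a 100-gene focal set
gs <- generate_geneset(cfg, motif = "CGTCCA", n_genes = 100, copies = 1)
enr <- hexamer_enrichment(gs$promoters, nullm,
                          dictionary = element_dictionary(),
                          name = "planted demo")
top_hexamers(enr, 5)[, c("motif", "observed_freq", "null_mean", "z",
                         "rank", "elements")]
```

The planted motif is recovered at rank 1 with a Z-score far above the rest
of the universe, and is annotated with its dictionary name. The same object
plots as the standard frequency-vs-Z scatter with the top motifs labeled:

```{r scatter, fig.width = 6, fig.height = 4}
plot(enr)
```

## The element dictionary and occurrence scanning

The bundled dictionary (`inst/extdata/cis_elements.tsv`, editable TSV) maps
element names to IUPAC patterns: DRE and the DRE-like variants CCTACC and
CCCCAC, ARR1AT (the printed variants GTTATT/GTGATT unified as `GTKATT`),
MYBST1 (`TATCCC`), BOXIII (`CATTT`, matched as a substring at any offset
since element length is dictionary-driven), the novel elements New3
(`CGTCCA`) and New4 (`TTCTCT`), recurrent AT-rich hexamers of lignin and
sugar-metabolism promoters, and classical bait elements. Entries whose exact
sequence is not established in the bundled sources carry canonical
literature consensus marked *external-literature, editable*; baits with no
published sequence at all are all-N placeholders, excluded from matching by
default (`include_placeholders = TRUE` restores them). Nothing in the test
suite depends on any of those entries.

`scan_geneset()` counts overlapping IUPAC-aware occurrences of every element
in every promoter and summarizes how many genes carry at least one hit:

```{r scan}
occ <- scan_geneset(gs$promoters, element_dictionary())
head(occ$summary[order(-occ$summary$fraction_with_hit), ], 5)
```

## What the synthetic generator does and does not emulate

`generate_background()` draws promoters with iid base composition (uniform
by default, configurable; a first-order Markov option exists for robustness
checks) and embeds them in a synthetic multi-contig genome with a BED
annotation constructed so that `extract_promoters()` reproduces the
generated sequences byte-for-byte — including minus-strand genes and
edge-truncated windows. `generate_geneset()` plants motifs by *overwriting*
uniformly chosen non-overlapping positions, keeping promoter length (and
hence window counts) fixed, and records ground-truth positions.

An iid background was chosen because the method's null is resampled real
promoters, not a composition model — the null adapts to whatever the
background is. Real promoter universes differ in ways the generator does not
emulate: long-range composition structure (TATA/CpG-like gradients along the
window), correlated motif co-occurrence, shared cis-regulatory architecture
between focal and background genes, and overlap of upstream windows with
neighboring gene bodies. Passing the synthetic validation therefore
demonstrates that the statistics are implemented correctly and calibrated
under their own assumptions; it does not by itself validate biological
conclusions on a real genome. For real data the background universe is an
explicit required input — all promoters vs expressed-gene promoters is a
scientific choice the package deliberately does not default.

## Numerical and degenerate-input choices

* Null sd uses the $n-1$ denominator across replicate totals; computed via
  sums of squares, clamped at 0 against rounding.
* `sd = 0` motifs: Z undefined (NA), excluded from ranking, flagged in
  printing; a fully degenerate null (background no larger than
  `sample_size`) is flagged on the object.
* Ties in Z rank lexicographically by motif, making rankings deterministic.
* Sequences shorter than 6 bases count zero windows — a valid result, not an
  error; empty promoter sets and backgrounds smaller than `sample_size` are
  errors.
* Normalization uppercases, maps U→T, and converts every other non-ACGT
  character to N, so soft-masked genomes lose windows rather than sequence
  silently.
* Focal standardization divides by the true focal-set size; a focal set of
  73 genes is scored on the same per-100 scale as one of 100.

## Design choices where the method is underdetermined

* **Overlapping occurrences are counted** (step-1 window). Exhaustive k-mer
  frequency analysis conventionally overlaps, and non-overlap would
  undercount periodic motifs; presence/absence per gene is available from
  the element scanner, so both conventions are reportable.
* **Within-replicate sampling is without replacement**: a replicate is a
  random 100-promoter subset, i.e. distinct promoters; replicates are
  independent of each other.
* **Top-set membership for contrasts is rank ≤ 10 by Z** (the conventional
  top-10 report), with an optional `z_min` filter rather than a hard
  significance threshold.
* **Gene-level TSS.** The gene feature's 5' end anchors the window;
  transcript-isoform-aware TSS selection is out of scope. Promoter/gene
  overlap filtering is exposed (`overlap_filter`) but off by default, since
  established promoter resources differ on it.
* **Scatter axes.** The single-table scatter uses observed frequency (x) vs
  Z (y); contrast panels default to the same x with a `x_var = "z"` switch
  for Z-vs-Z, and `scatter_data()` emits the numbers so either reading can
  be reproduced downstream.

## Validation scales

The test suite validates counting against a naive per-window oracle (1000
random sequences with 1% N injection) and against an independent
k-mer-frequency implementation; calibration and planted-motif recovery run
at full study scale — a 5000-promoter uniform background of 1-kb promoters,
nulls of 1000 replicates of 100, 100-gene focal sets — across a 10-seed
panel: background-only sets give mean Z in $[-0.1, 0.1]$ with 3–7% of
$|Z| \ge 1.96$, and a single planted copy per promoter is recovered at
rank 1 with $Z > 5$ in every seed. `scripts/acceptance.R` re-runs the
full-scale pipeline end to end and writes the resulting numbers as JSON.

## Known limitations

* No GC- or composition-matched background stratification; the background
  universe must already be the right reference set.
* No positional weight matrices, no position-within-promoter modeling, no
  gapped or spaced motifs.
* The normal p-values are approximations to a resampling distribution with
  finite replicates; use the Z ranking, not the p-values, for inference.
* `k ≠ 6` works but is only smoke-tested; the 4096-word hexamer space is
  the designed operating point.
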