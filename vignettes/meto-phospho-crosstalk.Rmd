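---
title: "Testing crosstalk between methionine sulfoxidation and phosphorylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing crosstalk between methionine sulfoxidation and phosphorylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metophos)
```

## The scientific question

Methionine is one of the two sulfur-containing amino acids and is readily
oxidized by mild cellular oxidants such as hydrogen peroxide, yielding
methionine sulfoxide (MetO). Unlike most oxidative damage, this
modification is enzymatically reversible (methionine sulfoxide
reductases), which makes it a candidate *regulatory* modification rather
than mere wear: an oxidation-sensitive switch sitting next to a
phosphorylation site could couple redox state to kinase signalling. The
package tests the statistical footprint such crosstalk would leave in
proteome-scale data:

1. **Co-occurrence** — proteins that carry MetO should be phosphoproteins
   more often than random protein sets of the same size, and the excess
   should survive matching for protein abundance (abundant proteins are
   easier to detect in mass spectrometry, which confounds naive overlap
   statistics).
2. **Proximity** — oxidized methionines should sit closer to phosphosites
   along the sequence than non-oxidized methionines of the same proteins,
   particularly in the `< 7` residue tail where kinase recognition motifs
   live, and the effect should persist in structured proteins (ruling out
   a trivial co-localization in disordered phosphosite clusters).
3. **Window composition** — phosphosite-centred ±7 windows should be
   methionine-poor yet MetO-rich relative to windows around
   non-phosphorylated acceptors of the same residue type, with
   position-specific hot spots (P+1, P+4) where methionine is a known
   kinase specificity determinant.
4. **Motif class** — phosphoserines with adjacent MetO should skew toward
   particular kinase classes under the standard Pro-directed /
   acidophilic / basophilic decision tree.

All coordinates are 1-based residue positions, matching UniProt and
PhosphoSitePlus conventions.

## Statistical machinery

### Empirical resampling nulls

Every headline comparison is referred to an empirical null rather than a
parametric one. A null distribution is a vector of the statistic computed
on resampled background sets; the empirical p-value uses the add-one
estimator

$$ p = \frac{1 + \#\{T_{\mathrm{null}} \ge T_{\mathrm{obs}}\}}{1 + n_{\mathrm{samples}}}, $$

which is never exactly zero. When no resampled value reaches the observed
statistic the result is reported as a bound (`is_bound = TRUE`, "p <
1/n"), mirroring the usual "p < 10^-6^" reporting style for 10^6^-sample
nulls. Tests default to 10^4^ resamples, a deliberate desk-scale choice;
`n_samples` is a plain argument wherever a practitioner wants 10^6^.

### Abundance-matched sampling

The matched null draws each background set in four strata: quartile
boundaries are computed from the *target* set's abundance distribution,
and a quarter of each sample is drawn from the background proteins whose
abundance falls within each quartile range. Ranges are closed on the
left, open on the right, with the outer ranges extended to cover the
whole axis. When the target size is not divisible by four, the remainder
is allocated one-per-stratum starting from the lowest quartile — the
sizes always sum exactly to the target size. Proteins without abundance
data are excluded from both sides and counted. Per-sample diagnostics
(mean log10 abundance, a Kolmogorov–Smirnov comparison against the
target) verify that matching actually reproduces the target profile.

### Classical tests

Welch's t (distance means), Fisher's exact test (2×2 lower-tail
contrasts), the Yates-corrected two-proportion chi-square (the "< 7
residues" proportions), and the two-sample KS test (matching diagnostics)
are delegated to the standard R implementations behind thin wrappers that
fix the degenerate-input conventions (a comparison with no information
returns p = 1 rather than `NaN`). The test suite cross-checks each
wrapper against closed-form or enumeration oracles.

## Key definitions and defaults

| quantity | definition | default |
|---|---|---|
| MetO curation | keep sulfoxide sites with oxidized fraction ≥ threshold | 0.20, boundary inclusive |
| sequence distance | positional difference `abs(i - j)`, not intervening residues | — |
| "near" a phosphosite | distance strictly `< 7` (i.e. ≤ 6 residues) | 7, configurable |
| cluster radius | phosphosites with `abs(delta) <= radius` of a Met | ±10, configurable to ±5 |
| window | offsets −7..−1, +1..+7 around an acceptor, truncated at termini | half-width 7 |
| MetO rate | MetO per 500 phosphosites at an offset | — |

Decisions worth spelling out:

* **The 20% curation boundary is inclusive** (`>= 0.20`). Whether the
  original exclusion of weakly oxidized residues was inclusive at the
  boundary is not determinable from the description, so the threshold and
  its boundary behaviour are arguments.
* **"Less than 7 residues" is strict.** ±7 windows elsewhere suggest a
  `<= 7` reading in other contexts, so the threshold is an argument; the
  default reproduces the strict reading.
* **Cluster counting uses a ±10 radius.** A "10 residue window" can also
  be read as ±5; both are supported (`radius = 5`), the radius reading is
  the default.
* **Methionines in proteins lacking the queried site kind** are excluded
  from that comparison (reported in a coverage table), never coded as
  infinite distances.
* **Truncated-window denominators are offset-specific** in the positional
  profile: positions beyond the termini leave the denominator, so
  terminal phosphosites do not deflate frequencies.
* **The positional-profile control band** is the mean ± SD across the 14
  per-offset control frequencies (pooled); per-offset control frequencies
  are returned alongside for the per-offset reading.
* **Fold enrichment** is the ratio of proportions `(k/n)/(K/N)`; a
  literal ratio-of-counts `k/K` variant exists behind a flag but is not
  scale-free and is off by default.

## The kinase-motif decision tree

Phosphoserine 15-mer windows (offsets −7..+7, `_` padding beyond termini)
are classified by a fixed-order rule cascade, first match wins:

1. P at P+1 → **Pro-directed**
2. ≥ 5 D/E within P+1..P+6 → **Acidophilic**
3. R/K at P−3 → **Basophilic**
4. D/E at P+1, P+2 or P+3 → **Acidophilic**
5. ≥ 2 R/K within P−6..P−1 → **Basophilic**
6. otherwise → **Others**

The order matters — a strongly acidic C-terminal stretch (rule 2)
pre-empts a basic residue at P−3 (rule 3) — and is locked by tests,
including an exhaustive set of single-rule and rule-pair constructions.
Ranges are inclusive. Padding never satisfies any rule; whether truncated
terminal windows should be classified at all is a judgement call, and
classifying them with inert padding is this package's convention. The
classifier accepts threonine centres via `allowed_center = c("S", "T")`
but defaults to serine, where the three classes are defined.

```{r motif-example}
w <- extract_window(paste0(strrep("A", 211), "LRAGLNCSTENMPIK"), 219)
w
classify_pser_motif(w)
nearest_distance(223, 219)  # the Met at P+4 sits four residues away
```

## The synthetic proteome generator

Real MetO-proteome and phosphoproteome compilations cannot ship with a
package, so every statistical claim is validated against a generator that
emulates the features the analyses rely on:

* **Sequences** are i.i.d. draws from a human-like residue composition
  with methionine at 2.3% of residues — the empirically rare-Met regime
  the window statistics live in.
* **Lengths** are negative binomial (default mean 450, size 2.5, floor
  50), giving the heavy right tail of real protein lengths; `Inf`
  dispersion gives fixed lengths.
* **Abundances** are log-normal (meanlog 9.2, sdlog 2.3 on the natural
  scale, i.e. about one decade of spread), the canonical shape of
  proteome abundance distributions.
* **Phosphosites** are placed per-acceptor with base probabilities S
  0.08, T 0.04, Y 0.03. These are deliberate desk-scale compromises: real
  curated phosphoproteomes have higher per-acceptor rates within
  phosphoproteins but also only cover part of the proteome; the defaults
  give a phosphoprotein fraction and site density that keep every
  downstream statistic non-degenerate at a few hundred proteins.
* **Oxidation** is per-methionine with baseline 0.067 (the order of
  observed MetO fractions among methionines of phosphoproteins under
  peroxide stress). The planted proximity effect acts on the odds scale:
  a methionine within `proximity_radius` (default 7) of a phosphosite is
  oxidized with probability `plogis(qlogis(base) + log(proximity_odds))`,
  so the effect composes with any base rate and `proximity_odds = 1` is
  exactly neutral. Oxidized fractions are uniform on [0.2, 1], so default
  curation is the identity on synthetic data.
* **Positional boost** (off by default) multiplies the phosphorylation
  probability of a serine that has a methionine at a stated offset,
  planting the P+1/P+4 coupling that the positional profile should
  recover.
* **Ubiquitination/acetylation** are per-protein flags placed on a random
  lysine, with odds multiplied by `ptm_corr_odds` (default 3) for
  MetO-carrying proteins, emulating the observed positive co-occurrence
  of the other modifications; calibration runs set it to 1.
* **Toy structures** are self-avoiding random walks with 3.8 Å steps
  (consecutive C-alpha spacing) plus a 2.0 Å pseudo side-chain atom, and
  segmental secondary-structure labels over the 8-letter DSSP alphabet.

What the generator does **not** emulate: real kinase specificity, domain
architecture, disorder, solvent accessibility, detection bias beyond
abundance, or realistic folds. Passing tests therefore demonstrate that
the *statistical machinery* is calibrated and can recover planted effects
of realistic size — not that any particular biological claim is true of
real data. Conversely, the worked stress-granule examples (the four
printed 15-mer motifs, their classes, and the Met-to-pSer offsets) are
exact deterministic checks against published values.

Reproducibility: one master seed; each protein draws its own sub-stream
(derived from the master seed and the protein index), so regenerating a
subset of proteins reproduces exactly the same sequences and sites.

## Validation experiments

Three replicated studies back the package's claims; all are ordinary
exported functions.

**Calibration** (`calibration_study`): 500 neutral replicates (all
planted effects at 1) of 400 fixed-length (300-residue) proteins; per
replicate, the empirical p of the co-occurrence overlap, of an
oxidation-label permutation test on the mean distance gap, and of the
mean Met-per-pSer window count against the serine acceptor null, each
with 2,000 resamples. The rejection rates at the 5% level should sit
within two binomial standard errors of 0.05. Two scale choices matter
here. Fixed lengths: with variable lengths, longer proteins are both more
likely to carry a MetO and more likely to be phosphoproteins, a real
confounding that is not a property of the p-value machinery being tested.
Moderate phosphosite rates (S 0.02, T 0.01, Y 0.005): the overlap
statistic is discrete, and add-one empirical p-values over a coarse
support are conservative; these rates keep the overlap count spread over
enough values for near-uniformity while leaving the phosphoprotein
fraction away from 0 and 1.

**Proximity recovery** (`proximity_recovery_study`): 200 replicates of
300 proteins with `proximity_odds = 4`; the Yates two-proportion test on
the `< 7` proportions should detect the effect in well over 80% of
replicates.

**Positional recovery** (`positional_recovery_study`): 200 replicates
with the serine phospho-probability boosted ×6 where a methionine sits at
P+1 or P+4. The ×6 boost is a pre-chosen power-analysis value: with ~800
phosphoserines per replicate and a ~17% near-phosphosite oxidation rate,
boosted offsets expect ~15–20 MetO counts against ~3 at the twelve
neutral offsets, which puts the top-2 recovery probability comfortably
above the 80% criterion while leaving visible Poisson noise.

## Numerical and degenerate-input conventions

* Empirical p-values are never 0 (add-one) and at most 1.
* Welch's test on two zero-variance samples returns p = 1 when the means
  agree and errors otherwise; Fisher's test returns p = 1 on any empty
  margin; the two-proportion test returns p = 1 when the pooled
  proportion is 0 or 1.
* Spatial nearest-acceptor ties resolve to the lowest residue index;
  quartile-boundary abundance ties fall into the left-closed stratum.
* Residues whose required atom (Met SD; Ser OG; Thr OG1; Tyr OH) is
  missing from a structure are kept in the table, marked unresolved, and
  excluded from spatial distances with a logged count; a blank DSSP
  structure column is coil.
* `X` residues are permitted in sequences and never match a modifiable
  residue.

## Problem sizes

Default test and example scales — 200–400 proteins, 2,000–10,000
resamples, 200–500 replicates — are the package's chosen desk scale: they
keep the full suite in minutes on a single core while leaving every
statistic non-degenerate. Every size is an argument, and the resampling
machinery is linear in `n_samples`, so scaling any analysis to
10^6^-sample nulls is a flag, not a code change.

## Known limitations

* The i.i.d. sequence model has no motif structure: classifier frequency
  tables on synthetic data reflect composition only, so tests assert
  normalization and planted-contrast directions, not absolute class
  frequencies.
* The abundance-matched sampler requires every stratum to hold at least
  its quota of candidates; it errors loudly rather than silently sampling
  with replacement.
* Only intra-chain spatial distances are computed; multi-chain
  assemblies are out of scope.
* Enrichment takes the annotation table as given — no ontology closure,
  no term relationships; results depend entirely on the supplied
  annotation snapshot.
* motif extraction tools (motif-x-style overrepresentation mining) are
  external: the package consumes their motif strings via the pattern
  file format (lowercase acceptor, `X` wildcard) but does not
  re-implement them.
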