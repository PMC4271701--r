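---
title: "Methods: local ancestry, haplotype migration and selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local ancestry, haplotype migration and selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hapflow analyses an admixed cohort (the motivating case is crossbred dairy
cattle descended from a few imported breeds) against parental haplotype
panels genotyped on a medium-density SNP chip. This vignette records the
models, the parameters that matter, and the design decisions taken where
the method description left choices open.

## Data model

All analyses operate on a `genotype_panel`: a phased 0/1 haplotype matrix
(two rows per diploid sample), a marker map (chromosome, 1-based bp as in
VCF), and a sample manifest assigning each sample to a population with a
role (`parental_panel` or `admixed`). Phasing is assumed done upstream;
unphased genotypes are rejected, not repaired. Sites are biallelic SNPs
only. Internally site indices are 1-based inclusive (the R convention);
BED exports are 0-based half-open.

The MAF filter retains a site when its minor allele frequency exceeds the
threshold (default 0.01) **in at least one population**. The wording "MAF
above threshold within any breed were included" is read as an OR across
populations; the AND reading would drop sites informative in a single
breed, contradicting "any ... included". The AND variant remains available
via `filter_maf(..., rule = "all")`.

## Windows and haplotype spectra

Windows are SNP-index based: `size` SNPs (default 30), a new window every
`step` SNPs (training grid: `step = size`, non-overlapping; migration scan:
`step = 15`, half-overlapping). Trailing windows shorter than `size` are
dropped rather than padded, and windows never span chromosomes. Haplotype
identity within a window is exact string match — the statistic below asks
whether an *identical* haplotype migrated, so no mismatch tolerance is
applied. A haplotype with any missing call in a window is excluded from
that window's spectrum (numerator and denominator); exclusions are counted.
The modal haplotype breaks ties by lexicographically smallest string, which
makes every result deterministic.

## Local ancestry

Local ancestry is inferred per admixed *haplotype* with a hidden Markov
model over the non-overlapping training windows. The hidden state is the
parental breed; the emission for an observed window haplotype $h$ given
breed $B$ is a haplotype-copying mixture over the breed's panel:

$$ e(h \mid B) = \frac{1}{|P_B|} \sum_{t \in P_B}
   \varepsilon^{d(h,t)} (1-\varepsilon)^{L - d(h,t)} $$

with $d$ the Hamming distance over the window's $L$ sites and
$\varepsilon$ a per-site copying error. Transitions between adjacent
windows stay with probability $1-\rho$ and switch to breed $B'$ with
probability $\rho\,\pi(B')$. This is a deliberate simplification of the
two-layer haplotype-cluster HMMs used by dedicated local-ancestry tools:
the interface (30-SNP training windows, per-window ancestry posteriors) is
the same, and the fidelity target is tract recovery on simulated data, not
equality with any particular external tool. Because inference is per
haplotype, a diploid is automatically limited to two ancestries at a locus.

Defaults: $\varepsilon = 0.01$ (chip-scale genotype/phasing error),
$\rho = 0.05$ (a window is ~1.5 Mb; at ~5 generations since admixture the
per-window switch probability is of this order), prior $\pi$ uniform,
exclusivity threshold $\tau = 0.95$. Scaled forward–backward recursions
and log-space Viterbi avoid underflow for any finite input; emissions are
floored at `1e-300` before scaling.

Two per-window summaries are reported. The **mean** summary averages
posteriors over haplotypes (multiple ancestries allowed). The **minimum**
summary is an interpretation of a verbally described quantity — "haplotypes
originating from only one parental breed": we count haplotypes whose
posterior mass for a single breed exceeds $\tau$ and report per-breed
fractions among those, flagging windows where no haplotype is exclusive.
This reading is one of several possible and is flagged as such. The
migration scan consumes the mean summary by default.

## The haplotype-migration statistic

For breed $B$ and scan window $w$: let $\mathrm{freq}(B)$ be the frequency
of $B$'s most frequent window haplotype in the parental panel, $p(B)$ the
local ancestry of $B$ at $w$, and $\mathrm{obs}$ the frequency of that
same haplotype string in the admixed cohort. Windows where the haplotype
is absent from the admixed cohort are not scored. The expected frequency
is $p(B)\,\mathrm{freq}(B)$ and the default difference is

$$ \mathrm{freq}(D) = \mathrm{obs} - p(B)\,\mathrm{freq}(B), $$

standardized per breed across the genome with the sample standard
deviation; $|z| \ge 3$ calls an outlier. The printed source formula
$p(B)\,\mathrm{freq}(K|B) - \mathrm{freq}(B)$ does not reproduce the
worked-example table under any single reading we tried (one row is
internally inconsistent, and two breeds' rows appear sign-flipped relative
to the rest); the default convention above matches the majority of the
worked-example rows and the accompanying figure legend ("positive = higher
frequency than expected"). The literal formula is available with
`convention = "literal"` and is documented as not matching the table.

$p(B)$ lives on the non-overlapping training grid while scan windows
overlap; the scan maps ancestry onto a scan window as the SNP-overlap
weighted mean of the overlapping training windows' mean posteriors.
Standardization is per breed (ancestry scales differ by breed), genome-wide,
over scored windows only. Overlapping outlier windows are merged into
maximal regions (bp union) for reporting, and report tables display rows
with parental or admixed frequency above 0.3, mirroring the source table's
display rule; scoring itself uses no frequency floor by default.

## Selection statistics

**EHH** at flanking site $x$ for a core allele is
$\sum_h \binom{n_h}{2} / \binom{n_c}{2}$ over distinct extended haplotypes
spanning core$\to x$ among the $n_c$ carriers; 1 at the core,
non-increasing outward. Curves truncate below an EHH floor of 0.05, beyond
1 Mb per side, or at inter-SNP gaps over 200 kb (conventions of the
standard EHH package, which the source study used with defaults). **iHS**
integrates the ancestral- and derived-allele curves over bp (trapezoid),
takes $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$, and standardizes within
derived-allele-frequency bins of width 0.05 (bins under 10 SNPs merge with
a neighbor). SNPs whose curve is cut by a chromosome edge while still
above the floor are excluded; MAF < 0.05 SNPs are not scored. The
ancestral allele is **assumed to be REF** by default — the source never
states how ancestral alleles were assigned, the sign of iHS depends on it,
and flags (`"major"`, or an explicit per-SNP vector) are provided.
**Rsb** integrates the allele-agnostic site EHH (normalized to 1 at the
core) in each population and standardizes $\ln(\mathrm{iES}_1/
\mathrm{iES}_2)$ genome-wide by median-centering and sd-scaling.

**F_ST** uses the Hudson two-population estimator
(num $= (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$,
den $= p_1(1-p_2)+p_2(1-p_1)$), chosen for small-sample robustness; the
source cites the classical fixation index without an estimator formula,
so the choice is documented and a Nei-style $(H_T-H_S)/H_T$ variant is
available. Negative per-SNP estimates are reported as computed; genome
summaries are given as the per-SNP mean (raw and truncated at zero) and
the ratio-of-averages $\sum \mathrm{num} / \sum \mathrm{den}$.

**Candidate regions** implement "at least 3 continuous significant SNPs
per 1 Mb": every run of `min_hits` consecutive significant SNPs
($|iHS| > 3$) spanning at most 1 Mb marks its members, and overlapping
runs merge into maximal regions bounded by the first and last significant
SNP. The phrase is ambiguous between run-based and density-based readings;
this hybrid is a documented choice, validated against brute-force
enumeration, not a claim about the original authors' code. Absolute iHS is
used (the source reports maxima as positive values without stating
signedness).

## The synthetic-data generator

No genotypes are distributed with the source study, so the package ships a
generator that emulates its design and serves as the test bed:

* **Parental breeds** — ancestral allele frequencies uniform on
  (0.05, 0.95); breed frequencies Balding–Nichols
  $\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ with drift $F = 0.1$ per breed
  (moderate differentiation, the scale seen among European dairy breeds);
  panel sizes 62/21/21 diploids, mirroring the reference panels of the
  study design.
* **Admixed cohort** — 100 diploids; ancestry proportions
  $\pi = (0.53, 0.32, 0.15)$, the genome-wide proportions reported for the
  crossbred cohort; tracts from a Markov process with switch probability
  $1-e^{-g d}$ between adjacent sites ($g = 5$ generations, uniform
  1 cM/Mb map), one random donor haplotype per tract so parental window
  haplotypes migrate intact.
* **Map** — 2,000 SNPs on a 100 Mb chromosome (~1 SNP / 50 kb, 50K-chip
  density).
* **Planted signals** — `inject_haplotype_selection()` overwrites one
  window in a chosen fraction $\delta$ of non-carrier haplotypes with a
  breed's modal haplotype, raising its observed frequency by ~$\delta$,
  and relabels the truth tracts.

Deliberate simplifications, and what a green test therefore does *not*
establish: sites are simulated independently within breeds, so there is no
background LD beyond admixture LD — adequate for migration-score and
ancestry calibration (which rely on tract structure), but the neutral iHS
distribution on such data is milder-tailed than on real bovine LD, and
injection is instantaneous rather than a selective trajectory. A
coalescent backend is out of scope. All outputs are bit-reproducible given
the configuration and seed.

The Hudson estimator has expectation exactly $F$ under this generator: for
two breeds with independent Beta-distributed frequencies around ancestral
$p$, $E[\mathrm{num}] = 2Fp(1-p)$ (the finite-sample correction terms make
this exact) and $E[\mathrm{den}] = 2p(1-p)$, so the ratio of averages is
$F$ for every $p$ and hence for any ancestral-frequency mixture. The test
suite checks recovery of $F = 0.1$ within ±0.03.

## Numerical and degenerate-input conventions

* Zero variance among migration differences, a monomorphic EHH core,
  fewer than two finite values to standardize: errors, not silent NA.
* Forward–backward is scaled per window; Viterbi runs in log space.
* Spectrum frequencies per (window, population) sum to 1 to 1e-12;
  ancestry posteriors to 1e-9 (asserted).
* Tie-breaks (modal haplotype, truth-ancestry majority, Viterbi argmax)
  are deterministic: lexicographic or first-index.

## Known limitations

Single-donor-per-tract copying overstates haplotype integrity relative to
real pedigrees; the HMM shares no information across haplotypes of a
diploid; ancestry recovery saturates when admixed donors are also training
haplotypes (the test suite holds donors out where the distinction
matters); no permutation p-values are attached to migration z-scores — the
method uses raw standardized scores by design.
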