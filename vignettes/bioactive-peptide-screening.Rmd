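---
title: "Screening endogenous food peptides for bioactivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening endogenous food peptides for bioactivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

## The screening problem

Cold-pressed food matrices such as virgin olive oil carry a small
water-soluble fraction of endogenous peptides, released from seed storage
proteins (legumins, 11S globulins) and other tissue proteins during fruit
maturation and oil extraction. Some of these peptides inhibit
angiotensin-converting enzyme (ACE) — the pharmacological target of
antihypertensive drugs — or scavenge radicals. Finding them starts from
LC-MS/MS identification reports and ends with a short list of sequences
worth synthesising and assaying. `pepscreen` implements that desk chain as
reusable, tested components:

1. parse identification reports (database-search and de-novo flavours) and
   apply acceptance filters;
2. roll peptide evidence up to proteins by label-free area;
3. scan sequences against a dictionary of short bioactive fragments and
   compute BIOPEP-style activity scores;
4. simulate gastrointestinal digestion and ask which active fragments
   survive;
5. combine criteria into candidate flags and a deterministic ranking;
6. reduce the confirmatory wet assays (ACE-inhibition fluorescence, ABTS)
   to their defining calculations.

A synthetic-data module generates ground-truthed reports and assay plates
so that every stage can be validated against a known answer.

## Sequence model and mass arithmetic

Peptides are runs of the 20 canonical residues with an optional sparse map
of residue-level mass deltas, written inline the way report tables print
them: `LLLGAGCM(+15.99)` is an eight-residue peptide with oxidised
methionine at position 8. The monoisotopic mass is

\[ M = \sum_i m_{\mathrm{res}(i)} + 18.010565 + \sum_j \Delta_j , \]

with the standard monoisotopic residue-mass table and one water. Printed
deltas are nominal (two decimals); by default the known nominal values are
promoted to their exact monoisotopic equivalents (+15.99 becomes
+15.994915 Da, methionine oxidation), because only the exact delta
reproduces search-engine precursor masses at the millidalton level. All 27
sequences in the bundled reports recompute to the printed masses within
0.002 Da. Charged species follow `(M + z * 1.007276)/z`; the precursor
error is the signed ppm difference on the m/z scale.

One caution learned from the bundled data: printed ppm columns of report
exports are not generally reproducible from the printed m/z and mass
columns (the engine's internal reference differs from the printed
precision), so `ppmError()` implements the standard definition and no
claim is made about matching exported ppm columns.

## Report filtering

The acceptance rules mirror standard peptidomics practice and are held in
a `filterPolicy()`:

* database-search score `neg10lgP` $\ge$ 30; the score is
  $-10\log_{10}p$, so 30 corresponds to $p = 0.001$ and the engine's
  suggested starting threshold of 20 to $p = 0.01$;
* de-novo average local confidence (ALC) $\ge$ 90%, where ALC is the mean
  of the per-residue confidence scores;
* precursor charge $\ge$ +2 (singly charged ions are dominated by
  non-peptide interferences);
* the modification-stripped sequence must appear in at least two
  individual samples. Replication is keyed on the stripped sequence, so an
  oxidised and an unmodified observation of the same peptide pool their
  evidence.

ALC values are printed as integers; `computeALC()` returns both the exact
mean and its round-half-up integer. Reference tables that print both the
per-residue confidences and the ALC quantise the confidences to integers,
so the recomputed ALC can sit one unit away from the printed one — in the
bundled report five of eight rows reproduce exactly and all eight within
one unit. No rounding convention can do better from the printed integers
(two rows with the same fractional mean print different ALCs), which the
test suite documents explicitly rather than papering over.

Protein roll-up sums supporting-peptide areas with not-detected areas as
zero — the convention under which the bundled protein table reproduces
exactly — and defaults to a plain sum of supporting scores. Exported
protein scores are described as weighted sums by the search engine without
published weights, and single-peptide protein scores in the bundled table
exceed their only supporting peptide's score, so no attempt is made to
match that column; `scoreFun` is the hook for custom weighting.

## Motif library and activity scores

The bundled `defaultMotifLibrary()` holds 22 (fragment, activity) records
— ACE, DPP-IV, DPP-III and renin inhibitors and one opioid motif — each
with its published EC50 (µM) where one exists. It is deliberately minimal:
every record is traceable to a published potency or activity annotation,
and the full BIOPEP export can be loaded with `loadMotifLibrary()` and
merged in. Scanning reports every occurrence of every library fragment as
a contiguous substring, with 1-based positions (the R/Bioconductor
convention).

For a peptide of $N$ residues containing $a$ fragments with a given
activity, the activity profile reports

\[ A = a / N, \qquad B = \frac{1}{N}\sum_i \frac{1}{EC50_i}\ \,[\mu M^{-1}], \]

the BIOPEP frequency and potency parameters. Fragments without a
quantified EC50 contribute to $A$ but not $B$. Occurrence counting is per
site by default (a motif present twice counts twice); distinct-fragment
counting is available because published tables report final counts only.
Published $A$ values for the bundled peptides reproduce from the printed
(count, $N$) pairs to four decimals in 80 of 90 rows; the other ten are
adjacent-line transpositions in the printed table (the $A$ values of
neighbouring DPP-III/DPP-IV rows are swapped), pinned as such in the
tests. Reproducing the published *counts* themselves would require the
full 4,399-record BIOPEP dictionary and is out of scope; counts are
treated as inputs.

## Digestion engine

Cleavage specificity is declarative: an `EnzymeRule` cleaves C-terminal to
every residue in its P1 set unless the following residue is in the P1'
block set (classically proline). The bundled profiles are

| profile | P1 | blocked P1' |
|---|---|---|
| `pepsin_ph1.3` | F, L | — |
| `trypsin` | K, R | P |
| `chymotrypsin_like` | F, L, M, N, W, Y | P |

The chymotrypsin-like set is broader than the textbook aromatic
specificity; it is the rule set consistent with published in-silico
digestions of food peptides, which also cut after Leu and Asn (W is
included by analogy and is untested by the reference fragmentations).
Profiles are data (`inst/extdata/enzyme_profiles.tsv`), not code.
Independent per-enzyme digestion is the default; sequential mode
accumulates cut sites along the rule chain. Fragment annotation is by
whole-fragment identity against the library — an active motif only
survives digestion if it is released as exactly itself — matching how
digestion tables mark released di- and tri-peptides.

## Candidate selection

`selectionCriteria()` encodes the multi-criterion screen: hydrophobic
fraction at most 0.85 as a water-solubility proxy (peptides above ~85%
hydrophobic residues are poorly soluble), predicted activity in the
required classes, survival of at least one annotated fragment through some
enzyme, optional abundance threshold (disabled by default, since no
published cut exists), the C-terminal rule (a hydrophobic or basic residue
within the last three positions, the classical ACE-inhibitor signature),
and cysteine presence (advisory by default: it matters for antioxidant,
not ACE-inhibitory, candidates). Missing data yield an `absent` flag that
never counts as failure. The manual expert choice that a published
shortlist reflects cannot be reproduced as a single hard verdict — one
confirmed-active peptide (NALLCSNS, ending ...SNS) fails the C-terminal
rule outright — so the screen exposes per-criterion flags plus a
deterministic ranking (passes, then area, then sequence) rather than a
boolean oracle.

## Assay calculators

ACE inhibition from a fluorescence plate is

\[ \%\,\mathrm{inhibition} = \frac{(F_C - F_B) - (F_S - F_{Bs})}{F_C - F_B} \times 100 , \]

with control $F_C$, blank $F_B$, sample $F_S$ and sample-blank $F_{Bs}$.
Values outside [0, 100] are returned as-is with a flag. Replicate wells
are averaged (SEM reported) before estimation. IC50 defaults to linear
interpolation of inhibition against $\log_{10}$ concentration between the
bracketing pair — assumption-free and exactly reproducible — with a
two-parameter log-logistic fit (`minpack.lm::nlsLM`) behind
`method = "logistic"`; on clean Hill-slope-1 data the two agree within a
few percent. When no pair brackets 50%, estimation refuses with the
observed range rather than extrapolating.

TEAC is the ratio of the compound's least-squares response slope to the
Trolox calibration slope (0–1 mM standards), which uses the whole curve;
single-point equivalence is available as an option. TEAC is invariant to
rescaling all responses by a common factor, which the tests verify.

## What the synthetic data emulates — and what it does not

`simulateReport()` plants each true peptide once per sample with mass
error `N(0, ppmSigma * 1e-6)` (default sigma 5 ppm, matching the observed
0.5–9.6 ppm spread under a 10 ppm search tolerance), charge 2–3,
Beta-shaped per-residue confidences (default shape (28, 2), giving ALC
~90–96), and log-normal areas (meanlog 12.5, sdlog 1.5, spanning roughly
1e4–1e7). Decoys each violate exactly one acceptance rule — failing
score, charge +1, or single-sample occurrence — so filter recall and
rejection can be asserted at 100%. The generator does not emulate:
correlated mass errors, retention-time structure, chimeric spectra,
sequence-dependent detectability, or shared decoy/true sequences.
Passing filters on simulated data therefore demonstrates the rule logic,
not real-data FDR behaviour.

`simulatePlate()` generates inhibition from the log-logistic curve
$I(c) = 100/(1 + (IC50/c)^h)$ and converts it to fluorescence readings
consistent with the inhibition formula (fixed $F_C = 1000$, $F_B = F_{Bs}
= 100$), with multiplicative reading noise (default CV 2%). The default
concentration series is a half-log ladder centred on the true IC50 plus a
zero well, so the noiseless midpoint identity (50% at the IC50) holds by
construction. `simulateAbts()` mirrors the ABTS protocol's replication —
three independent experiments, each in triplicate at every concentration,
pooled — with Trolox standards at 0–1 mM and sample concentrations kept
inside the calibration's linear range.

At 2% reading noise and this replication, IC50 interpolation recovers the
truth within 10% on every tested seed, and the TEAC slope-ratio estimator
is unbiased well within 0.05 with a seed-to-seed SD of about 0.026. A
single simulated experiment set can therefore stray slightly beyond 0.05;
the recovery claim the tests assert is the simulation-study one (bias and
SD), matching how the wet protocol reports means of three experiments.

## Numerical choices and degenerate inputs

* ALC printing uses round-half-up; comparisons against printed integers
  carry the quantisation caveat above.
* Absent areas ("ND") are zeros in sums, never propagating missing values.
* Ties in candidate ranking break by area, then lexicographic sequence —
  a total, deterministic order.
* A terminal P1 residue is never a cut site (no successor bond); digesting
  a fragment again with the same rule returns it unchanged, which holds by
  construction and is property-tested.
* Empty scan results, empty libraries, header-only reports and
  single-residue peptides are all legal and return empty-but-typed
  objects.
* Simulation problem sizes used by the test suite — 1,000 random peptides
  for digestion properties, 200 for the scan oracle, 100 seeds for
  dose-response recovery — were chosen to make the property estimates
  stable at interactive runtimes.

## Known limitations

* The bundled motif library is a curated subset; absolute $a$ counts
  against it are smaller than counts against the full BIOPEP dictionary.
* Sequence coverage in protein roll-up requires residue positions that
  identification exports do not carry; it is reported absent.
* The digestion engine models complete, kinetics-free cleavage: no missed
  cleavages, partial digestion or pH-dependent switching beyond the named
  profiles.
* The assay calculators recover parameters from readings; they cannot
  reproduce wet-lab IC50/TEAC values of specific peptides, only
  demonstrate recovery on synthetic data at the same scales.

## A compact end-to-end example

```{r example, eval = FALSE}
lib <- defaultMotifLibrary()
rules <- defaultEnzymes()
rep <- readPeaksReport(system.file("extdata", "voo_denovo.tsv",
                                   package = "pepscreen"), "denovo")
p <- parsePeptide(rep$sequence[1])           # CCYSVY
activityProfile(p, lib)
digs <- lapply(digestMulti(p, rules), annotateFragments, library = lib)
fragmentString(digs$chymotrypsin_like)       # "CCY-SVY"
evaluateCandidate(p, activityProfile(p, lib), digs)$overall
```
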