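---
title: "Discovering cilia-derived amidated peptides: models and methods"
author: "ciliapep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cilia-derived amidated peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliapep)
```

## The biological problem

*Chlamydomonas reinhardtii* carries the full enzymatic machinery of
peptidergic signaling — subtilisin-like prohormone convertases,
carboxypeptidase-B-like exoproteases and peptidylglycine α-amidating
monooxygenase (PAM) — but no secretory granules. Bioactive amidated
peptides instead leave the cell on ectosomes budding from the ciliary
membrane. `ciliapep` implements the computational side of that story:
finding candidate peptide precursors in protein sequences, predicting and
simulating their processing to α-amidated products, screening
mass-spectrometric evidence for those products, clustering the precursor
families, and quantifying the chemotactic activity of an amidated peptide
in a microfluidic gradient channel. Synthetic-data generators reproduce
the statistical structure of every input, so the complete workflow runs
and is tested without any external database or instrument files.

## Precursor grammar and in-silico processing

A neuropeptide precursor is recognized by a small sequence grammar:

* **Prohormone convertase (PC) sites**: a pair of basic residues,
  `(K/R)(K/R)`, cleaved C-terminal to the second basic residue (the P1
  position, the convertase convention).
* **Furin-like sites**: `R-X-(K/R)-R`, cleaved after the final arginine.
* **Amidation sites**: a glycine immediately C-terminal to the residue
  that will carry the amide. PAM removes the glycine and amidates the
  exposed C terminus. Donor glycines are found (i) immediately N-terminal
  to a cleavage motif, (ii) at the chain terminus, or (iii) followed only
  by a short basic run `G(K/R)n` removable by carboxypeptidase-B-like
  trimming.

All matches are reported, including overlapping windows, and an unknown
residue `X` never matches a motif. A furin site embeds a PC pair in its
last two residues; when one glycine abuts both, the furin classification
wins, but the two motif kinds are tallied separately at the protein level
(the census counts them as separate categories).

`process_precursor()` chains the three enzymatic steps: cleave after
every site, trim up to `max_basic_run` C-terminal K/R residues per
fragment, then convert an exposed C-terminal glycine into an amide flag.
Choices worth noting:

* `max_basic_run = 3` by default — this covers the `-GRRR` terminus of
  the chemotactic peptide precursor. The paper-scale census leaves *n* in
  `G(K/R)n` unstated; we fix *n* ≤ 3.
* `his_trim` (off by default) additionally removes a single histidine
  exposed after basic trimming. One of the three identified precursors
  requires this route (`...GGH | RK | RA` → remove R, K, then H, then the
  donor G); it is opt-in because His removal is a special case of
  carboxypeptidase-B-like activity.
* Products shorter than `min_length = 3` residues are dropped with a
  warning; a zero-length remainder is silently discarded.
* Re-processing an amidated product returns it unchanged: cleavage at
  every site plus trimming removes all C-terminal basic context by
  construction. The test suite asserts this idempotence on generated
  precursors.

Membrane topology (`classify_topology()`) is a deterministic function of
two external annotations (signal peptide, TMH spans): Sig+ without TMH is
secreted, Sig+ with one TMH is Type I, Sig− with one TMH starting in the
first 60 residues is Type II (signal-anchor geometry — the orientation
that places a subtilisin catalytic domain on the ectosome surface), two
or more TMHs is multipass. A single Sig− TMH starting after residue 60 —
a case the annotation rule set leaves open — is classified
`NON_SECRETORY`, since it carries no recognizable secretory targeting
signal. When annotations are missing, deliberately simple Kyte–Doolittle
hydropathy heuristics stand in (mean hydropathy of residues 6–20 above
1.0 with a basic n-region for signal peptides; 19-residue windows above
1.6 for TMHs) and the record is flagged `heuristic`. These stand-ins make
the package self-contained; they are not re-implementations of dedicated
predictors, and externally supplied annotations always take precedence.

## Mass arithmetic and the Gly-loss + amide filter

Neutral monoisotopic masses are the internal currency; m/z appears only
in `fragment_series()`. Residue masses are derived from elemental
compositions — monoisotopic atomic masses for the `mono` scale, IUPAC
2021 standard atomic weights for the `average` scale (reported to two
decimals, the convention of instrument software). The amide substitutes
NH~2~ for OH at the C terminus (−0.98402 Da monoisotopic), and the
"Gly-loss + amide" dynamic modification used in the database search is
the algebraic combination

$$\Delta = -(\text{Gly residue}) + (\mathrm{NH_2} - \mathrm{OH})
        = -58.00548\ \text{Da (monoisotopic)},$$

which ties the database (glycine-extended) form of a peptide to its
amidated product: `mass(S + "G") + Δ = mass(S-amide)` exactly. The test
suite asserts this identity over 1,000 random peptides.

Tryptic digestion cleaves after K/R, suppressed before proline, with up
to 3 missed cleavages (the stricter of the two search-engine settings
used; the other engine used 2 — both are reachable through
`digest_config()`). The evidence screen (`gly_loss_amide_screen()`)
builds candidate amidated peptides by two routes mirroring how a search
engine applies the modification: tryptic C-terminal fragments of
processed amidated products, and every database tryptic peptide ending in
glycine. Each PSM's observed neutral mass is matched against candidate
masses within a 10 ppm tolerance (the precursor tolerance of the original
searches), and calls must be supported in at least `min_samples`
replicates (6 for the headline screen) to survive consensus. The screen
is deterministic; all stochasticity lives in the generators.

## Count tables

Spectral-count matrices are normalized so every sample total equals the
pre-normalization average total (this conserves the grand total exactly),
proteins detected in fewer than `min_samples` of the replicates are
eliminated (4 of 6 in the merged-dataset convention), and
`abundance_share()` reports the fraction of total mean counts carried by
the top *k* proteins, with ties broken by a stable sort on protein id.
Whether the published share was computed on normalized or raw counts is
not stated in the source material; we follow the normalization described
for the count tables themselves. The published top-29 figure depends on a
supplementary table that is an external download, so the acceptance
machinery validates the computation on a synthetic ectosome-like matrix
against an independent inline oracle instead of asserting the printed
percentage.

## Precursor clustering

Precursor relatedness uses pairwise Needleman–Wunsch global alignment
identity (match 1, mismatch 0, gap −1; identity = matched columns /
alignment columns) rather than a multiple sequence alignment: the
grouping claim being reproduced is qualitative, and pairwise identity
distances (d = 1 − identity) are sufficient and fully deterministic. The
traceback prefers diagonal, then up, then left, fixing the reported
alignment under score ties.

`upgma()` is classic size-weighted average-linkage agglomeration with
node height = merge distance / 2, which makes every output tree
ultrametric; tied merges choose the lexicographically smallest pair of
cluster representative labels, so input order never changes the result.
The test suite checks equivalence with an independent average-linkage
implementation on 200 random matrices, and Newick output round-trips
through an independent parser. `cut_groups()` removes the k − 1 highest
merges; seven groups is the default granularity, matching the published
precursor census.

## Chemotaxis statistics

The microfluidic geometry is a 50 mm × 5 mm × 0.2 mm channel with the
chemo-effector reservoir at x = 0; region 2 is the channel third nearest
the chemo-effector. The chemotaxis index is

$$\mathrm{CI} = \frac{n_2 / n_1}{(n_2/n_1)_{\text{vehicle, 4 h}}},$$

always normalized by the 4-hour vehicle ratio, including for earlier
treatment time points. The region boundaries are not specified in the
source assay; equal thirds are the default and configurable. Slice
profiles divide 19 slice counts by the slice-0 count. Population
statistics summarize 10-second tracks sampled at 0.5 s: the center of
mass is the mean endpoint displacement (translation-invariant by
construction), mean speed is path length over duration, and endpoint
direction uniformity uses the Rayleigh test with the standard
second-order series approximation for the p-value, clamped to (0, 1].
Its type-I error is verified to sit in [0.03, 0.07] at α = 0.05 over
2,000 uniform null sets of n = 50.

## What the generators emulate — and what they do not

* **Planted proteomes**: decoys are rejection-sampled to contain no
  motif and no C-terminal amidation context, so screen recovery has an
  exact planted truth. Real proteomes contain near-motifs, compositional
  bias and low-complexity regions that this fixture does not emulate;
  passing recovery tests demonstrates correctness of the rules, not
  field performance of the census.
* **PSM sets**: six replicates carry each planted amidated peptide with
  uniform ppm-scale mass noise (≤ 5 ppm in the headline configuration),
  plus decoys whose masses are kept ≥ 3× the tolerance away from every
  candidate window. Real searches face co-eluting near-isobaric
  peptides; specificity here is a hard guarantee by construction, so the
  fixture tests the consensus logic, not false-discovery behavior.
* **Count tables**: log-normal protein abundances (meanlog 2, sdlog 1.3
  — the strong skew typical of label-free count data) with Poisson
  sampling and 15 % dropout.
* **Gradient**: 1-D diffusion from an end bolus with reflecting
  boundaries, solved by cosine eigenfunction series. D defaults to
  250 µm²/s, the Stokes–Einstein scale for a ~2.2-kDa peptide in water;
  at this D the 1 h and 6 h profiles correlate above 0.9, matching the
  observed stability of the fluorescent reporter gradient. Mass is
  conserved to series precision and the profile is monotone in x.
* **Trajectories**: per 0.5-s step, the heading is von Mises
  (Best–Fisher sampler) centered up-gradient with concentration chosen
  so the mean heading cosine equals the bias λ; speed is drawn once per
  cell from 100–150 µm/s and never depends on λ, encoding the
  observation that the peptide changes direction, not velocity. When a
  gradient is supplied, λ is scaled by the local normalized gradient
  slope, so the response develops as the gradient front propagates.
  Region-count simulations start cells uniformly along the channel
  (emulating the distribution phase before counting) and step at a
  coarse 5 s — regional redistribution is hour-scale — while CI values
  average three simulated experiments, mirroring the triplicate design
  of the assay. Hydrodynamics, flagellar beating, phototaxis and the
  third channel dimension are out of scope.

## Numerical choices and degenerate inputs

Masses: unknown residues (including X) raise a mass-undefined error;
empty peptides are invalid. ppm matching is relative to the theoretical
mass. UPGMA requires a finite symmetric nonnegative matrix with zero
diagonal; ties (measure zero under the generators) are resolved as
described above. `rayleigh_test` needs n ≥ 5; antipodal cancellation
(R = 0) gives p = 1 exactly. Zero-displacement cells contribute no
endpoint angle. Single-sample count matrices normalize to themselves;
zero-total samples are an error naming the sample. All generators are
byte-deterministic under fixed seeds, and problem sizes used in the
packaged analyses (200-protein proteomes, 318-PSM screens, 1,000-cell
triplicate region simulations, 200 six-leaf oracle matrices) were chosen
to exercise every code path at comfortable desk scale.

## Known limitations

The screen consumes mass-level PSM tables, not spectra: engine scoring,
FDR modeling and protein parsimony are explicitly out of scope, and
"identified" means a nonzero spectral count. The census cannot resolve
gene models whose true N terminus is absent from the database (one of
the three identified precursors is such a case). Pairwise identity is a
coarser relatedness measure than a tuned MSA; groups cut from the UPGMA
tree should be read qualitatively. The hydropathy heuristics are
fallbacks, not predictor replacements.
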