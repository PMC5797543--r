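---
title: "Methods: neoepitope ranking and peptide/MHC threading in epithread"
author: "epithread authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoepitope ranking and peptide/MHC threading in epithread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epithread)
```

# Scope

`epithread` couples two computational workflows around tumor neoepitopes.
The *genomic* side turns somatic single-nucleotide variants (SNVs) into
ranked candidate epitopes: a caller-consensus filter, an oxidative-artifact
(OxoG) and RNA-expression filter chain, translation of surviving missense
variants into 2n−1 peptide contexts, percentile-rank binder filtering with
self-peptide comparison, and grouping into ImmunoActive Regions (IARs). The
*structural* side screens a peptide against HLA class-I alleles by
fixed-backbone threading on a template peptide/MHC complex, side-chain
repacking, and binding-energy estimation, with a polyAla groove as negative
control, BLOSUM62 identity landscapes and Kullback–Leibler groove logos as
analytics. Supporting tools (superposition RMSD, solvent-accessible and
buried surface area, contact counts, φ/ψ-based 3~10~ classification,
theoretical peptide masses, Boltzmann melt-curve fits) quantify the
structures and biophysics involved.

# Variant filtering

A variant record carries the verdicts of five somatic callers, its tumor
allele fraction, the ALT-supporting read-1/read-2 counts, RNA depth / ALT /
spanning-read counts, and a gene expression value. Three stages run in
order; a record's audit names the **first** failing stage:

1. **Consensus** — kept if no more than `max_caller_reject` (default 2)
   callers rejected it. Callers without an opinion are not rejections.
2. **OxoG / read provenance** — dropped if ALT support comes solely from
   read 1 or solely from read 2 of the pairs, the signature of guanine
   oxidation during library preparation; additionally dropped if the allele
   fraction is strictly below 0.1 *and* the RNA shows no ALT evidence. The
   read-provenance clause applies to all substitution types; whether the
   change is OxoG-consistent (C>A/G>T) is annotated, not required. "No
   RNA-seq coverage" is read strictly as `rna_alt_count == 0`, consistent
   with the expression filter's unexpressed-ALT clause.
3. **Expression** — dropped when the gene is unexpressed (expression ≤ 0 by
   default; the metric — raw or normalized — is the caller's choice and the
   threshold is configurable), when reads span but none cover the position
   (a splice variant), or when the position has no ALT evidence in RNA.

Filters are pure functions: verdicts are independent of record order, and
raising the allele-fraction cutoff can only shrink the kept set.

# Peptide windowing

Each missense SNV at protein position *p* yields the mutant substring
spanning `p − n + 1 … p + n − 1` (length 2n−1 away from the termini,
truncated at them — truncation keeps candidates rather than discarding
near-terminal mutations) for every configured *n* (default 9, 10, 15;
15-mers are windowed for class-II use but scored only if a predictor for
them is supplied). All length-*n* substrings containing the mutated
position are enumerated — exactly *n* of them for an untruncated context —
and each is paired with the reference substring at the same coordinates,
which differs at exactly the mutated offset. Identical peptides arising
from several transcripts are merged with their origins unioned.

# Binder calling and IAR ranking

Binding predictions are percentile ranks against a background: 100 × the
fraction of background scores strictly better than the query, so 0 is the
strongest possible call. Calls with rank strictly greater than 5 are
discarded (a rank of exactly 5.0 survives, the literal reading of "greater
than 5%"). The predictor is an interface: the bundled position-specific
scoring matrix (PSSM) predictor draws a seeded log-odds matrix per
(allele, length) and calibrates ranks against 100,000 random peptides drawn
from uniform residue frequencies. It exists so the pipeline runs
end-to-end with no external service, and its ranks are meaningful only
relative to its own background — it is **not** a reimplementation of any
consensus MHC predictor. Precomputed ranks from a real predictor can be
injected via `tsv_predictor()`.

Kept calls are grouped by (mutation, transcript set) into IARs with four
metrics: best contained rank, transcript expression, promiscuity (distinct
alleles bound), and the number of 10-mers overlapping a 9-mer that binds
the same allele at similar affinity. "Similar affinity" is undefined in the
source method; the default window is 2 percentile points, configurable.
The composite ranking is a weighted sum

$$s = w_1\,(1 - \mathrm{best}/100) + w_2\,\widetilde{\mathrm{expr}} +
      w_3\,\widetilde{\mathrm{prom}} + w_4\,\widetilde{\mathrm{overlap}}$$

with min–max normalization within the sample and defaults
$w = (0.4, 0.3, 0.2, 0.1)$. The exact composite used by the original
pipeline is not published; these weights are this package's documented
choice, ties break deterministically by mutation id, and rescaling the
whole weight vector leaves the order unchanged.

# Threading protocol

The template complex is trimmed to the α1/α2 peptide-binding domain —
heavy-chain residues 1–180, the standard class-I domain boundary — plus the
untouched peptide chain. The groove is the set of heavy-chain residues with
any atom within 3.5 Å of any peptide atom. An allele sequence is globally
aligned to the template heavy chain (BLOSUM62, gap open 11 / extend 1);
alleles whose alignment puts a gap at a groove position are rejected rather
than modelled. At mismatched positions the side chain is rebuilt from the
new residue's most probable rotamer on the fixed backbone; matched
positions keep the template side chain. The same machinery substitutes
peptide residues, which is how self/mutant peptide pairs are modelled in a
common groove.

Per allele, `n_models` (default 100) independent repack trajectories are
run and the mean binding energy of the `top_k` (default 10) lowest-energy
models is reported, together with a per-peptide-position decomposition in
which anchor positions appear as minima. The polyAla control replaces every
groove residue — including Gly and Pro, the literal reading of "all
residues" — with alanine, using each template's own groove set.

## Energy model

Energies use an intentionally small, fully documented physics score — *not*
a published force field; every conclusion drawn from it in this package is
ordinal (orderings and signs, never absolute values):

* **Softened Lennard-Jones** on element radii (C 1.70, N 1.55, O 1.52,
  S 1.80 Å) and well depths (0.10–0.20), 12-6 beyond 0.6·r₀, linear
  continuation inside, per-pair cap at 100 with a hard-clash flag;
* **Hydrogen bond**: a smooth well of depth 1 on donor(N, hydroxyl
  O)–acceptor(O) pairs between 2.6 and 3.2 Å — heavy-atom distances, since
  crystal structures carry no hydrogens. The window deliberately excludes
  sub-2.6 Å geometries so a steric clash can never be rewarded as a bond;
* **Screened Coulomb** with distance-dependent dielectric (ε = 4r) over
  formal charges on Arg/Lys/Asp/Glu side-chain termini;
* **Burial penalty** for polar atoms with more than 22 neighbours within
  5.2 Å (surface atoms in proteins sit near 15–20), weight 0.25.

Pairs within a residue, and backbone–backbone pairs of chain-adjacent
residues (fixed peptide-bond geometry), are excluded.

The binding energy is ΔE = E(complex) − E(MHC) − E(peptide) with the
unbound parts scored at frozen coordinates — no re-relaxation, stated
explicitly because the source protocol is ambiguous on this point. With
frozen coordinates the intra-chain pair terms cancel exactly, so ΔE equals
the cross-interface pair energy plus the burial-penalty change on binding;
the per-residue map assigns cross terms and own-atom burial changes to each
peptide position and attributes MHC-atom burial changes to the nearest
peptide residue, making the map sum to ΔE.

## Repacking

Side chains of groove and peptide residues are resampled by Metropolis
simulated annealing over a compact backbone-independent rotamer library
(≤ 9 rotamers per type, probabilities summing to 1; the library is an
argument everywhere, so a richer one can be plugged in). The schedule is
geometric from T = 4 to 0.05 model units over `max(20, 3 × n_repackable)`
sweeps, followed by greedy coordinate descent until no single-rotamer move
improves. The per-move objective is the pairwise part of the energy; the
burial term, which is insensitive to single-rotamer moves at this scale, is
evaluated in full scoring only. Discrete repacking was chosen over
continuous torsion minimization — a documented divergence from protocols
that minimize after packing. Trajectories are bit-reproducible given a
seed, the caller's RNG state is saved and restored, and the returned
configuration never scores worse than the input (the best visited state is
kept and quenched). On systems small enough to enumerate (≤ 3 chi-bearing
residues) the annealed result matches the exhaustive optimum, which the
test suite checks against an independently coded enumeration.

# Screen analytics

Identity to the reference allele is the BLOSUM62 score of the groove
columns normalized by the reference's self-score, so identity(x, x) = 1.
Groove columns come from the threading alignment itself — all alleles
share template coordinates — so no separate multiple-sequence alignment
program is invoked; this is a documented divergence from workflows that
realign with an external tool. Good binders are alleles with mean ΔE
strictly below a threshold allele's. The KL logo reports, per column,
Σₐ p(a) log₂(p(a)/q(a)) against a background q (uniform by default,
configurable to database frequencies), with letter heights p(a)·KL. Zero
frequencies contribute zero by the 0·log 0 convention, so no pseudocount is
needed for well-formedness; the `pseudocount` argument (default 0) exists
for very small sets, and the default keeps closed-form column values exact
— a fully conserved column against the uniform background is log₂ 20 ≈
4.32 bits. A background with zero mass on an observed letter is an error.

# Structural metrics

Superpositions are least-squares Kabsch fits (SVD with the proper-rotation
correction). `selection_rmsd` fits on a *frame* selection and measures on a
*measure* selection without refitting; the default frame for cross-complex
comparisons is the backbone of heavy-chain residues 1–180, stated here so
that numbers computed on deposited structures are reproducible. Nonamer
and decamer peptides pair by residue index over their shared residues 1–9.
SASA is Shrake–Rupley with a deterministic spherical Fibonacci point set
(960 points, probe 1.4 Å; doubling the points moves totals by under 1%),
and buried surface area is the standard two-sided
SASA(A) + SASA(B) − SASA(AB). Contacts are typed geometrically — N/O–N/O
pairs within 3.5 Å polar, carbon–carbon within 4.5 Å hydrophobic (side
chains or apolar residues) — a simplification of the unpublished criteria
behind the reported counts, so counts are reported but never asserted.
A residue is 3~10~-helical when φ ∈ [−90°, −40°] and ψ ∈ [−45°, 0°], and
spans are runs of ≥ 3; the window is a standard Ramachandran region,
documented because the source describes only an inspection.

# Biophysics

Peptide masses are residue-mass sums (standard IUPAC average or
monoisotopic tables) plus one water; the reported neoepitope masses
(1,086.17 and 1,249.35 Da for AQDIYRASY and AQDIYRASYY) match the average
table, confirming the choice. Melt curves are fit to the Boltzmann sigmoid
F(T) = F_min + (F_max − F_min)/(1 + exp((Tm − T)/k)) by
Levenberg–Marquardt; the automatic guess takes the extremes for the
plateaus, the maximum-derivative temperature for Tm and k = 2 °C, and Tm is
reported from the fitted parameter, not the derivative peak. Flat curves
and fits escaping the scanned range are errors, not numbers.

# Synthetic fixtures: what they do and do not show

Every input class has a seeded generator, so the whole toolkit is testable
offline; all generators are pure functions of their arguments, and named
substreams derive from one master seed.

* **Variant sets** plant unambiguous populations — clean passers,
  single-mate OxoG artifacts, low-fraction calls without RNA support,
  unexpressed genes — so filter agreement with the planted truth is 100%
  *by construction*. This validates the rule logic, not the filters'
  error rates on real sequencing data, where evidence is graded and
  clauses overlap.
* **Allele families** mutate a groove sequence at a per-position rate while
  holding chosen positions invariant, giving logo maxima at the planted
  positions with probability 1 — again a check of the statistic, not of
  real HLA conservation.
* **The micro-groove** is a deliberately tiny idealized complex: a 9-mer
  peptide in extended conformation (φ −120°, ψ 120°) flanked by two ideal
  α-helices and a four-strand floor (~60 residues), built from ideal bond
  geometry with wall spacing in the attractive contact range (≈3.3 Å
  minimum approach) and side-chain rotamers chosen to avoid steric
  overlap. It runs a full 100-model screen in about half a minute. With
  `occlude_pocket_b = TRUE`, blocking residues are placed along the reach
  of every bundled arginine rotamer at peptide position 2 — just beyond
  the guanidinium tip, with the dummy backbone pointing away so only
  carbon sits in the reach zone — so an arginine there clashes in every
  rotamer while the native glutamine still fits. The energetic orderings
  the tests assert (native groove better than polyAla; neoepitope better
  than the Arg-containing self peptide) are properties this construction
  is designed to exhibit under the package's energy model; they
  demonstrate that the protocol detects what it is supposed to detect,
  not that it reproduces measured affinities on crystal structures.
* **Melt curves** come from the Boltzmann model plus Gaussian noise, with
  the scan range (25–95 °C) and reference Tm values taken from the
  experimental setting they emulate.

# Problem sizes

The shipped tests and the acceptance script choose sizes that exercise
every code path at full protocol settings where the protocol defines them
(100 models, top 10; 5% cutoff; 3.5 Å groove) and compact sizes elsewhere:
200-variant synthetic sets, 5,000-score percentile backgrounds, 50
melt-curve replicates at 2% noise, the ~60-residue micro-groove for
screens, and a 3-residue system for the exhaustive repack cross-check.

# Known limitations

The energy model has no explicit solvent, no polarization, no hydrogen
positions, and a blunt burial term; its numbers are model units with no
experimental scale. Backbone flexibility is absent by design — peptides of
lengths without a matching template cannot be modelled, and loop
remodelling is out of scope. The bundled rotamer library is far smaller
than a full backbone-dependent library. The PSSM predictor is a calibrated
stand-in, not an immunologically trained model. Contact counts depend on
typing criteria that differ from the unpublished ones used for the
reported values. The IAR composite weighting fills a gap the source method
leaves open and is flagged as such.
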