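# epithread

Tumor-specific missense mutations can create **neoepitopes**: short
peptides that an HLA class-I molecule may display in the groove formed by
its α1/α2 domains, making the tumor visible to T cells. Deciding which of
a patient's hundreds of somatic variants could yield such a peptide takes
two very different kinds of evidence — sequencing-level (is the variant
real and expressed?) and structural/biophysical (does the peptide actually
fit an HLA groove better than its unmutated self counterpart?).
`epithread` implements both sides as one R toolkit, for computational
immunologists and structural bioinformaticians who want a transparent,
fully scriptable version of this workflow.

## What it computes

**Variant → ranked epitope candidates.** Somatic SNVs pass a
caller-consensus filter (rejections by at most 2 of 5 callers tolerated),
an OxoG/read-provenance filter (ALT support confined to read 1 or read 2
of the pairs, or allele fraction < 0.1 with no RNA ALT evidence), and an
expression filter (unexpressed gene, splice variant, unexpressed ALT).
Each surviving missense variant is expanded to its mutant 2n−1 context and
every n-mer containing the mutation (n = 9, 10 by default, exactly n
windows away from the termini). Peptide/HLA calls are percentile ranks —
100 × the fraction of a background strictly better than the query; calls
above 5 are non-binders — each paired with the rank of its self peptide.
Binders group by mutation and transcripts into **ImmunoActive Regions
(IARs)**, ranked by best contained rank, expression, allele promiscuity,
and 9/10-mer overlap:

```
s = w1 (1 − best/100) + w2 expr' + w3 prom' + w4 overlap'
```

**Peptide/HLA threading screen.** A template p/MHC complex is trimmed to
heavy-chain residues 1–180 (the groove domain); the groove is every heavy
residue within 3.5 Å of the peptide. An allele sequence is aligned to the
template (BLOSUM62, gap 11/1) and threaded onto the fixed backbone,
groove and peptide side chains are repacked by simulated annealing over a
rotamer library, and the binding energy

```
dE = E(complex) − E(MHC) − E(peptide)
```

is averaged over the 10 lowest-energy of 100 independently repacked
models. A polyAla groove (every groove residue mutated to Ala) is the
negative control. Downstream analytics give the energy-vs-BLOSUM62
identity landscape and a Kullback–Leibler sequence logo of groove columns
from good binders. The energy function is a documented simplified physics
score (softened Lennard-Jones, H-bond well, screened Coulomb, polar burial
penalty); all conclusions built on it are orderings, never absolute
affinities.

Supporting tools: Kabsch superposition and frame/measure RMSD, per-atom
Shrake–Rupley SASA and buried surface area, polar/hydrophobic contact
lists, φ/ψ dihedrals with 3₁₀-helix span calling, exhaustive rotamer
clash scans, theoretical peptide masses, and Boltzmann sigmoidal melt-curve
fitting for DSF Tm extraction. Seeded generators (`make_variant_set`,
`make_protein_with_mutation`, `make_allele_family`, `make_micro_groove`,
`make_melt_curves`) synthesize every input class for offline testing.

## Worked example

```r
library(epithread)

# a synthetic 100-residue protein with a planted missense mutation (L50Q)
pr <- make_protein_with_mutation(seed = 21, length = 100, mut_pos = 50)
w  <- windows_from_variants(pr$variant, pr$proteome, c(9L, 10L))
head(w[, c("seq", "self_seq", "n", "start", "mut_offset")], 3)
#>         seq  self_seq n start mut_offset
#> 1 DCEGIKWKQ DCEGIKWKL 9    42          9
#> 2 CEGIKWKQW CEGIKWKLW 9    43          8
#> 3 EGIKWKQWC EGIKWKLWC 9    44          7

pred <- pssm_predictor(c("HLA-A*01:01", "HLA-B*15:01"),
                       lengths = c(9L, 10L), seed = 42)
res <- rank_neoepitopes(w, c("HLA-A*01:01", "HLA-B*15:01"), pred)
res$calls[, c("peptide", "allele", "percentile_rank", "self_rank")]
#>      peptide      allele percentile_rank self_rank
#> 22 EGIKWKQWC HLA-B*15:01           2.467     1.796
res$iars[, c("mutation_id", "best_rank", "promiscuity", "rank")]
#>     mutation_id best_rank promiscuity rank
#> 1 chr1:1150:G>A     2.467           1    1
```

Of the 19 mutant windows × 2 alleles, one call ranks inside the top 5% of
the PSSM background (2.467) and forms a single IAR; its self peptide also
ranks well here (1.796), so the call is flagged as not better than self —
exactly the comparison used to prioritize true neoepitopes. (The bundled
PSSM scorer is a seeded stand-in so the pipeline runs without an external
predictor; plug real consensus ranks in with `tsv_predictor()`.)

Biophysics one-liners:

```r
peptide_mass("AQDIYRASY")    # 1086.17 Da (expected LC-MS mass)
fit <- fit_boltzmann(simulate_melt_curve(0, 100, 53.4, 2,
                                         noise_sd = 2, seed = 3))
fit$tm                       # 53.41 degC
```

A shell interface mirroring the R surface lives in `inst/cli/epithread`
(`filter-variants`, `peptides`, `bind-rank`, `thread`, `screen-analyze`,
`metrics`, `mass`, `dsf-fit`, `simulate`); every run writes a JSON
manifest with config, seeds and input checksums.

## VCF dialect

Variant evidence travels in INFO keys of an SNV-only VCF 4.x subset:
`MUTECT/MUSE/RADIA/SNIPER/STRELKA` (per-caller `accepted|rejected`;
absent key = no opinion), `AF`, `R1ALT`, `R2ALT`, `RNADP`, `RNAALT`,
`RNASPAN`, `GEXP`, `GENE`, `TRANSCRIPTS`, `PPOS`, `PAA` (e.g. `R/Q`).
Missing optional keys are recorded as absent, never as zero.

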