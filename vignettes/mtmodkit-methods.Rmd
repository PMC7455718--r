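---
title: "Methods: mass, Ψ-score and codon-occupancy analysis of mt-tRNA modifications"
author: "mtmodkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass, Psi-score and codon-occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmodkit)
```

This vignette documents the models, parameter choices and numerical
conventions behind the package's three analysis stages, and what the
synthetic-data generators do and do not emulate.

## 1. Mass arithmetic for modified oligonucleotides

All masses are derived from elemental formulas over C, H, N, O, P, S —
never from stored decimal residue masses. Monoisotopic atomic masses
and standard average atomic weights are embedded to six decimals; the
proton mass used in negative-mode ion arithmetic is 1.007276 Da.

A residue is a nucleoside defined by its parent base plus an elemental
delta: every base methylation is +CH2, 2-thiolation is +S−O,
dihydrouridine is +H2, pseudouridine (written `Y`) has delta zero and
is therefore *mass-silent* — indistinguishable from U by mass alone,
which is why the Ψ-specific chemistry of sections 2–3 exists. The
bulkier side chains are stored as formulas from the community
modification reference: isopentenyl +C5H8, 2-methylthio-isopentenyl
+C6H10S, threonylcarbamoyl +C5H7NO4, taurinomethyl +C3H7NO3S,
carboxymethylaminomethyl +C3H5NO2, 5-formyl +CO and the queuosine side
chain +C7H10O2 versus G.

An oligonucleotide of *n* residues contributes *n* nucleosides plus
*n − 1* phosphodiester bridges (each +HPO3 −H2O); terminal
monophosphates add +HPO3 and a 2′,3′-cyclic phosphate is a
3′-monophosphate −H2O. Mature tRNAs default to 5′-monophosphate /
3′-hydroxyl. These conventions make mass exactly additive: the test
suite verifies, against an independent atom-count oracle, that
concatenation, cleavage and every modification delta shift masses by
exactly their formula masses.

**Monoisotopic vs average mode.** Fragment-level m/z values (hundreds
to a few thousand Da) are monoisotopic, as the instrument resolves
isotopes at that size. Whole-molecule masses of intact tRNAs
(~22 kDa) are reported in average mode: a species this large is
isotopically unresolved and its deconvoluted centroid tracks the
average mass. Under that convention the curated 69-nt mt-tRNA-Cys
computes to `r round(oligo_neutral_mass(mt_trna_cys(), "average"), 1)`
Da fully modified and 14.03 Da less (one CH2) without its minor m1A.

**The curated mt-tRNA-Cys entry.** The packaged sequence was
reconstructed from its published constraints — 5′-terminal pAGp,
3′-terminal CUUCCA-OH, anticodon GCA, the anticodon-arm RNase T1
fragment CA-i6A-A-Ψ-U-C-Gp, the RNase A fragment A-m1A-A-C-p, and
m1G9 — and is validated by mass: all four printed values (two fragment
m/z, two whole-molecule masses) are reproduced by computation from
this sequence. Canonical position labels (27, 28, 32, 37, 39, 58) are
attached where the short D-arm makes them differ from sequence
positions.

**Cyanoethylation.** Acrylonitrile adds +C3H3N (53.0266 Da, nominally
53) to the N3 of Ψ, converting it to 1-cyanoethyl-Ψ and rendering it
mass-visible; the secondary-amine side chains of τm5U, τm5s2U and Q
also react. `derivatize_cyanoethyl()` returns the fully derivatized
sequence by default and, on request, all 2^k partial combinations for
ambiguous matching.

## 2. Digestion, assignment, localization, stoichiometry

RNase T1 cleaves 3′ of G (and Q); RNase A 3′ of pyrimidines including
their modified forms. Internal products carry 5′-OH / 3′-phosphate,
terminal products inherit the parent termini, and each 3′-phosphate
product is optionally also emitted as its 2′,3′-cyclic (−H2O) variant.
Whether T1 cleaves after base-methylated G (m1G, m2G, m2,2G) is not
experimentally settled for this workflow; the default treats them as
resistant, and the rule object makes the sets fully configurable. The
default digest is complete (`max_missed = 0`), with missed cleavages
available behind a parameter.

Peak assignment compares each observed m/z against the fragment
catalog at 10 ppm default tolerance, both unshifted and shifted by one
delta from a small library (methyl, dimethyl, cyanoethyl, isopentenyl,
thio, dihydro, formyl) — one modification difference per fragment,
matching how fragments are assigned from the difference between
observed and calculated m/z in practice. Ties are ordered by absolute
ppm error then fragment start, so results are independent of peak-list
order.

CID localization predicts c/y (optionally w and a−B) ladders with the
delta placed at each candidate position and scores candidates by
matched-ion count. The exact scoring used by vendor assignment
software is not public; matched-ion counting is a documented,
deliberately simple stand-in. Ties are reported as an ambiguous set
with the 5′-most position as the point call. The c/y series satisfy
the bookkeeping identity mass(c\_k) + mass(y\_{n−k}) = M + H2O, which
the tests exploit as a closed-form oracle.

Site stoichiometry is the XIC ratio: summed intensity of the
modified-isoform fragments over summed intensity of all isoforms
covering the site. Intensities of chemically interconverted species
are pooled before normalization — by default m6A (produced from m1A by
the Dimroth rearrangement during handling) into m1A.

Whole-molecule deconvolution maps each ion to M = z·(m/z) + z·1.007276
and reports the intensity-weighted mean and spread; unknown charges
are inferred as the consecutive-integer assignment (charge increasing
as m/z decreases) minimizing the spread.

## 3. The Ψ score

CMC derivatizes Ψ at N3; the adduct blocks reverse transcription one
position 3′ of the Ψ, so CMC-plus libraries lose coverage 5′ of a Ψ
site relative to CMC-minus libraries. "Reads piled up at position x"
is implemented as spanning coverage of the read interval from the
*effective* 5′ end — the published definition does not elaborate
beyond that phrase, and spanning coverage is the natural reading that
makes the score a function of coverage drop. The 5′-proximal mismatch
shift (non-templated additions by the RT at an adduct) moves the 5′
end to the 3′ side of the most 3′ mismatch within the first two read
nucleotides, applied once and not re-evaluated after shifting.

The score contrasts the coverage ratio drop at x against the local
baseline drop at x+1 (see the formula in the README). Zero
denominators make the score undefined rather than pseudocounted —
pseudocounts would change the statistic — and a minimum-coverage gate
(default 20 reads at x+2 in both samples) keeps site calling away from
sparse regions. Replicate scores are averaged only where defined in
every replicate. The default calling threshold is 10 on the score
scale, restricted to reference U positions, and positions within 3 nt
of the 3′ end are never called (the score needs x+2, and the assay is
blind to 3′-terminal Ψ); the published analysis leaves its exact
cutoff to supplementary material, so the threshold here is a
configurable default, not a reproduced constant.

## 4. Codon occupancy and fold change

Footprints of 23–31 nt place the A site 14 nt from their 5′ end;
32–34 nt footprints, 15 nt. Footprints of 17–22 nt are retained by the
gel selection of the protocol but have no published offset, so they
are discarded from occupancy by default (the offset table is a
parameter). Occupancy is the A-site count divided by the mean count
over *all* CDS codons of the transcript in that sample — the
published phrase "averaged reads per codon" does not pin down the
denominator set; including zero-count codons keeps per-transcript mean
occupancy at exactly 1, which the tests assert to machine precision.

Codon positions with occupancy below 5% in two or more of the four
samples are removed, as are the start and stop codons. Fold change per
position is the ratio of replicate-mean occupancies (KO/WT); positions
are grouped by codon identity under the vertebrate mitochondrial code
(taken from the standard genetic-code registry via Biostrings), and
each codon's fold-change distribution is compared against the pooled
fold changes of all other codons by a two-sided Wilcoxon rank-sum
test. The published figure annotates per-codon significance without
printing the exact contrast; focal-codon-versus-pooled-others is this
package's documented interpretation.

## 5. Synthetic data: what it emulates, and what it does not

The generators fix every random draw under a user seed and emit the
truth tables their recovery tests consume.

* `simulate_ms_peaks()` digests a reference in silico and emits one
  peak per modification-isoform combination per fragment, intensity
  proportional to the product of per-site frequencies with optional
  log-normal multiplicative noise (the `cv` parameter; 5% in the
  noisy recovery test, a typical XIC replicate spread). It does not
  model isotope envelopes, adducts, retention time or chimeric
  co-elution.
* `simulate_psiseq_reads()` draws the 5′-end of each read from the
  exact survival distribution of a per-position drop-off process:
  baseline drop-off 0.005 per position (a typical RT processivity
  scale) plus a CMC-specific stop probability (0.4 in the standard
  recovery setting) at Ψ sites in the plus sample only. Reads always
  terminate at the 3′-CCA. It does not model ligation bias, mismatch
  errors, multi-mapping between near-identical tRNAs, or incomplete
  CMC removal at U/G.
* `simulate_footprints()` draws A-site codons proportional to dwell
  weights and back-computes 5′ ends through the offset rule, with
  lengths uniform on 23–34 (the length distribution is irrelevant to
  occupancy once offsets are correct). It does not model nuclease
  sequence bias or transcript-abundance differences beyond uniform
  codon pools.

Passing recovery tests therefore demonstrates the *analysis logic* —
filters, score, normalization, grouping — is correct, not that the
package overcomes real-data artifacts such as alignment ambiguity or
ion suppression.

**Problem sizes.** The recovery experiments run at 100 random MS
sites, 50,000 read pairs per Ψ-seq sample, and 200,000 footprints per
profiling sample over a 6-gene toy transcriptome of 100-codon CDSs —
sizes at which the statistical budgets (±0.02/±0.05 frequency error,
complete site/non-site separation, ±10% fold-change recovery) are
comfortably met while the whole suite runs in well under a minute.

## 6. The packaged catalog

The 22-entry catalog carries one curated sequence (mt-tRNA-Cys) and 21
synthetic stand-ins, clearly flagged in their provenance column. The
stand-ins follow field placement conventions (m1A9/m1G9, D20, Ψ27/28,
wobble-34 chemistry by decoding family, position-37 purine
modifications, m5C48, m5U54) and are constructed so the set reproduces
the published summary totals exactly: 1575 residues, 137 modified
positions (8.7%), 18 modification kinds, 52 Ψ sites, per-tRNA site
counts spanning 3 (Val) to 9. The residue total counts mature
sequences *including* the 3′-CCA and the post-transcriptionally added
G−1 of mt-tRNA-His; that convention is what makes the total come out
at 1575. The catalog is a test fixture for pipeline code and a
demonstration of `catalog_summary()`; it is not a measured
modification map of the 21 synthetic species.

## 7. Known limitations

* No raw-spectrum processing: inputs are centroided peak lists.
* Single-delta assignment by default; fragments carrying two
  unexpected modifications need the multi-delta flag or prior
  knowledge in the reference sequence.
* The Ψ-score coverage model ignores paired-end inner-mate gaps;
  reads are intervals.
* Digestion behaviour of RNases on rare modified residues is encoded
  as configurable assumptions, not measured kinetics.
* The mass-silent Ψ cannot be quantified by the MS stoichiometry
  route; its detection rests on cyanoethylation or the Ψ score.
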