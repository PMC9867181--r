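---
title: "Designing and verifying species-diagnostic COI assays with sscoi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying species-diagnostic COI assays with sscoi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscoi)
```

## The problem

Quarantine agencies routinely need to decide, within hours, whether an egg
mass or larva belongs to a regulated pest species or to a harmless
look-alike congener. Species-specific PCR on the mitochondrial cytochrome
oxidase I (COI) gene answers this with a single gel: a primer pair is
designed so that it amplifies a product of known size from the target
taxon and nothing from its relatives. Presence or absence of the band *is*
the identification — no sequencing required.

`sscoi` implements the computational side of building such an assay from a
taxon-labeled COI alignment:

1. barcode phylogenetics — uncorrected p-distances, neighbor-joining,
   bootstrap — to establish that the target is distance-separable from its
   relatives;
2. a diagnostic-window scan that finds alignment regions conserved within
   the target but divergent from every non-target species;
3. primer enumeration and pairing under length/GC/Tm/product-size
   constraints;
4. degenerate-aware in-silico PCR with a 3'-clamp mismatch rule,
   specificity/mixture panels, and a virtual gel;
5. a synthetic panel simulator so the whole pipeline is testable with no
   sequence downloads.

## Models and their assumptions

### p-distance and deletion modes

The p-distance between two aligned sequences is the proportion of
differing sites among comparable sites — uncorrected for multiple hits,
which is the convention in barcode gap analysis where distances are small
(here, at most ~0.1). A site is comparable iff **both** characters are
unambiguous bases; gaps and IUPAC ambiguity codes never count as matches
or mismatches. Under *pairwise* deletion (the default, and the common
barcoding choice) each pair uses its own comparable sites; under
*complete* deletion every column containing any gap/ambiguity in any
record is dropped globally first. Both are exposed because published
matrices rarely state which was used; per-pair comparable-site counts are
always reported so the effective overlap is visible. A pair with zero
comparable sites is an error, not a zero — silently reporting 0 would
fabricate identity.

### Neighbor-joining

`nj_tree()` is a from-scratch Saitou–Nei implementation with the
Studier–Keppler Q-criterion. Numerical choices:

* **Tie-breaking.** Among equal-Q pairs the lexicographically smallest
  index pair is joined (a strict `< tol` comparison with `tol = 1e-12`),
  so runs are reproducible and order-dependence is documented rather than
  accidental.
* **Negative branch lengths** (possible on non-additive input) are clamped
  to zero with the deficit moved to the sister edge, preserving the joined
  pair's total path length — the standard practical fix.
* On additive matrices the algorithm is exact: leaf-to-leaf path sums
  reproduce the input within 1e-9, which the test suite verifies against
  trees drawn independently with `ape`.

Trees are returned as ordinary `ape` `phylo` objects (basal trifurcation
for the unrooted topology) so downstream tooling applies unchanged.

### Bootstrap

Columns are resampled with replacement; a replicate tree is built per
resample; the support of each internal edge of the original-data tree is
the percentage of replicates containing the same leaf bipartition. Support
is mapped onto the original tree, not a consensus tree, matching how
barcode studies print supports next to branches. Replicates in which some
pair loses all comparable sites are skipped with a warning but stay in the
denominator — dropping them would silently inflate support. Each
replicate's RNG stream is derived from the user seed by fixed arithmetic,
so runs are bit-reproducible and independent of R's global RNG state.

### Diagnostic windows

Per column, the *target consensus* is the most frequent unambiguous base
among target records (ties broken alphabetically, for determinism).
"Conserved within the target" is the share of target records carrying that
base. "Highly variable among species" is deliberately formalized as the
**worst case over non-target species**: a window's discrimination is the
minimum, over species, of the number of columns where that species'
consensus differs from the target consensus. A diagnostic primer must
separate the target from its *closest* relative — sister species at
p ≈ 0.02 are precisely the failure mode of averaged divergence scores.

Columns with any gap or ambiguity in a target record are ineligible: a
primer must bind an unambiguous target site. A non-target species with no
unambiguous base at a column is counted as non-discriminating there
(conservative; absence of evidence is not divergence). Qualifying
sub-windows are merged into maximal windows; because both conservation and
the discriminating-site count are monotone under window extension within a
conserved run, merged windows still satisfy the thresholds — the suite
re-checks this from scratch.

The thresholds themselves (`min_within = 0.95`, `min_disc_sites = 2`,
`min_len = 18`) are exposed configuration. The source study selected its
region by expert inspection and published no numeric criteria, so these
defaults are stated as sensible field practice, not as a reconstruction of
the authors' choice.

### Primer constraints and melting temperature

Candidates are enumerated from the target consensus (one primer pool must
serve every target population), on both strands, and must pass: length
18–25 nt, GC 0.30–0.60, Wallace Tm 45–70 °C, homopolymer runs < 5, and no
3'-terminal self-complementarity of ≥ 4 bp (the reverse complement of the
3'-terminal 4-mer must not occur in the primer — a 3' end that can anneal
to the primer pool primes artifacts). The published diagnostic pair for
the Asian spongy moth assay (ASMF, 25 nt, GC 0.32, Wallace 66 °C; ASMR,
18 nt, GC 7/18, Wallace 50 °C) passes all defaults; reachability of that
pair is an acceptance test. AT-rich insect mitochondrial DNA motivates the
low GC floor.

Two Tm estimates are reported: the Wallace rule 2(A+T)+4(G+C) (advisory
above 14 nt — it is only calibrated for short oligos) and a
nearest-neighbor Tm from the unified dinucleotide ΔH/ΔS parameter set with
terminal initiation terms, a symmetry correction for self-complementary
oligos, and the monovalent-salt entropy correction
ΔS' = ΔS + 0.368 (N−1) ln[Na⁺]; Tm = 1000·ΔH / (ΔS' + R ln(Cₜ/x)) − 273.15
with R = 1.987 cal mol⁻¹ K⁻¹ and x = 4 for non-self-complementary
duplexes. Defaults are 50 mM monovalent salt and 500 nM primer — common
assay conditions, both configurable. Pairing filters on the
nearest-neighbor difference (default ≤ 10 °C; the Wallace spread of the
published pair is 16 °C, which would be misleading to filter on).

The annealing recommendation `[min(Tm) − 5, min(Tm) + 3]` is the bench
heuristic "Ta ≈ Tm_min − 5" widened upward; applied to the published
pair's Wallace Tms it gives 45–53 °C, bracketing the empirically optimal
49–56 °C range reported for that assay. It is a starting point for a
gradient, not a guarantee.

### In-silico PCR

The binding model is sequence logic only. A primer binds where it matches
with at most `max_mismatches` (default 2) mismatches overall and at most
`max_clamp_mismatches` (default 0) within the 3'-terminal `clamp_len`
(default 3) bases — mismatches in the clamp abolish extension, which is
what makes a single diagnostic 3' base decisive. Degenerate codes in the
**primer** match by IUPAC set intersection (primers are designed pools); a
degenerate code in the **template** matches only if every base it could
denote is covered by the primer base (templates are observed data — an
ambiguous read should not manufacture specificity).

Amplicons are reported for both template orientations: the canonical
forward-on-plus/reverse-on-minus configuration and its mirror image,
because PCR is indifferent to which strand a database record happens to
report. This makes the predicted product-size multiset invariant under
reverse-complementing the template, a property the suite fuzzes.

Detection is boolean. Wet-lab detection limits — the picogram-scale
template minima and the loss of signal at extreme mixture dilutions — are
concentration and kinetics phenomena with no sequence content, and are
deliberately outside the model; the mixture panel's output says so in an
attached note. Consequently a mixture lane is "detected" iff at least one
target copy is present and the pair amplifies the target at all.

The virtual gel renders each band on its own size row between the
bracketing ladder rungs (default ladder: DL2000 — 2000/1000/750/500/250/
100 bp). It is a reporting aid, not an electrophoresis migration model.

## The synthetic world

`simulate_panel()` states one fixed world, chosen to mirror the study
design the toolkit targets: a 658 bp fragment (the canonical COI barcode
length), 14 target sequences (one per geographic population in the
emulated survey), five congeneric species × 3 sequences, within-species
per-site substitution probability 0.005, and species divergence drawn
uniformly from [0.06, 0.08] — the barcode-gap regime reported between the
target and its confusable congeners. Substitutions are uniform
(Jukes–Cantor-like) with no indels: COI barcodes are protein-coding and
effectively indel-free, and the downstream statistic is the uncorrected
p-distance, so rate heterogeneity and codon structure would add parameters
without changing what is being tested. Optionally, exact primer binding
sites are spliced into every target sequence (the packaged default plants
the published pair at positions 60/585, a 543 bp construct — the true
assay product size was never published, so this fixture size is labeled as
constructed throughout).

What a green test on this world establishes: the pipeline recovers planted
diagnostic signal, reproduces the generating divergence regime within
binomial sampling error, and is internally consistent. What it does not
establish: performance on real alignments with indels, heterogeneous rates
across codon positions, intra-species haplotype structure, NUMTs, or
sequencing error — none of which the generator emulates.

## Degenerate inputs and edge cases

* Zero comparable sites → error naming the pair (never a silent 0).
* Bootstrap replicates with undefined distances → skipped, warned,
  counted.
* All-zero distance matrices → a valid tree with zero branch lengths.
* A primer longer than its template → empty site list, not an error.
* The no-template control lane is always reported and always undetected.
* Newick output fixes branch lengths at six decimals and writes integer
  bootstrap supports as internal node labels — the encoding with the
  widest parser compatibility; distance TSVs print two decimals, matching
  the display precision of published barcode matrices.

## Design choices where the design was open

* **FASTA parsing** is delegated to Biostrings; validation (duplicate ids,
  empty records, non-IUPAC characters with positions, `U`→`T`, case) is
  package code, because the error contract is part of this toolkit's
  interface.
* **Newick writing** is package code (the 6-decimal/node-label format is
  pinned); re-parsing in tests uses `ape` as an independent oracle.
* **NJ is authored here** rather than wrapping `ape::nj`: the tie-break
  and negative-length policy are part of the stated behavior; `ape` serves
  as the independent topology oracle in the tests instead.
* The published primer strings ship in `known_primers()` as data: they are
  the worked example the field would reach for first.

## Known limitations

No thermodynamic duplex/hairpin folding, no multiplex compatibility
scoring, no qPCR/LAMP/RPA design, no protein-frame awareness in the
window scan, and no network access anywhere in the library (the optional
`scripts/fetch_reference_panel.R` documents how to reproduce published
distances from public accessions when a connection is available).
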