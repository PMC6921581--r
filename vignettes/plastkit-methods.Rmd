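---
title: "Methods and design of plastkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of plastkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plastkit` analyses plastid genome variation and strand-specific plastid
transcriptomes, and ships a synthetic-data generator that gives every
analysis stage a known ground truth. This vignette describes the models
and procedures, the parameters that matter, the design decisions taken
where several defensible choices existed, and what the synthetic tests do
and do not demonstrate about real data.

## Genome-level methods

### Inverted-repeat detection

`find_inverted_repeats()` searches for the longest pair of disjoint
intervals whose sequences are exact reverse complements. Matching is
seed-and-extend on a k-mer join (default seed 32 nt): maximal exact
inverted matches correspond to maximal runs of consecutive seed hits on an
anti-diagonal, so the scan is fully vectorized. Only repeats of at least
`min_ir` bp (default 1000 — well below any true plastid IR, far above
chance matches in a 30–150 kb genome) are considered; ties on length are
broken by the leftmost start. Single-copy regions are the two gaps between
the repeats on the circle: the longer is labelled LSC, and the repeat that
follows the LSC in circular order is called IRb, matching the conventional
LSC–IRb–SSC–IRa deposit layout. Highly repetitive seeds (more than 25
occurrences) are dropped before the join; a genuine IR longer than
`min_ir` always retains non-repetitive seeds in practice, but a genome
consisting mostly of one low-complexity family could in principle defeat
the heuristic.

### Distances on alignments

Substitution counts consider only columns where both rows have unambiguous
non-gap bases; N and gap columns are skipped. Indel distance is computed
under two models: `indel` counts columns gapped in exactly one row,
`indelblock` counts maximal runs of such columns (one event per contiguous
block). Published whole-plastome comparisons do not always state which
model a printed indel count uses, so both are always reported side by
side. Distances are symmetric and zero on the diagonal by construction.

### SSR discovery

`find_ssrs()` reports maximal tandem repeats of unit sizes 1–6 with the
standard microsatellite-survey thresholds: mononucleotide tracts longer
than five nucleotides, at least four units for di- and trinucleotides, at
least three units for tetra-, penta- and hexanucleotides. Implementation:
for each unit size u, positions where `s[i] == s[i+u]` are computed in one
vector operation; maximal runs of equalities of length m correspond to
tandem tracts of length m + u. The reported tract includes a trailing
partial unit; the unit count is the number of complete units. Units that
are themselves periodic (ATAT = 2×AT) are reported only at their smallest
period, and the unit is given in canonical phase (lexicographically
smallest rotation). The scan runs on the linearized sequence as deposited;
origin-spanning repeats are not detected, matching the behaviour of the
usual survey tools on GenBank records. Compound (adjacent) loci are
reported as separate loci.

Cross-genome SSR polymorphism maps each genome's loci into the columns of
a whole-genome alignment, clusters loci of the same unit size by column
overlap, and flags a position as variable when unit counts differ (absence
in a genome also counts). Mononucleotide loci are flagged separately and
excluded from the recommended-marker set: their apparent length variation
in real data is commonly within-individual heteroplasmy rather than a
stable genotype.

### Segregating sites and Ka/Ks

A site is segregating when at least two distinct unambiguous bases occur
across the aligned genomes. Classification is contextual: the site is
nonsynonymous if substituting any observed allele into any genome's own
codon (other positions held at that genome's state) changes the amino
acid. Codons containing a gap or N in any genome are excluded and the
exclusion count is reported. Alleles creating a premature stop are
flagged. Genes are partitioned into `identical`, `synonymous-only` and
`nonsynonymous` classes; the classes are exhaustive and disjoint.

Pairwise Ka/Ks uses Nei–Gojobori (1986): per-codon synonymous site counts
as the fraction of the three possible changes at each position that
preserve the amino acid, with changes to stop codons counted as
nonsynonymous so that synonymous + nonsynonymous sites always sum to 3 per
codon; differences averaged over all minimal mutational pathways between
differing codons with equal weight, excluding pathways through stop codons
(if every pathway is blocked, all are used and the pair is flagged);
Jukes–Cantor correction d = −3/4·log(1 − 4p/3) applied to pS and pN. Both
corrected and uncorrected proportions are emitted because reference
implementations differ in whether the printed ratio is corrected. The
ratio is reported only when Ks > 0; p ≥ 3/4 makes the correction undefined
and is flagged as saturation. Codon-model maximum-likelihood dN/dS is out
of scope.

### Phylogenetic input preparation

`remove_ira()` drops all alignment columns overlapping the IRa interval of
a reference row (including insertion columns internal to it), so the
duplicated repeat does not double-weight the signal. `mask_homopolymers()`
masks columns belonging to a mononucleotide run longer than five
nucleotides, measured on the ungapped sequence of any row; when rows
disagree on run length the union of implicated columns is masked
(conservative: exactly the non-informative signal is removed). Masking is
suppressed inside annotated CDS — the wording of this rule in the
comparative literature is ambiguous, and the non-coding-only reading was
chosen because coding homopolymers are not subject to the assembly
heteroplasmy that motivates masking. The mask is a separate log, so
output plus mask reconstruct the input.

`simple_indel_coding()` codes each distinct gap block (maximal gap run
with identical start and end columns across taxa) as one binary character:
1 for taxa with exactly that block, `?` for taxa whose gap strictly
contains the block's span (the character is inapplicable), 0 otherwise.
`concatenate_cds()` splices and concatenates one copy of each
protein-coding gene in alphabetical order, filling genes missing from a
genome with `?` and writing a partition file; genes whose extracted
lengths differ across genomes raise an error naming the gene, because the
function expects length-matched CDS (true for the package's planted
haplotypes, whose indels are non-coding; diverged real genes should be
supplied as per-gene alignments). Writers emit relaxed PHYLIP, RAxML-style
partition text and a NEXUS with a mixed DNA + binary (0/1, missing `?`)
matrix, the inputs expected by the usual ML and Bayesian tools; tree
inference itself is out of scope.

## Transcriptome-level methods

### Strand separation

Each properly-paired fragment is assigned to the transcriptional strand
implied by the library convention, decoded from the SAM flags. Under
`fr-firststrand` (dUTP chemistry) read 1 sequences the strand opposite
the transcript, so read-1-reverse (equivalently read-2-forward) means a
plus-strand fragment; `fr-secondstrand` is the inverse. The convention of
a given real library must be supplied by the user — the package makes no
claim about any particular data set. Records that are not properly paired
or whose mate-strand flags are inconsistent within the pair are routed to
an `unassigned` set with a reason code; the partition is exhaustive and
disjoint, and read accounting (plus + minus + unassigned + discarded =
input) is asserted in the tests.

### MTPT read filtering

Plastid DNA inserted into the mitochondrial genome (MTPT) produces
mitochondrial transcripts that map onto the plastid reference and can
masquerade as plastid reads — in particular as false editing signal,
because the insert copies are diverged and unedited. Within the
insert-homologous intervals, a read is discarded if and only if it carries
at least one mismatch at or above the base-quality floor (default Q20)
that is not a candidate editing change (C→T for plus-strand assignments,
G→A for minus). Reads outside the intervals are untouched. The filter is
deliberately one-sided: a mitochondrial read whose covered stretch happens
to contain no divergence marker is retained, which leaves a small
residual contamination proportional to exp(−divergence × read length);
the editing thresholds absorb it.

### Coverage, TPM and antisense calls

Depth of coverage counts aligned bases per reference position and strand
(CIGAR-aware: M/=/X consume reference and add depth, D/N consume without
adding). Per-feature mean depth is the average over the gene span (exons
and introns of the primary transcript — reads are unspliced pre-mRNA in
the simulation, and plastid introns are genuinely covered in real data).
Because mean per-base depth is already length-normalized, TPM is simply a
feature's mean depth divided by the sum over quantified features, times
10⁶; the sum-to-10⁶ invariant is asserted per sample. Only protein-coding
genes are quantified: rRNA is depleted during library preparation and
tRNAs are lost with the small-RNA fraction, so their apparent coverage is
not interpretable.

Antisense transcripts are maximal intervals longer than 100 nt on the
strand opposite every overlapped annotated feature where depth stays at or
above a floor. In `auto` mode the floor is the sense mean depth of the
least expressed protein-coding gene in the same sample — the depth
corresponding to the TPM of the weakest annotated transcript, which is the
natural "as abundant as a real gene" criterion; a fixed manual floor is
also supported, and whether a floor should be per-sample or global is a
user decision (auto mode is per-sample). Above-floor runs separated by at
most `merge_gap` (default 100 nt) are merged first: paired-end coverage of
a short transcript dips in the fragment interior that neither 100 nt read
reaches, and the merge bridges exactly that sequencing artefact, not a
biological gap.

### Editing discovery and quantification

Pileups are built per strand with base-quality awareness: bases below the
floor are excluded from the A/C/G/T counts but kept in depth. Candidate
sites are every position whose reference base is C on the transcribed
strand — reference C in the plus-strand pileup (edits appear as T) and
reference G in the minus-strand pileup (edits appear as A; counts are
complemented so the rate is always T/(C+T) on the transcript). This
exhaustive scan replaces the variant-caller pre-screen of the original
two-step workflows; it is strictly more sensitive and the reporting
thresholds are applied identically downstream. A site is reported when at
least one individual has depth ≥ 200 and either rate ≥ 5% or ≥ 10 edited
bases (the smaller criterion admits the site). Sites failing the
thresholds in every individual but showing edited bases in all of them are
listed in a separate below-threshold annex rather than silently dropped.
Sites in rRNA/tRNA are not evaluated (biased coverage). Raising the depth
floor can only remove sites (monotonicity, asserted in tests).

Codon effects are annotated from the exon map: the codon before and after
editing with amino acids (`TCA (S) => TTA (L)`), silent changes,
premature-stop creation and start-codon creation (edited ACG at codon 1).
Conservation across taxa uses an orthologous CDS alignment: per taxon the
homologous position is `T` (editing hard-wired in DNA), `Edit` (C with the
position on the taxon's known-edit list), `C` (C, known unedited), `C?`
(C, no editing information) or `NA` (gapped). Intergenic sites are `NA`
for all taxa — intergenic regions cannot be aligned reliably across
species.

### Group comparisons

Expression between groups (sexes or haplotypes) is compared per feature by
a two-sided Welch t-test on log2(TPM + 1) — the smallest-assumption choice
for 3-vs-3 designs — with Benjamini–Hochberg adjustment across features.
Editing rates are compared per site by a two-proportion test on pooled
edited/unedited counts per group, with BH adjustment across sites and
per-individual mean ± SD reported alongside. Both tests are deliberately
simple and are isolated behind `compare_groups()` / `compare_editing()` so
a different test can be substituted. Cross-haplotype editing comparisons
match sites at homologous positions through the planted alignment (for
real data, through whatever coordinate map the user supplies); raw depths
are never compared across haplotypes sequenced on different platforms —
only rank structure and rates.

## The synthetic-data generator

`simulate_study()` emulates the design of a two-haplotype, two-sex plastid
transcriptome study. Its defaults are the package's study conditions:

* **Plastome**: 30 kb circular toy genome (LSC 17 kb, SSC 5 kb, IR 4 kb) —
  one fifth the size of a real ~151 kb plastome so that full-pipeline runs
  finish in about a minute; 16 protein-coding genes of 90–260 codons and 3
  tRNAs placed in the single-copy regions with ≥ 450 bp spacing, ~15% of
  genes carrying one intron, one gene with an ACG start codon whose
  editing creates the start.
* **Haplotypes**: two, each separated from the ancestral sequence by
  exactly 50 substitutions and 10 indel events (3 of them realized as
  unit-count changes at planted SSR loci, the natural mode of SSR
  polymorphism; the rest 1–12 bp insertions/deletions in non-coding
  sequence, ≥ 25 bp apart so each event is one gap block). Edits avoid the
  IRs, SSR tracts, editing sites and terminal codons; the true alignment
  is emitted directly from the edit operations, so distance recovery is
  exact by construction and no aligner is involved.
* **SSRs**: ten loci spanning the unit-size classes, planted in
  intergenic space with flanks forced non-extending; the sequence is
  scrubbed so the detectable SSR set equals the planted set exactly.
* **Editing**: 22 sites (16 coding, 2 intronic, 4 in transcribed UTRs)
  with per-haplotype true rates between 0 and 0.96, mirroring the typical
  plastid editome: high-rate serine→leucine and histidine→tyrosine
  restorations, intermediate silent sites, a low-rate stop-creating site,
  a low-edited ACG start, and one haplotype-specific site (0 vs ~6%).
  Rates are identical across sexes and individuals within a haplotype —
  the null condition for the sex comparison. Editing is applied per
  fragment (both mates of a molecule share the edit state) with a
  Bernoulli draw at the site's true rate.
* **Antisense**: three transcripts of 400–450 nt at expression comparable
  to protein-coding genes, two over tRNAs and one over a gene's 3′
  region; one is present in haplotype 2 only.
* **Mitochondrial inserts**: two plastid-homologous intervals (1000 and
  377 nt — the smaller mirrors the scale of real insert tables) at 2–3%
  divergence; marker substitutions never mimic candidate edits (no C→T or
  G→A), so reads from the insert copies are unambiguous filter truth. 5%
  of reads over the insert intervals are mitochondrial in origin.
* **Sequencing**: 100 nt paired-end reads, fragment length 250 ± 30 nt,
  mean per-base depth 500, per-gene expression multipliers lognormal
  (σ = 0.5) clamped to [0.5, 3] with per-individual lognormal noise
  (σ = 0.15), and uniform 0.2% base-call errors. 95% of miscalled bases
  get quality Q10 (below the Q20 floor) and 5% get Q30 — a simple model of
  the fact that most real miscalls are low-quality, which is what makes
  base-quality-aware filtering meaningful. Reads are emitted pre-aligned
  at their true positions with all-M CIGARs; mapping is out of scope.

What the generator does **not** emulate: splicing (reads are contiguous
over unspliced transcripts, so the intron-versus-exon coverage contrast of
real data is absent), IR-duplicated genes, soft-clips and multimapping,
indel sequencing errors, heteroplasmy beyond SSR unit variation, platform
differences between haplotypes, and U→C editing. Passing the synthetic
tests therefore demonstrates correctness of the algorithms under clean
alignments and a known truth — not robustness to mapping artefacts or
library pathologies of real data.

## Numerical and statistical choices

* Coordinates are 1-based inclusive in every emitted table (stated in a
  header comment); the only 0-based output is bedGraph, whose format
  mandates it.
* Determinism: every stochastic step derives its seed from the single
  study seed (with per-purpose and per-individual offsets), so one seed
  reproduces byte-identical outputs and manifest checksums.
* The per-haplotype editing rate reported for a site is the pooled
  T/(C+T) and mean ± SD across that haplotype's six individuals.
  Individual estimates are binomial draws around the true rate; the
  package's whole-pipeline check asserts the 3-SD binomial band on the
  pooled per-haplotype estimates (the granularity at which rates are
  reported) and that the overwhelming majority of individual estimates
  fall inside their own band — a strict "all individual estimates within
  3 SD" assertion would be violated by ordinary sampling in about half of
  all studies, since roughly 260 such draws are made.
* Problem sizes: unit tests use a 12 kb / 6-gene configuration at depth
  150 (a few seconds per study); the whole-pipeline check runs the full
  default conditions (30 kb, 12 individuals, depth 500, ~1 minute); the
  null-behaviour check repeats the small configuration over 20 seeds.
  These sizes were chosen so the generator's statistical properties are
  testable interactively while the full conditions still exercise every
  code path at realistic depth.
* Degenerate inputs: all-zero TPM is an error; zero C+T at a candidate
  site gives an undefined (missing) rate for that individual; a group
  with fewer than two replicates is an error; configurations whose genes
  do not fit the single-copy regions fail with a message naming the
  constraint.

## Known limitations

* `concatenate_cds()` requires length-matched CDS across genomes; use
  per-gene alignments for diverged taxa.
* The MTPT filter's residual contamination (marker-free reads) is not
  removed; at the default 2% divergence and 100 nt reads about 13% of
  insert-derived reads survive, a ~0.7% depth contribution at the default
  contamination level.
* Circular-origin-spanning features, reads and repeats are not handled;
  linearize so that no feature crosses the origin (true for the usual
  GenBank deposits).
* The two-proportion editing test treats pooled reads as exchangeable;
  with very deep data it will detect biologically tiny rate differences,
  and at FDR 0.05 it produces the expected false-positive rate under the
  null.
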