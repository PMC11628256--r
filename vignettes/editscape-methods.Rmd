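---
title: "Methods: phasing, synthetic assembly and editing-outcome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasing, synthetic assembly and editing-outcome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscape)
```

# The problem

Whole-genome evaluation of CRISPR/Cas9 editing in a clonally propagated F1
hybrid faces a specific obstacle: the F1 is heterozygous, with one genome
inherited entire from a homozygous parent and one recombinant haplotype from
a heterozygous parent. Read alignment against either parental assembly alone
mis-assigns haplotype-specific variation as editing-induced. The remedy is a
*synthetic F1 assembly*: infer which parental haplotype was inherited along
every chromosome, then concatenate the corresponding parental-assembly
intervals into a reference tailored to the F1 clone. Against that reference,
variant calls can be hard-filtered, purged of variants shared with
transformation controls, intersected with candidate Cas9 off-target sites,
and the on-target editing outcomes classified from deep-sequenced amplicons.

`editscape` implements each of those stages as reusable functions, together
with a truth-tracked simulator so that every stage is testable without any
external data download.

# Haplotype markers and phasing

**Markers.** Two SNP tables — each haplotype of the heterozygous parent
aligned independently against the reference — are intersected to positions
called in *both* haplotypes where the two alternate alleles differ
(`derive_marker_set()`). Positions called in only one table are excluded: at
such a site the F1's alternate-allele comparison cannot distinguish "the
other haplotype was inherited" from "no variant", so these half-informative
sites would only add noise. Positions where both haplotypes carry the same
alternate allele are likewise uninformative and removed. Within one table,
any reference position occurring more than once is treated as an ambiguous
alignment and dropped entirely, and indel rows are discarded: markers are
biallelic substitutions only.

**Binning.** F1 alternate alleles at marker positions are labelled A or B by
exact allele match (`match_f1_alleles()`); calls matching neither haplotype,
or both (a multi-allelic tie), are dropped before windowing. A window of 20
consecutive labelled markers slides in steps of one; a window is assigned to
a haplotype when at least 80% of its labels agree, i.e. 16 of 20 — the
boundary is sharp and `ceiling()`-based, so 16/20 assigns and 15/20 does
not. Each marker then takes the haplotype of the assigned windows covering
it; markers covered by conflicting windows, or by none, stay unassigned.
Maximal runs of same-haplotype markers become bins, and unassigned gaps
between two bins of the *same* haplotype are absorbed. Gaps between bins of
*different* haplotypes are left open: they are the breakpoint intervals, and
the reported breakpoint is the integer (floor) midpoint between the
flanking markers (`detect_breakpoints()`). The midpoint minimizes the
worst-case placement error given that no read-level information about the
exact crossover position survives binning.

Two design choices here were genuinely open. The window step (the rule's
published form does not state one) is 1 marker, which maximizes resolution
and keeps the merge semantics simple. Whether the congruence rule uses
`>=` or `>` is also unstated; we use `>=` (16/20 passes) and report an A/B
conflict within a window as unassigned.

# The synthetic assembly

All chromosomes of the homozygous parent pass through whole
(`<chrom>_DM`). For the recombinant haplotype (`<chrom>_RH`), each
reference-coordinate breakpoint must be translated into the coordinates of
each source haplotype. The translation anchor is the *nearest flanking
marker on the retained side*: its query coordinate is shifted by the
reference-coordinate distance to the breakpoint. This is our choice — the
source pipeline does not describe its translation rule — and it is exact
whenever no indel variation separates the marker from the breakpoint.
Terminal segments extend to source position 1 and to the source chromosome
end, so unaligned chromosome ends travel with the inherited haplotype.

The segment map uses AGP component-line semantics (1-based, inclusive,
orientation fixed to `+`; inversions are not modelled because co-oriented
haplotype assemblies are assumed). `stitch_assembly()` concatenates source
substrings; assembly gaps (`N` runs) pass through verbatim. Coordinate
liftover is an affine shift inside the containing segment; positions in
uninherited source regions raise a `"not inherited"` error and features
spanning a segment boundary raise `"split feature"` rather than returning a
silently wrong interval.

Because breakpoints are only resolved to the flanking-marker interval, the
stitched sequence can differ from the truly inherited sequence *inside*
that interval; the tests assert identity everywhere outside ±20 markers
around each true crossover.

# Variant filtering and off-target triage

Hard filters use the annotations QD, MQ, DP and AD. Two printed filter
expressions coexist in this workflow's lineage: a conjunctive
`QD < 2.00 & MQ < 50.00` used when selecting calls for haplotype binning,
and a comma-separated list `QD < 2.00, MQ < 50.00, DP < 4, DP > 50, AD < 4`
used for event call sets. Both readings are provided as modes
(`filter_config(mode = "assembly")` / `mode = "event"`), with the event mode
reading the list disjunctively: any violated criterion removes the record.
All comparisons are strict, so records exactly at a threshold are retained.
AD is compared against the *maximum* alt-supporting depth — the permissive
reading of an unindexed "AD" — and records missing an annotation are removed
with reason `"missing"`.

Control subtraction removes any event record whose reference span overlaps
a control record's span on the same chromosome, *regardless of allele
identity*. That mirrors interval subtraction of VCFs (the behaviour of
`bedtools subtract`), not an idealized allele-aware subtraction; control
sets are applied cumulatively, so retained counts can only decrease as
controls are added. `set_intersections()` computes the exclusive per-subset
counts an UpSet plot displays.

Off-target enumeration scans both strands for 20-nt protospacer matches with
up to 5 mismatches adjacent to a canonical (`NGG`) or non-canonical
(`NGA`, `NAG`) PAM. Mismatches are counted on the protospacer only; the PAM
must match its IUPAC pattern exactly and contributes nothing to the mismatch
budget. Ambiguous genome bases never match: an `N` counts as a spacer
mismatch and disqualifies a PAM even under the pattern's `N`. DNA/RNA bulges
are unsupported (the search is mismatch-only), and no activity scoring
scheme is applied. The implementation (Biostrings pattern matching plus PAM
verification) is checked in the test suite against a brute-force
position-by-position oracle over random genomes and random spacers.

Variants falling inside a 23-bp site span are triaged against cross-sample
evidence: a key called identically in two or more independent events, or in
any control, is tissue-culture background (`shared_background`); a variant
with at least 2 supporting reads in another sample at a fraction below the
calling threshold is `allele_fraction_background`. The 2-read default is a
free parameter — the underlying read-support cutoff is not published.
Remaining candidates stay `putative_cas9`, but single-base substitutions
carry evidence text noting that SNVs are not a common outcome of
Cas9-dependent editing, so they remain background-leaning rather than being
auto-promoted.

# Amplicon outcome calling

`call_amplicon_outcomes()` reimplements the deep-sequencing caller
convention of a *comparison range* (100 bases either side of the predicted
blunt cut, 3 bp 5' of the PAM), a *minimum frequency* (25, read as a read
count, the convention of the tool it emulates, not a percentage) and a
*10-base wild-type marker*. The window is assumed symmetric around the cut
site. A read is classified only if it contains both `wt_marker`-length
reference flanks immediately outside the window as exact substrings; the
segment between the anchors is the read's window allele and its length
change relative to the reference window is the net indel, collapsing
compound events to one signed number while the full allele string is kept
for pathway calls. Anchor-based matching was chosen over global alignment
deliberately: with large replacement alleles, optimal-alignment gap
placement inside a novel insert is ambiguous and can drift into the flank,
discarding legitimate reads, whereas exact flank anchoring is deterministic
and fast. When a flank sequence recurs by chance, the anchor pair whose
enclosed segment is closest in length to the reference window is taken.

**Repair pathways** (`classify_repair()`) are inferred from the allele's
structure, recovered by longest exact prefix/suffix anchoring against the
reference window (deletions are left-aligned before scanning, since anchor
maximality right-shifts a deletion with junction homology):

* pure deletion with junction microhomology ≥ 2 → `MMEJ`;
* insertion of 1–3 bp at the cut, or a ≤ 3-bp deletion without junction
  homology → `cNHEJ`;
* replacement (both a removed span and an inserted sequence) whose insert
  has no exact ≥ 20-bp match in the local reference → `SDSA_like`;
* anything else, including wild type and short substitution runs, is
  `unclassified`.

`scan_microhomology()` returns the longest k such that the k bases starting
at the deletion start equal the k bases starting just past the deletion end
(left-aligned junction homology), verified against a character-by-character
oracle.

**Zygosity** (`classify_site()`) uses two free parameters the source
workflow leaves unquantified: an error floor of 0.01 (fractions at or below
it are noise — one read in a hundred does not make an allele) and a fixed
threshold of 0.35, chosen so a 50% diploid allele passes comfortably while
sub-allelic chimeric fractions do not. A site is mosaic when one haplotype
carries two or more distinct non-reference outcomes or when more than two
outcomes are present at a diploid locus. Transgenerational editing is
flagged when a site with a fixed or wild-type majority (≥ 0.65) also shows
an outcome inside the band (0.01, 0.35] with at least 4 supporting reads;
the band and read floor are likewise free parameters, documented rather
than hidden.

# What the simulator emulates — and what it does not

`sim_config()` defaults describe the study layout this package was built
around: 12 chromosomes with crossovers planted on chromosomes 1, 2, 5, 7, 8
and 9 (the remaining six inherit one haplotype entire), a marker density of
0.01/bp, haplotype divergence of 0.015/bp, 1% marker noise (half flips,
half dropouts), background SNVs and indels with passing annotations, an
excess of artifactual 1-bp indels, and a small set of filter-fodder records
each violating exactly one hard-filter criterion so every clause is
exercised independently. Chromosomes are 200 kb — 2,000 markers each, the
marker count at which the acceptance checks run — and each haplotype
chromosome carries a short random pad so haplotype coordinates genuinely
differ from reference coordinates. The heterozygous parent's true divergence
is not published; these densities are desk-scale choices, not calibrations.

Deliberate non-realism, so that test outcomes stay attributable: marker
placement is uniform without replacement and background variants never
collide with parental sites (truth categories stay disjoint); read
qualities are constant Q40 and base errors are not simulated in reads
(error handling enters through marker noise and VCF-level artifacts, since
caller semantics, not sequencing-error modelling, are the target); there is
no read-level alignment simulation, no coverage titration and no polyploid
dosage. Edited-read simulation draws multinomial outcome counts, builds
MMEJ deletion junctions with engineered ≥ 2-bp microhomology (deletion
sizes of MMEJ outcomes should be ≥ 2 apart or construction fails loudly),
and gives replacement inserts junction-distinct end bases so the planted
replaced span is unambiguous. Passing tests on this simulator therefore
demonstrate the *logic* of each stage, not robustness to real sequencing
noise or alignment artifacts.

Determinism is a contract: the same `sim_config` (seed included) yields
byte-identical FASTA/VCF/TSV outputs, and the demonstration pipeline
(`run_demo()`) writes byte-identical reports across runs. The demo default
is down-scaled (4 chromosomes × 50 kb) to keep a full end-to-end run in a
few seconds; the acceptance checks use the full 12 × 2,000-marker layout.

# Known limitations

* Breakpoints are resolved only to the flanking-marker interval; with 1%
  noise the practical uncertainty is a handful of markers.
* Chromosomes with fewer labelled markers than one window are left
  unassigned (with a warning) and their recombinant haplotype is omitted
  from the assembly rather than guessed.
* The off-target scan is exhaustive and exact but mismatch-only; bulged
  sites are invisible to it.
* Zygosity classification of untagged (unphased) outcome sets cannot
  distinguish a 30% chimeric edit from trace continued editing; both sit
  below the fixed threshold and are reported via the TGE flag at a
  wild-type-majority site.
* Interval subtraction of controls deliberately ignores allele identity; a
  control SNV masks an event indel at the same position.
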