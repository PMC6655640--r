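---
title: "Triage and characterization of mycovirus genomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage and characterization of mycovirus genomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycovir)
```

# The problem

RNA mycoviruses are routinely discovered as a side effect of fungal RNA-seq:
reads that fail to map to the host genome assemble into contigs, and a small
number of those contigs encode a viral RNA-dependent RNA polymerase (RdRP).
Because no eukaryotic genome encodes a virus-type RdRP, that single domain is
a near-perfect discovery marker. `mycovir` implements the post-assembly
stages of this workflow — RdRP triage, family-diagnostic feature detection,
and ICTV-style species demarcation — together with a synthetic genome
simulator that makes every stage testable offline. This vignette documents
the models, the tunable parameters, and the design decisions.

# ORF prediction and the two genetic codes

ORFs are found in all six frames. Within one reading frame, each
stop-bounded region yields at most one ORF, running from its 5′-most ATG (or
from the region start when `require_start = FALSE`) to the next in-frame
stop or the sequence end; the stop codon is inside the `[start, end)`
coordinates but not in the translation. This one-ORF-per-region convention
is one of several defensible enumeration rules; the test suite's six-frame
oracle implements the same definition independently, so the choice is
explicit and checked. Coordinates are 0-based half-open internally;
reporting layers convert to 1-based inclusive.

Two genetic codes are supported: the standard code and the
mold-mitochondrial code, which differs only in reading UGA as tryptophan.
Mitoviruses replicate in mitochondria and their single ORF is interrupted
by in-frame UGA codons under the standard code — triage therefore predicts
ORFs under both codes and deduplicates calls that agree. Codons containing
degenerate bases translate to `X` and never terminate an ORF.

The default minimum ORF length for triage is 100 aa. This is an ecosystem
convention (the common default of transcriptome ORF predictors), not a
biological constant; it is configurable down to 1 aa. The smallest RdRP
proteins in the packaged catalog are ~460 aa, so 100 aa is conservative for
the target class while suppressing most random open regions.

# The RdRP motif-block scanner

The internal scanner is deliberately *not* a profile-HMM implementation.
Each bundled model is an ordered set of three ungapped position-specific
score matrices (PSSMs) representing the conserved polymerase motifs (an
aspartate-rich motif A, a glycine/serine-rich motif B, and the catalytic
motif C around the GDD triad). A PSSM column assigns log2-odds +3.81 to the
consensus residue and −1.66 otherwise (consensus probability 0.7 against a
uniform background); unknown residues score as mismatches.

Scanning finds the best in-order, non-overlapping placement of all blocks by
dynamic programming. A hit requires every block to reach 60% of its maximum
attainable score. This per-block floor is what gives the scanner its
specificity: a chain-score threshold alone lets a few percent of random ORFs
through per model, which at six models and dozens of decoy ORFs would
swamp a desk-scale screen. With the floor, decoy transcriptomes essentially
never produce hits while planted baits score near the model maximum.

The e-value-like statistic is a calibrated exceedance: each model is scored
against 200 random background proteins (length 300 aa; seeds are fixed per
model and recorded in the calibration), a Gumbel null is fitted by the
method of moments, and a hit's e-value is the null exceedance probability
times the search size (the number of ORFs scanned). It is documented as an
e-value-like quantity, not an HMMER e-value; the `domtblout` ingestion path
exists for bit-exact parity with an external profile search, and the triage
logic treats the two sources identically. The default triage cut-off of 10
follows the over-inclusive convention for catching distant RdRP similarity.

# Feature detectors

**Slippery sites.** The −1 frameshift heptamer is matched literally as
X XXY YYZ (three identical, three identical, anything). The pattern admits
homopolymer heptamers (X = Y); these are reported with a low-complexity flag
rather than suppressed, since the pattern itself does not forbid them.
Pseudoknot confirmation is out of scope; the record carries the heptamer
and its position only.

**Termination–reinitiation junctions.** Three geometries are classified
relative to the ORF1 stop codon: the AUGA tetramer (ORF2's AUG overlapping
the stop's first two bases, −1 frame), one-base stop/start overlaps
(UGAUG/UAAUG, −1 frame), and a start codon 4–8 nt before the stop with a
+1 frame relation. ORF2 starts beyond ±10 nt of the stop are treated as
independent ORFs. Because ORF callers may extend ORF2 upstream of the true
reinitiation codon (any in-frame ATG upstream without an intervening stop
captures the call), the classifier re-anchors on in-frame ATGs inside the
junction window before giving up.

**Amber readthrough.** An ORF ending in TAG whose reading frame continues
to a second stop at least 50 codons downstream is flagged as a readthrough
candidate, with the fused ORF1–RdRP length reported. TAA/TGA stops and
frame-shifted continuations are rejected.

**Conserved UTR blocks.** Multi-segment mycoviruses share conserved 5′UTR
stretches across segments. The detector anchors on exact k-mers (default
k = 6) present in *every* UTR, and on each anchored diagonal selects the
interval that maximizes summed per-column conservation scored against a
softer growth threshold (`max(0.5, 2·min_conservation − 1)`), subject to
the interval's mean per-column conservation reaching `min_conservation`
and its length reaching `min_len` (default 13, the length of the conserved
partitivirus-type 5′ block). Blocks without an exact shared anchor are never
reported — this is what keeps chance agreement between unrelated sequences
out. The default `min_conservation` is 0.85: with only two segments a
conserved position scores 1 and a divergent one 0.5, so a real 13-mer with
three degenerate positions runs at 0.885 mean conservation. Positions below
the threshold are rendered lowercase in the IUPAC consensus (minimal
covering code per column). In a pairwise comparison of short UTRs, a
genuinely conserved degenerate motif is close to the statistical floor —
chance blocks of similar quality arise in a few percent of unrelated
80–150 nt pairs at strict settings — so block localization should be
confirmed with a degenerate-pattern search when the motif is known, which
is how the package's own recovery checks operate.

**Coverage.** Per-base counts are normalized by their maximum so the
highest-covered position equals 1, matching the usual density-plot
convention; mean coverage and (when the read length is known) total reads
are attached. Counts may come from a 2-column TSV, from a minimal SAM
reader (POS/CIGAR with M/=/X consuming and D/N advancing the reference;
secondary and supplementary alignments excluded), or from the simulator's
truth track, which avoids any aligner dependence.

**Extension and stitching.** Contig ends are extended greedily with reads
overlapping at least `min_overlap` (default 30 nt) with at most
`max_mismatch` (default 1) mismatches, longest extension first, ties broken
by input order; two incompatible equal-support extensions raise an error
rather than guessing. Extension proceeds on the growing 3′ end; callers
reverse-complement to extend 5′ ends. The defaults are conventions — the
manual read-based extension they emulate does not come with published
tolerances.

# Percent identity and demarcation

Percent identity uses Needleman–Wunsch global alignment with affine gaps
(BLOSUM62, gap open 10, extend 0.5 for proteins; match 2/mismatch −3, open
5, extend 2 for nucleotides — fixed for reproducibility), and the identity
denominator counts only columns where neither sequence is gapped. This is a
documented approximation to percent-identity matrices produced by MSA
tools, whose denominator conventions differ by about a point; values
derived through this route should be compared with that tolerance in mind.

The demarcation rules table stores one row per taxon with thresholds on
RdRP, CP, nucleotide, and ORF1 identity. Comparators are strict (`<`)
except for the taxa whose published criteria are inclusive
(Alphapartitivirus, Fusarivirus), where equality passes. The
Betaendornavirus criterion (75% on either the RdRP or the
methyltransferase motif) is stored in the single RdRP slot with a note, a
one-field simplification. A candidate is a **new species** when every set
threshold passes and its host species binomial (strain suffixes ignored) is
absent from the known hosts; a **known species** when at least one identity
sits at or above threshold and the host is the same species or the same
genus (the related-genus case is recorded as an advisory in the rationale);
anything else — including Alternavirus, for which no criterion has been
established — is **indeterminate**. This three-way logic is monotone:
lowering an identity can never demote a new-species call.

# What the simulator emulates — and what it does not

Each of the thirteen archetypes draws segment lengths from the ranges
observed for its family in the packaged catalog and embeds: an RdRP bait
built from the bundled model's consensus blocks joined by random linkers
(so scanner sensitivity tests exercise the scanner, not biology), the
family's triad variant (ADD for alternaviruses, GDN for ambiguiviruses),
and the family's diagnostic features — slippery heptamer at a codon-aligned
position near the coat-protein 3′ end, one of the three junction
geometries, amber readthrough with the RdRP in frame, shared 5′UTR blocks
across segments (the degenerate partitivirus-type 13-mer pair, identical
box-type blocks with CAA repeats for chrysoviruses), 3′UTR motifs, an
A/G/P-enriched coat-protein C-terminus, and mitovirus genomes at 62–73% A+U
whose ORF is intact only under the mold-mitochondrial code. Accidental
triad look-alikes in flanks and linkers are neutralized so the planted
triad is unambiguous. Every 5′UTR ends with an in-frame stop so ORF calls
begin at the planted start codon.

Decoy transcripts are random-composition ORF-bearing sequences at 50% GC
with no RdRP blocks. Reads have uniform starts, both strands, substitution
errors at a configurable rate, and constant quality; the truth coverage
track is emitted alongside.

Passing the synthetic recovery tests therefore demonstrates that the
detectors recover exactly the signals they are specified to recover, under
genomes whose lengths and feature geometry are realistic. It does *not*
demonstrate performance on real assemblies: the simulator does not model
assembly fragmentation or chimerism, sequencing-coverage bias, codon-usage
or dinucleotide structure of real viral genomes, divergence between the
bundled toy profiles and real Pfam models, or host transcripts with genuine
polymerase-like domains. Real screens should use the external
profile-search path with curated RdRP profile HMMs.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
desk scale: transcriptome pools of 50 decoys plus 3 planted genomes,
archetype sweeps of 13 families × 3 seeds, 400 random-UTR trials for the
conserved-block false-positive rate, oracle comparisons on 300-nt sequences
and ≤ 30-aa alignments, and 1-kb stitching problems at 30× read depth.
These sizes make the whole battery complete in a few minutes while keeping
every estimate's sampling error small relative to the margins being tested.
Scanner calibration uses 200 decoys per model with fixed recorded seeds;
Gumbel tails are evaluated with an asymptotic form for large deviations to
avoid underflow. All generator and pipeline randomness flows from a single
user seed.

# Known limitations

* The internal scanner's e-values are calibrated exceedance estimates, not
  profile-HMM e-values; use the `domtblout` path when parity with an
  external search matters.
* Pairwise (two-segment) conserved-UTR detection at strict settings sits
  near the statistical noise floor for short UTRs; conclusions about shared
  motifs in segment pairs should lean on the degenerate-pattern search.
* Identity values approximate MSA-derived percent-identity matrices to
  about one point.
* No RNA secondary-structure prediction (pseudoknots are not confirmed),
  no frameshift-efficiency modeling, no phylogenetics: clade placement is
  the user's concern.
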