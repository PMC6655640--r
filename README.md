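# mycovir

Most fungal viruses (mycoviruses) have RNA genomes and cause cryptic
infections, so they surface as a by-product of ordinary RNA-seq experiments:
after assembling the reads that do not map to the host genome, a handful of
contigs encode a viral RNA-dependent RNA polymerase (RdRP) — the one enzyme
RNA viruses carry that eukaryotic genomes lack. `mycovir` implements the
post-assembly half of that discovery workflow as a tested, reusable R
package, for virologists and bioinformaticians who want to triage assembled
transcriptomes for viral genomes and characterize what they find:

* **Triage** — six-frame ORF prediction under both the standard and
  mold-mitochondrial genetic codes (mitovirus ORFs are intact only when UGA
  reads as tryptophan), scanned against bundled RdRP motif-block profiles
  (named for the profile families RdRP_1–RdRP_5 and Mitovir_RNA_pol) with a
  decoy-calibrated e-value-like statistic, or against externally computed
  HMMER3 `domtblout` hits ingested verbatim. The default cut-off (e-value 10)
  is deliberately permissive, the convention for catching distant RdRPs.
* **Characterization** — family-diagnostic feature detectors: the −1
  ribosomal frameshift slippery heptamer `X XXY YYZ` (totiviruses), the
  termination–reinitiation junctions AUGA / UGAUG / UAAUG and the
  spacer-type start–stop arrangement (victoriviruses), amber (UAG) stop
  readthrough with the RdRP in the same frame (ambiguiviruses), RdRP
  catalytic triads (canonical GDD, variant ADD and GDN), degenerate IUPAC
  motif search, conserved 5′UTR blocks shared across genome segments,
  per-base coverage tracks normalized to a 0–1 scale, and read-based contig
  extension/stitching.
* **Species demarcation** — an ICTV-style rules engine with per-taxon
  percent-identity thresholds (e.g. Chrysovirus RdRP < 70% and CP < 53%;
  Alphapartitivirus ≤ 90%/≤ 80%; Fusarivirus RdRP ≤ 60%) combined with the
  unique-fungal-host criterion; identities come from global alignments
  (BLOSUM62, gap open 10/extend 0.5 for proteins).
* **Synthetic genomes** — a ground-truthed simulator for thirteen mycovirus
  family archetypes (genome organization, segment-length ranges, planted
  RdRP baits and family features), decoy host transcripts, and reads —
  so the whole pipeline is testable without downloading anything.
* **Catalog** — a machine-readable table of 59 mycoviral genomes from 44
  fungal hosts with summary statistics.

## Worked example

Simulate a victorivirus-like genome, hide it among decoy transcripts,
triage, and characterize:

```r
library(mycovir)

v   <- make_virus("victorivirus", seed = 7)
tx  <- make_transcriptome(10, list(v), seed = 7)
tri <- triage_contigs(tx$contigs)
tri
#>              seq_id orf_index orf_start orf_end strand codon_table model_name
#> 1 victorivirus_seg1         1      1839    5043      +    standard     RdRP_1
#>   bit_score       evalue
#> 1  114.2206 2.702338e-11

rep <- characterize_genome(v$segments, family = "Totiviridae")
sg  <- rep$segments[[1]]
sg$junction$kind   # "spaced"  (ORF2 start 5 nt before the ORF1 stop, +1 frame)
sg$triad$label     # "GDD"     (canonical catalytic triad, inside the RdRP hit)
rep$genome_class   # "dsRNA"
```

Of the eleven contigs, only the planted viral segment is flagged; its coat
protein/RdRP junction and catalytic triad come back as planted. Species
demarcation on published identity values:

```r
demarcate(list(taxon = "Victorivirus",
               identities = c(rdrp = 97, cp = 98),
               host = "Penicillium digitatum KH8",
               known_hosts = "Penicillium digitatum"))$status
#> "known_species"   # sequence thresholds failed and the host is not new
```

Catalog summary:

```r
summarize_catalog(load_catalog())
#> <summary_stats> 59 viruses from 44 hosts
#>    dsRNA (+)ssRNA    ssRNA
#>       34       20        5
#> dsRNA 58%, (+)ssRNA (incl. undetermined polarity) 42%
```

A thin command-line wrapper with `simulate`, `triage`, `characterize`,
`classify`, `summarize` and `run` subcommands is installed at
`system.file("cli", "mycovir.R", package = "mycovir")`.

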