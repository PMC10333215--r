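---
title: "Comparing reduced endosymbiont genomes: models, parameters and design notes"
author: "endosym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing reduced endosymbiont genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosym)
```

## The biological setting

Sap-feeding insects of the Auchenorrhyncha (planthoppers, leafhoppers,
spittlebugs, cicadas) live on nutrient-poor plant sap and depend on
heritable intracellular bacteria for the ten essential amino acids (EAAs)
their diet lacks. The anciently acquired symbiont *Sulcia* is typically
accompanied by a second, co-resident symbiont — in planthoppers the
betaproteobacterium *Vidania*. These symbionts carry some of the smallest
cellular genomes known: 100–200 kb, extremely AT-rich, gene-dense circles
that descend from a shared ancestral gene order through gene loss,
truncation-pseudogenization and occasional segmental inversions.

`endosym` packages the comparative-genomics workflow for such genomes:
reference-guided annotation with a length-fraction pseudogene classifier,
EAA-pathway completeness and partitioning between co-symbionts, circular
gene-order synteny with inversion calling, parsimony mapping of
rearrangement events onto a host phylogeny, long-read quality control, and
contig profiling — plus a synthetic-data generator that plants known
evolutionary events so that every analysis step can be validated against a
machine-readable truth.

## The annotation model

Annotation proceeds in three steps.

**ORF extraction.** All maximal start-to-stop ORFs are collected from the
six frames of the circular sequence, including ORFs spanning the origin
(`extract_orfs()` scans a tripled copy of the sequence and reports
coordinates modulo the genome length, with `end` allowed to exceed the
length to denote wrap). Under the `uga-trp` translation table TGA is read
as tryptophan, a recoding observed in some reduced symbiont genomes; the
default is the standard bacterial table. ORFs shorter than `min_orf_aa`
(default 10 aa) are not reported — on AT-rich sequence the six-frame scan
would otherwise be dominated by few-codon fragments that can never be
classified.

**Homology assignment.** Each ORF translation is compared against a
curated reference catalog by seed-and-extend: references sharing at least
two amino-acid 4-mers are aligned locally (BLOSUM62, gap open 10 / extend
0.5) and the score is converted to a Karlin–Altschul-style E-value against
the catalog treated as the database. The default significance cutoff is
an E-value of 0.01. Assignment is iterative best-hit: the highest-scoring
(ORF, gene) pairs claim each other first and each reference gene keeps
only its best ORF per genome, so a second, weaker copy of an already
claimed gene is demoted (or reported, with `keep_duplicates = TRUE`).
The similarity engine sits behind a single score-and-cutoff contract, so a
profile-based search could be substituted without touching the classifier.

**Classification.** A call's `length_fraction` is its ORF length divided
by the reference protein length (the median length when a symbol has
several reference sequences). The status is a step function with strict
breakpoints: *functional* above 0.85, *putative pseudogene* above 0.60,
*pseudogene* otherwise — a fraction of exactly 0.85 is putative, exactly
0.60 is a pseudogene. Unassigned ORFs strictly longer than 300 nt are
kept as *hypothetical*; shorter ones are dropped. The fraction is
measured on the ORF itself rather than on an alignment envelope; for
5'-intact truncation pseudogenes the two coincide, and the ORF reading
keeps the classifier independent of alignment parameters.

## EAA pathways and the co-symbiont partition

The ten EAA biosynthesis pathways ship as data
(`inst/extdata/eaa_pathways.tsv`), one row per reaction step with the set
of alternative genes sufficient for that step: isozymes are alternatives
within a step, complex subunits are separate steps. A step is present
when at least one of its genes is functional (putative pseudogenes can be
counted with `include_putative = TRUE`, but are treated as absent by
default — the conservative reading of a partially decayed gene).

`partition()` credits each amino acid to the symbiont with *strictly
more* present steps; ties, including 0–0, stay unassigned. The
strictly-more rule matters: a pathway can be credited to a symbiont even
when a terminal step is missing (as for phenylalanine, where the last
steps are absent but the rest of the pathway is intact in one partner and
completely absent in the other) — a completeness-threshold rule would
leave such pathways orphaned. On the transcribed gene presence of the
*Pyrops* symbiont pair the rule yields the published three-versus-seven
division of labor:

```{r}
pws <- load_builtin_pathways()
pres <- read.delim(system.file("extdata", "pyrops_eaa_genes.tsv",
                               package = "endosym"))
partition(completeness(pres$gene[pres$symbiont == "sulcia"], pws),
          completeness(pres$gene[pres$symbiont == "vidania"], pws),
          labels = c("Sulcia", "Vidania"))
```

The methionine step list uses the transsulfuration route (`metA`, `metB`,
`metC`, then methionine synthase); published descriptions of the
*Vidania* pathway disagree on whether `metA`/`metB` were lost or the full
`metABC` route is used, and the shipped table records the loss reading
without trying to resolve the tension — the table is data and can be
edited.

## Circular gene-order synteny

Two annotated circles are compared at gene level, not nucleotide level:
the shared gene symbols (statuses `functional` and `putative_pseudogene`
by default) are rotation-normalized so that a common anchor gene comes
first and reads forward in both genomes — `lipB` by convention for
*Sulcia*-type runs, `tufA` for beta-symbionts; if the anchor is missing
the lexicographically smallest shared symbol is used, with a warning.
The query order is then a signed permutation of the reference order, the
sign recording relative orientation.

`call_blocks()` decomposes the permutation into maximal collinear runs.
Adjacency is circular on **both** sides: query position *n* joins back to
position 1 and reference index *n* is circularly adjacent to index 1.
This makes the decomposition independent of where the circle is cut — a
rotation of either genome changes nothing — at the price of one perhaps
surprising behaviour: a run may continue across the anchor. Gene-level
comparison (rather than a nucleotide dot-plot) is what makes the reported
quantities — CDS counts and approximate spans — directly comparable with
published inversion descriptions, and is robust on AT-rich sequence where
nucleotide aligners struggle.

One inversion call is emitted per inverted block, with the member genes,
the number of member CDS features (rRNA markers may order the comparison
but are not counted as CDS), and the nucleotide span measured on the
query circle from the first to the last member along the arc that
contains them, so spans stay below the genome length even when a block
straddles the coordinate origin. Published spans come with "~", so the
configuration carries a ±2 kb `span_tolerance_nt` for comparisons; whether
printed spans include flanking intergenic DNA is not documented, and the
first-to-last-member definition is a recorded choice. Duplicate shared
symbols (e.g. the two parts of an origin-split feature) are merged to the
part with the lower start so the permutation stays a bijection.

`synteny_fraction()` summarizes global collinearity as the fraction of
shared genes inside forward blocks of at least two genes: 1 for perfect
collinearity, 0 when every shared gene is a singleton.

**Anchor caveat.** The anchor is assumed to lie in the conserved
backbone. If it falls inside an inverted segment, orientation
normalization flips the whole representation and the complement of the
rearranged region appears inverted instead. The validation harness
therefore anchors on a gene outside planted inversions, exactly as a
curator picks `lipB` because it is syntenic across the published genomes.

## Mapping rearrangement events onto the host tree

Each distinct derived arrangement is a binary character (ancestral /
derived) on the tips of the host phylogeny. `map_events_on_tree()` runs
Fitch parsimony — Hartigan's generalization, so multifurcating trees are
accepted — and assigns events to branches where the reconstructed state
changes. Ambiguities are resolved by keeping the parental state wherever
parsimony permits, with the root preferring the ancestral order; for a
derived state confined to a clade this places the event on the clade's
stem, the single deepest branch compatible with the tips. The package
ships a transcription of the published *Sulcia* arrangement characters
and host topology (`inst/extdata/`); mapping them reproduces the
published census of one ancestral plus five more recent inversions.

## Long-read quality control

Mean read quality is always computed in probability space:
$\bar Q = -10\log_{10}\left(\tfrac1n\sum_i 10^{-Q_i/10}\right)$, the
convention of the long-read QC tools this module mirrors (an arithmetic
mean of Phred values would understate the error rate). `filter_reads()`
keeps reads strictly longer than 1500 nt with mean quality strictly above
Phred 10 — both published cutoffs. `split_reads()` tiles each read with
non-overlapping 100 nt windows (final partial window included), removes
windows at or below mean Phred 10, and re-emits maximal runs of kept
windows as segments of at least 500 nt, ids suffixed `:<start>-<end>`.
The window length and threshold of the original splitting script are not
published; the non-overlapping tiling (rather than a rolling window) is a
deliberate simplification that makes the output a deterministic partition
of each read, and all three constants are exposed in `qc_config()`.

## Contig profiling

`profile_contigs()` computes per-contig length, GC (over A/C/G/T only)
and mean coverage — coverage is consumed from a table rather than
recomputed from mappings, keeping read alignment out of scope — plus the
plotting flag used by GC-versus-coverage scatter plots (strictly longer
than 1500 nt). `assign_taxonomy()` replaces the original dual
nucleotide/protein BLAST voting with an explicit, testable rule: contigs
are cut into 1 kb chunks, each chunk votes for the reference label
sharing the most 15-mers with it (strand-insensitive; ties and zero-hit
chunks abstain), and the contig takes the majority label when the vote
fraction reaches `min_vote_fraction` (default 0.5), otherwise
`unassigned`.

## The synthetic-data generator

The simulator is the package's test bed and defines the conditions under
which the validation suite runs.

* **Catalog.** `generate_catalog()` draws reference proteins with
  lognormal lengths around 230 aa (minimum 30 aa) from a codon model
  whose base composition matches the genome GC target with stop codons
  excluded — at GC 0.22 this skews both codons and amino-acid usage the
  way real AT-rich symbiont proteomes are skewed. The ancestral circular
  order is a uniform random permutation with strands assigned
  independently at p = 0.5, since no ancestral order is documented.
* **Descendants.** Events are applied in the fixed order loss →
  pseudogenize → invert, which makes the truth log unambiguous to replay.
  Pseudogenes are 5'-intact 3' truncations with a premature stop codon
  written at the truncation point, and every gene is emitted with an
  in-frame stop immediately upstream of its start codon — two choices
  that make maximal-ORF extraction recover planted boundaries exactly, so
  annotation tests measure the classifier rather than start-codon
  ambiguity. Inversions are placed by distributing the free genes among
  the segment gaps, so any request whose total size fits is satisfiable.
  Intergenic spacer lengths are exponential with the mean chosen to hit
  the target coding density (default 0.9) in expectation; spacer bases
  are i.i.d. at the genome GC target. Defaults (150 genes, GC 0.22,
  coding density 0.9) emulate the published genome statistics of
  planthopper symbionts; realized GC lands within ±0.03 of the target.
* **Reads.** `simulate_reads()` draws reads uniformly from the circle on
  both strands, lengths normal, per-base qualities equal to the
  configured mean plus a ±1 integer jitter (keeping the realized error
  probability within ~2% of the nominal one); configured low-quality
  windows overwrite the qualities exactly, giving sharp truth boundaries
  for the splitter.

What the generator deliberately does **not** model: nucleotide
substitutions, indels, codon usage beyond the GC bias, horizontal
transfer, repeats, chimeric or adapter-bearing reads. Passing tests
therefore demonstrate the correctness of the algorithms on clean planted
signal, not robustness to divergent real sequence — on real genomes the
homology step, not the gene-order machinery, is the component that would
feel that difference first.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: planted-inversion
recovery uses 200 simulated genome pairs of 140–160 genes with 1–3
inversions of 2–40 genes and 5% gene loss; block decomposition and the
synteny fraction are checked against a brute-force maximal-run finder
exhaustively for all signed permutations of up to 6 elements and on
random permutations of 7–8; parsimony scores are checked against
exhaustive minimal-change enumeration on trees of up to 6 tips, and
against an independent Fitch implementation where available. End-to-end
annotation recovery runs on 20–60-gene genomes (~20–55 kb), which keeps
the full suite in the minutes range while exercising every code path of
the full-size problem.

Degenerate inputs are errors with named causes: non-ACGT characters
(reported with their offset), empty FASTA records, fewer than two shared
genes, pathway tables with empty steps (reported with their row), tree /
character-table mismatches (reported with the offending taxa), planted
read windows outside their read. Ties in taxonomic voting abstain rather
than guess; equal pathway completeness leaves an amino acid unassigned
rather than crediting either symbiont.

## Known limitations

* Gene-level synteny cannot see rearrangements whose breakpoints fall
  inside genes, and reported spans exclude flanking intergenic DNA beyond
  the first and last member gene.
* The E-value calibration of the pairwise-alignment homology engine uses
  standard gapped BLOSUM62 constants; for the near-exact matches the
  simulator produces this is far from the decision boundary, but real
  divergent pseudogene fragments would deserve a profile-based engine
  behind the same contract.
* Inversion *distance* (minimal sorting-by-reversals scenarios) and
  rearrangement-based phylogeny inference are out of scope; the event
  census is per-character parsimony on a fixed host tree.
* tRNA/rRNA/ncRNA detection is consumed from external annotations when
  present, never computed.
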