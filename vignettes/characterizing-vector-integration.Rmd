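---
title: "Characterizing plasmid-vector integration events from short reads and assembly contigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing plasmid-vector integration events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectrace)
```

## The problem

Random insertional mutagenesis of a small haploid genome — here modelled on a
picoeukaryotic green alga with a ~13 Mb nuclear genome transformed with a ~6 kb
linearized plasmid — leaves each transformant line with one question mark per
clone: where did the vector land, how many copies went in, how much of the
molecule survived, and what did the repair machinery do to the junctions?
Resequencing each line with short-insert paired-end libraries answers all four,
provided the analysis handles three complications:

1. **The vector is partly host-derived.** Transforming constructs routinely
   reuse host promoters and terminators. Reads from those segments map equally
   well to the genome and the vector, so they are useless as evidence of vector
   presence and poisonous for junction detection. They must be found and masked.
2. **Junctions are not clean.** Nonhomologous end-joining leaves target-site
   duplications (TSDs), small target deletions, filler DNA of untraceable
   origin, inversions and duplications of vector sequence, and occasionally
   deletes large chromosome segments adjacent to the insert.
3. **Short reads alone cannot resolve multi-copy or rearranged inserts**, so
   locus contigs (from hybrid assembly in real studies; emitted from truth
   here) are read as anchor chains — the machine-readable form of a dot plot.

## The procedure

The pipeline mirrors the standard junction-read workflow for transgene
localization:

* **Mapping.** Reads are mapped jointly against genome + vector with a
  seed-and-extend mapper (k-mer seed vote, ungapped extension scored +1/-3,
  soft clips at extension boundaries). Reads whose best and second-best
  placements tie are *ambiguous* and excluded from coverage and evidence —
  the conservative multi-mapping policy. The mapper is deliberately
  fixture-scale; SAM input from any external aligner is accepted instead.
* **Junction pairs.** A pair with one mate unique to a chromosome and the
  other unique to the (unmasked) vector localizes a junction to within one
  insert size. The genome mate's orientation fixes the side: forward mates
  face the insert from the left, reverse mates from the right.
* **Split reads.** Soft-clipped tails of unique reads are remapped; a clip
  unique to the other target dates the breakpoint to the base. When filler DNA
  sits at the junction the clip maps nowhere (or ambiguously, if the filler
  duplicates host-shared sequence); such clipped reads still yield an exact
  genome-side coordinate when their mate maps uniquely to the vector,
  otherwise fillered junctions would never get base-exact breakpoints — a
  2x101 bp read cannot bridge an 83 bp filler with 15 bp anchors on both
  sides.
* **Clustering.** Single-linkage on the genome coordinate (gap <= `window`),
  sides split by strand geometry, breakpoint = modal split coordinate, else
  pair-interval midpoint. Calls below `min_support` total evidence are
  dropped.
* **Copy number.** N = C_marker / C_housekeeping, where C = total mapped
  length over feature length. The selectable marker is the one vector feature
  guaranteed present in every survivor; a single-copy housekeeping gene
  calibrates the denominator. The integerized call is round(N), flagged
  uncertain when |N - round(N)| > 0.25.
* **Integrity.** Positions with depth >= `min_depth` count as covered;
  fractions are computed over the *unmasked* vector length; features are
  intact (>= 99% covered), deleted (<= 1%), or partially deleted.
* **Contig reading.** Maximal exact matches >= 50 bp between contig and
  targets, both strands, are chained by an O(n^2) DP (weight = anchored bases
  minus gap penalties, small overlaps tolerated); the chain is classified
  into the junction-variant taxonomy by local rules (gap at a junction ->
  filler; target gap/overlap across the insert -> target deletion / TSD;
  reversed sub-vector block -> inversion, or inverted duplication when its
  interval is covered elsewhere; adjacent near-full-length vector blocks ->
  tandem multicopy; coverage ending inside the vector ends -> truncation).
* **Adjacent-deletion scan.** Windows flanking the locus with mean depth
  below `del_frac` of a robust nuclear baseline, merged while contiguous,
  reported when >= `min_del_len`.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `k` | 15 (toy), 20 (real scale) | bp | seed length; 20 echoes the usual short-read aligner seed, 15 suffices for 10-150 kb toys |
| `min_clip` | 15 | bp | 15-mers are effectively unique at both toy and real genome sizes |
| `min_support` | 3 | evidence items | kills singleton artifacts; vastly exceeded at 100x and above |
| `window` | 530 | bp | 2 x mean insert: a discordant pair's positional uncertainty is one insert per side |
| `min_depth` | 5 | x | binary presence/absence of vector coverage is robust to this at 100-800x |
| `del_frac`, `min_del_len` | 0.1, 10 kb | -, bp | the motivating adjacent deletion is ~98 kb of near-zero coverage; 10 kb floors out windowing noise |
| `blunt_tol` | 5 | bp | junction microhomology tolerance (below) |
| insert mean/sd | 265 / 30 | bp | the sequenced libraries' insert means ranged ~250-278 bp |
| error rate | 0.001 | per base | substitution-only short-read error model |

## What the synthetic generator does and does not emulate

The generator realizes a *stated world*: 2 toy chromosomes (20-150 kb; the
chromosome-end-deletion preset uses 150 kb so a 98 kb adjacent deletion fits),
a 6 kb vector whose promoter/terminator segments are verbatim copies of host
loci, 2x101 bp inward pairs with truncated-normal inserts (min = read length)
at 100x, uniform fragment starts, and independent per-base substitutions.
Presets named after the study's clonal lines encode the published event
sizes: a 518 bp TSD with 83 bp (unknown) and 62 bp (vector-duplicate) fillers;
a 206 bp target deletion with a 171 bp vector inversion and 64 bp filler; a
four-copy tandem with one reversed copy; a 90 bp inverted duplication beside a
~98 kb chromosome-end deletion (left-side junction evidence only); a 10 bp
target deletion with a 55 bp external-origin filler. Insertion coordinates are
arbitrary — the source reports them only graphically — so only event sizes
and architectures carry over.

"Unknown origin" fillers are generated by rejection sampling to share no
20-mer with genome or vector, which makes database-free origin classification
well-posed.

Deliberately not emulated: indel sequencing errors, PCR duplicates, GC bias,
long-read error profiles, or real assembly (contigs are emitted from truth).
A green truth-recovery test therefore establishes that the *logic* recovers
the stated architectures under sampling noise — not that the pipeline is
robust to aligner- or assembler-specific artifacts.

## Numerical choices and degenerate cases

* **Junction microhomology bounds attainable precision.** When the first
  bases of the insert coincide with the reference continuation, every read
  crossing the junction over-extends by the length of that run, and the modal
  breakpoint shifts with it — the breakpoint is genuinely ambiguous within
  the homology run. Consequences: reconciliation treats |right - left| <= 5 bp
  as a blunt junction, and SV lengths (differences of two breakpoints) are
  verified to +-5 bp, the same tolerance as the breakpoints themselves. True
  TSDs/deletions of <= 5 bp are thus reported blunt at the junction-read
  level; the simulator's truth record and the contig chain still carry them
  exactly.
* **Robust depth baseline.** The adjacent-deletion scan is specified relative
  to a median depth, but a per-base chromosome median degenerates to zero
  when a deletion spans most of a chromosome (the 98 kb / 150 kb preset).
  The baseline is instead the median of per-window mean depths over nuclear
  windows with nonzero depth; a uniformly half-covered chromosome still
  yields no call (the rule is relative, not absolute), while a true
  near-zero run is detected regardless of its extent.
* **Chain post-processing.** Two rules keep contig calls faithful: a short
  (<= 100 bp) anchor block sandwiched between larger blocks is folded into
  its junction gap and classified by origin (its anchor may have landed on
  either of two identical copies, e.g. a vector-duplicate filler that also
  matches the host-shared segment); and a junction gap whose sequence
  contiguously extends a neighbouring vector block within 5 bp (vector
  sequence too short to anchor, e.g. the 40 bp vector head outside a 171 bp
  inversion) is merged into the block rather than called filler.
* **Filler thresholds.** Origin assignment needs >= 80% identity over >= 90%
  of the filler length (local alignment, both strands, vector tried before
  genome); below 10 bp a filler is a micro-insertion with no origin assigned.
  The published analysis used database BLAST with no stated cutoff; these
  are this package's documented choices.
* **Ambiguity policy.** Ambiguous reads never contribute to coverage,
  junction evidence, or clip remaps; they are counted. Exclusion is
  conservative and makes the untransformed-line specificity property
  structural: without vector-linked fragments, no evidence class can fire.
* **Config files are JSON**, not YAML: the package keeps a single-file,
  module-namespaced config but relies only on jsonlite, which every
  deployment of its dependency stack already carries.
* **Mapped-length bookkeeping.** "Total length of mapped reads" counts full
  read lengths of uniquely mapped records, which reproduces the published
  mapping-table arithmetic (those totals are divisible by read count x 101);
  the published raw totals are counted in pairs and the mapped-% footnote is
  applied verbatim. One published coverage cell (688 vs the 688.68 its own
  footnote arithmetic yields) is internally inconsistent at printed
  precision; the tests assert the arithmetic and note the one-unit gap.

## Known limitations

* The mapper is ungapped: reads spanning small indels would be soft-clipped
  rather than gapped-aligned. The simulator matches this (substitution-only);
  real data should be mapped externally and imported as SAM.
* Tandem copy counts from contigs are contig-visible counts; collapsed
  assemblies under-report them. The coverage-ratio estimate and the
  contig-visible count are reported separately and never reconciled — the
  motivating study itself left a 4 (coverage) vs 2 (contig) case open.
* Organelle replicons are handled only as copy-ratio observations; no
  organelle-specific calling.
* Chromosome-end events are annotated (vector block abutting a contig end),
  not modelled as telomeric rearrangements.
* The published study's real-data results (chromosome identities, exact
  coordinates, effective vector coverages, transformation efficiency,
  luminescence) require its archived sequencing data and are exercised here
  only through presets borrowing the printed event sizes.

## A minimal run

```{r, eval = FALSE}
w <- simulate_preset("T3", seed = 1)          # stated world, 100x, 2x101 bp
rep <- characterize(w$reference, w$vector, reads = w$reads,
                    contigs = w$contig, marker = w$marker,
                    housekeeping = w$housekeeping, line_name = "T3")
print(rep)
verify_against_truth(rep, w$truth)
```
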