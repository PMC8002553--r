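# vectrace

Characterization of plasmid-vector integration events in small haploid
genomes from short-read resequencing and locus contigs.

After random insertional mutagenesis (e.g. PEG-mediated transformation of a
picoeukaryotic alga with a linearized ~6 kb vector), each clonal transformant
line poses four questions: **where** did the vector integrate, in **how many
copies**, how **intact** is the transforming molecule, and **what structural
variation** did the repair machinery leave at the junctions? `vectrace`
answers them from a paired-end library (2 × 101 bp style) plus, optionally,
a locus contig:

* **Insertion locus** — junction read pairs (one mate on a chromosome, the
  other on the vector) localize the site; soft-clipped split reads whose
  clips remap to the other target give base-exact breakpoints; evidence is
  clustered into per-line locus calls with left/right support and a
  completeness status (`both_ends` / `left_only` / `right_only`).
* **Copy number** — the coverage ratio
  `N = C_marker / C_housekeeping`, with `C = L / G` (total mapped length over
  feature length), comparing the vector's selectable marker (present in
  every survivor by selection) against a single-copy housekeeping gene.
* **Vector integrity** — per-base vector coverage after masking vector
  segments shared with the host genome (promoters/terminators copied from
  host loci recruit genomic reads in every line); features are graded
  intact / partially deleted / deleted.
* **Junction taxonomy** — breakpoint reconciliation (`d = right − left`:
  deletion if `d > 0`, target-site duplication if `d < 0`, blunt otherwise),
  filler-DNA origin classification (vector-duplicate / genome-derived /
  unknown), anchor-chain reading of contigs (maximal exact matches chained
  by DP — a machine-readable dot plot) into TSDs, deletions, fillers,
  inversions, inverted duplications, tandem multi-copy inserts and
  truncations, and a windowed scan for large deletions adjacent to the
  locus.

A ground-truthed synthetic transformant generator (module `synthetic_data`)
and a fixture-scale seed-and-extend read mapper make the whole pipeline
runnable and testable with no external data or aligner; SAM from a real
aligner is accepted interchangeably.

## Worked example

Simulate a transformant line carrying the "T3"-style architecture — a single
forward vector copy flanked by a 518 bp target-site duplication, with an
83 bp filler of unknown origin at the 5′ junction and a 62 bp duplicate of
vector sequence at the 3′ junction — then characterize it blind and score
the result against the simulation truth:

```r
library(vectrace)
w <- simulate_preset("T3", seed = 1)          # 45 kb toy genome, 100x, 2x101 bp
rep <- characterize(w$reference, w$vector, reads = w$reads, contigs = w$contig,
                    marker = w$marker, housekeeping = w$housekeeping,
                    line_name = "T3")
print(rep)
verify_against_truth(rep, w$truth)
```

which prints:

```
== line report: T3 (config 273bb198) ==
<mapping_stats> coverage 108x, mapped 92.7% (23,707 pairs of 25,576 raw), insert 264.3
<copy_number_estimate> 1.02 (98x / 96x) -> 1 copy
<integrity_report> vector present: 100.0% of unmasked vector covered (depth >= 5), 0 uncovered segment(s)
  Ap           intact
  ubiP         masked
  KanR         intact
  Luc          intact
  tubPT        masked
<vt_locus_calls> 1 call(s), 0 cluster(s) dropped below support
<locus_call> chr1: left 12,519 (exact) | right 12,001 (exact)  [both_ends, support 191]
structural variants (4):
  target_site_duplication  chr1      12,001     518 bp  [junction_reads]
  filler_insertion         vector     2,519      83 bp  [contig]
  filler_insertion         chr1       8,602      62 bp  [contig]
  target_site_duplication  chr1      12,001     518 bp  [contig]
<vt_scorecard> PASS
  loci 1/1, bp error L=0 R=0, status TRUE, copies 1/1
                    type length expected found
        filler_insertion     83        1     1
        filler_insertion     62        1     1
 target_site_duplication    518        1     2
```

Reading it: the library maps at 108× mean coverage; the marker/housekeeping
coverage ratio 1.02 calls one vector copy; the vector is fully covered
outside the masked host-shared promoter/terminator segments; one insertion
locus on chr1 with base-exact breakpoints whose offset (left 12,519 > right
12,001, 1-based print) reveals the 518 bp target-site duplication; and the
contig chain recovers both fillers (the 83 bp one unclassifiable, the 62 bp
one a vector duplicate). The scorecard confirms exact truth recovery.

Breakpoints print 1-based inclusive; everything is 0-based half-open
internally.

### Command line

```sh
VT=$(Rscript -e 'cat(system.file("exec","vectrace",package="vectrace"))')
Rscript $VT simulate --preset T12 --seed 7 --out sim_t12
Rscript $VT characterize --config sim_t12/characterize_config.json --out sim_t12/out
Rscript $VT verify --config sim_t12/characterize_config.json   # exit 1 on mismatch
```

Presets `T3 T6 T12 T14 T16` encode the observed insertion architectures
(TSD; deletion + vector inversion + filler; four-copy tandem with one
reversed copy; inverted duplication beside a ~98 kb chromosome-end deletion;
small deletion + external-origin filler); `NT` is an untransformed control.

## Package layout

| module | file | role |
|---|---|---|
| synthetic_data | `R/synthetic_data.R`, `R/presets.R` | ground-truthed genomes, events, reads, contigs |
| io_alignment | `R/io_alignment.R`, `src/core.cpp` | k-mer index, mapper, mapping stats, SAM subset |
| coverage_stats | `R/coverage_stats.R` | depth profiles, copy number, masking, integrity |
| junction_detection | `R/junction_detection.R` | junction pairs, split reads, locus calls, context |
| sv_characterization | `R/sv_characterization.R` | reconciliation, fillers, anchor chains, deletion scan |
| pipeline_cli | `R/pipeline.R`, `R/cli.R` | orchestration, reports, truth verification, CLI |

See `vignettes/characterizing-vector-integration.Rmd` for the model,
parameter rationale, numerical choices and limitations.
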