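Package: vectrace
Title: Characterization of Plasmid-Vector Integration Events in Small Haploid Genomes
Version: 0.1.0
Authors@R:
    person("Marin", "Delacroix", email = "marin.delacroix@posteo.net", role = c("aut", "cre"))
Description: Locates transgene insertion loci in resequenced transformant
    lines from junction read-pair and split-read evidence, estimates
    transgene copy number from read-coverage ratios against a single-copy
    housekeeping gene, profiles the integrity of the transforming vector
    after masking vector segments shared with the host genome, and
    classifies structural variation at integration junctions (target-site
    duplications, target deletions, filler DNA, inversions, inverted
    duplications, tandem multi-copy inserts, adjacent large deletions).
    Includes a ground-truthed synthetic transformant generator (genomes,
    paired-end reads, locus contigs) so the whole pipeline is testable
    without external sequencing data, and a fixture-scale seed-and-extend
    read mapper so no external aligner is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    IRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
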