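# hybscreen

**In silico hybridization screening for protein-coding variant loci.**

`hybscreen` finds genomic loci that encode proteins similar to a query
protein — including loci that standard nucleotide homology searches miss
because their DNA has diverged *synonymously*. It was built for the problem
of discovering unannotated histone H3 variant genes and pseudogenes in
mammalian genomes, and ships the histone H3.2 query and H3.1/H3.2/H3.3
references as defaults, but every step is parameterized for arbitrary
queries and genomes.

## The method

The screen mimics nucleic-acid hybridization computationally:

1. **Windowing.** The query protein of length *L* is split into overlapping
   peptide windows of *k* = 8 residues with stride 1, giving *L* − *k* + 1
   windows (129 for the 136-aa H3.2 query).
2. **Degenerate reverse translation.** Each window is expanded into *every*
   DNA sequence encoding it under the standard genetic code — the Cartesian
   product of the synonymous codon sets, ∏ᵢ deg(aaᵢ) sequences of 3*k* = 24
   nt per window (4,162,752 in total for H3.2). The count is computed in
   closed form; matching never materializes the set, since a 24-mer is a
   realization of a window exactly when its frame-0 translation equals the
   window peptide (a translate-and-lookup scan over all six frames).
   An explicit enumerate-and-match oracle (`oracle_scan()`) verifies the
   equivalence.
3. **Locus assembly.** Exact hits on either strand are chained into candidate
   loci when consecutive hits lie within 90 nt of each other; loci need at
   least two distinct window sequences.
4. **ORF reconstruction and filtering.** Per locus, hits vote on a reading
   frame, the stop-to-stop ORF is reconstructed, and candidates encoding
   < 10 aa (`TOO_SHORT`) or whose histone-fold core domain (mature residues
   63–135 by default) is interrupted by a frameshift or stop
   (`CORE_OUT_OF_FRAME`) are rejected.
5. **Characterization.** Candidates are compared to references by
   Levenshtein edit distance d(a,b) and percent identity
   100·(1 − d/max(|a|,|b|)), annotated with substitution notation (e.g.
   `A31S, S87A, V89I, M90G` for H3.3 vs H3.2), the diagnostic 87–90 motif
   (SAVM vs AAIG), grouped by average-linkage clustering of the edit-distance
   matrix (H3.1-group / H3.3-group / distant-A / distant-B), and classified
   by 3′-end structure (histone stem-loop vs AATAAA/ATTAAA polyadenylation
   signal vs not detected).

Annotation context (promoter = TSS ± 2 kb / gene-body / intergenic
fractions, peak category proportions, putative 3 kb 3′-UTRs, RPM
quantification) and a seeded synthetic-genome simulator with ground truth
round out the toolkit.

## Worked example

```r
library(hybscreen)

query <- h3_query()                      # 136-aa histone H3.2, core 63-135
make_windows(query) |> nrow()            # 129
count_reverse_translations(make_windows(query))  # 4162752

# a 60-kb synthetic genome with 20 implanted elements and known truth
sim <- simulate_genome(demo_implants(), seed = 7)
screen <- run_screen(query, sim$genome)
screen
#> <hyb_screen> query H3.2 (136 aa), k = 8
#>   windows                129
#>   enumerable_sequences   4,162,752
#>   hits                   2,004
#>   loci                   20
#>   after_length_filter    18
#>   after_core_filter      14
```

All 20 implanted elements are recovered as loci; the two 9-aa fragments
fall to the length filter and the frameshift pseudogenes plus non-core
fragments to the core-domain filter, leaving 14 passing candidates — the
exact, recoded, and substituted variants plus the core-covering fragment,
as the simulator's truth table predicts. Candidates are then characterized
with:

```r
loci <- tidy(screen) |>
  dplyr::filter(pass) |>
  dplyr::mutate(name = locus_id,
                protein = substr(protein, 2, nchar(protein))) # mature, Met off
reports <- build_report_table(loci, genome = sim$genome)
grouping <- cluster_variants(setNames(loci$protein, loci$name))
autoplot(grouping)   # edit-distance dendrogram with group colours
```

A thin command-line wrapper (`inst/cli/hybscreen.R`) exposes the same
pipeline as `simulate`, `scan`, `characterize` and `context` subcommands.

## Scope notes

Full-genome runs against mm9/hg19-scale references (and the published
counts that depend on a specific aligner's mismatch tolerance and
annotation version) are outside the test scope: this package matches
exactly at codon level, which is the method's defining robustness property
but can shift full-scale hit counts relative to mismatch-tolerant mapping.
See the methods vignette (`vignettes/in-silico-hybridization.Rmd`) for the
model, parameter defaults, and known limitations.
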