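# rflpkit

In-silico PCR–RFLP assay design and genotyping, in R.

PCR–RFLP (restriction fragment length polymorphism of a PCR product, the
CAPS-marker idea) identifies genotypes without sequencing: a locus is
amplified, digested with a restriction enzyme whose recognition site overlaps
a diagnostic SNP, and the resulting band pattern is read off an agarose gel.
Because nuclear loci are biparentally inherited, a heterozygote shows the
union of both alleles' band patterns, so the same assay also detects hybrids.

`rflpkit` is for marker developers and molecular-identification labs who want
to design and sanity-check such assays computationally before touching a
pipette: it does virtual PCR, restriction digestion of haploid and
heterozygous templates (including offset type IIS-like cutters such as
SfaNI), virtual gel electrophoresis with densitometric peak quantification,
discovery of diagnostic enzymes over a haplotype alignment with minimal panel
selection, and genotype calling from observed band patterns. The worked
system throughout is a licorice (*Glycyrrhiza*) identification assay on the
nuclear ribosomal ITS1–5.8S–ITS2 region: Haplotype A (*G. uralensis*) carries
C at position 241 and TGC at 465–467, Haplotype B (*G. glabra* / *G.
inflata*) carries T and CAA, and Haplotype C (T, TGC) marks hybrids with
further relatives. The C at 241 completes the single NaeI site
(GCC▼GGC, cutting the 729 bp amplicon into 242 + 487 bp), and the TGC at
465–467 completes an extra antisense SfaNI site (GCATC(5/9)), so the
NaeI + SfaNI pair separates all the genotype classes of interest.

## The model in brief

* **Matching.** All motif and primer comparisons use IUPAC set-intersection
  semantics: codes match iff their base sets intersect. Primer sites
  additionally require an exactly matching 3'-terminal base.
* **Digestion.** For a plus-strand motif match at 0-based `m`, the top strand
  is cut at `m + cut_top`; for a minus-strand match, at
  `m + L − cut_bottom` (motif length `L`; offsets measured from the motif 5'
  end and allowed to exceed `L` for offset cutters). Fragments are the
  intervals between pooled scissions, so lengths tile the amplicon exactly.
  Incomplete digestion is modelled by a single `uncut_fraction`.
* **Gel.** Migration is piecewise-linear in log10(size) between ladder
  anchors; bands closer in size than a gel-dependent relative threshold
  co-migrate; band intensity is mass-proportional (length × molarity).
  Densitometry renders Gaussian peaks and recovers peak areas between
  flanking minima after rolling-minimum baseline subtraction.
* **Calling.** The two-step workflow reads SfaNI first (excluding Haplotype
  B carriers), then NaeI, applying the rule that a pure Haplotype A lane
  keeps its residual uncut 729 bp band below 20% of the 487 bp band's
  intensity.

## Worked example

```r
library(rflpkit)

haps <- its_reference_haplotypes()     # bundled synthetic 729 bp amplicons
pr   <- its_primers()                  # ITS5 / ITS4

amplify(haps, pr[1, ], pr[2, ])[, c("template_id", "start", "end", "length")]
#>   template_id start   end length
#> 1 HapA            1   729    729
#> 2 HapB            1   729    729

digest(haps, "NaeI")
#>   id    start   end length molarity
#> 1 HapA      1   242    242        1
#> 2 HapA    243   729    487        1
#> 3 HapB      1   729    729        1
```

Both haplotypes amplify as a single 729 bp product; NaeI cuts Haplotype A
once (242 + 487 bp) and leaves Haplotype B uncut — the Haplotype A
diagnostic. An A×B heterozygote digested with SfaNI on a 3% gel shows all
six resolvable bands (the B-specific 397 bp band and the A-specific
276 + 121 bp bands above the three shared fragments):

```r
het <- digest_genotype(tibble::tibble(id = haps$label, seq = haps$seq), "SfaNI")
resolve_bands(het, gel_params(3))
#>    size intensity  mass molarity n_fragments weak
#> 1   397     0.882   397        1           1 FALSE
#> 2   276     0.613   276        1           1 FALSE
#> 3   225     1       450        2           2 FALSE
#> 4   121     0.269   121        1           1 FALSE
#> 5    59     0.262   118        2           2 FALSE
#> 6    48     0.213    96        2           2 FALSE
```

Enzyme discovery over the two-haplotype alignment recovers the assay pair
(plus MspI and FokI, whose sites nest inside the same two polymorphisms):

```r
diagnostic_enzymes(haps)[, c("enzyme", "n_pairs")]
#>   enzyme n_pairs
#> 1 FokI         1
#> 2 MspI         1
#> 3 NaeI         1
#> 4 SfaNI        1
```

A full survey — simulate a 190-individual population with the
4 / 59 / 125 / 2 (HapA / HapB / HetAB / HetAC) composition, render noisy
lanes, detect peaks and call genotypes — is one pipeline:

```r
haps3 <- its_reference_haplotypes(include_c = TRUE)
pop   <- make_population(seedlot_spec(seed = 3), haps3)
sv    <- simulate_survey(pop, haps3, uncut_fraction = c(NaeI = 0.1), seed = 3)
summarize_population(call_population(sv$lanes))
#>   class     n   pct
#> 1 HetAB   125  65.8
#> 2 HapB     59  31.1
#> 3 HapA      4   2.1
#> 4 HetAC     2   1.1
```

Only 2.1% of the simulated seed lot is pure *G. uralensis*, recovered
perfectly from the virtual gels.

A command-line front end with `digest`, `design`, `call`, `simulate` and
`summarize` subcommands lives at `inst/cli/rflpkit.R`.

## Notes on the bundled reference

The packaged haplotype sequences
(`inst/extdata/its_haplotypes_synthetic.fasta`) are a constructed synthetic
stand-in for the assay's real amplicons (which are published only as a
figure): amplicon length, primer ends, variable-site positions, restriction
site counts and the NaeI fragment sizes all match the published assay. See
the methods vignette (`vignettes/rflp-methods.Rmd`) for the model details,
parameter choices and limitations.
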