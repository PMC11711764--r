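# lactylmine

Mining lysine lactylation (Klac) sites from tandem mass spectrometry data.

Lactate-derived lactylation of lysine ε-amines (+72.0211 Da, net C3H4O2) is a
regulatory protein modification whose confident detection is harder than its
search: a lactyl mass shift alone is easily confused with isobaric artefacts
or mislocalized placements. `lactylmine` implements, as a reusable and fully
testable R pipeline, the dry-lab mining strategy used to nominate
functionally important lactylation sites:

1. **In-silico digestion** — trypsin, up to 2 missed cleavages, full or
   semi-specific termini.
2. **Peptide-spectrum matching** — a windowed binomial scorer
   (score = −10·log₁₀ P[X ≥ k], X ~ Binom(n, p) over the top-10 peaks per
   100 Da window) against a reversed-sequence target-decoy database, with
   q-values from FDR(t) = #decoys ≥ t / max(1, #targets ≥ t).
3. **Site validation** — three gates in order: PSM q ≤ 0.01; AScore > 20
   (binomial contrast of site-determining ions between the two best lactyl
   placements at the most discriminating peak depth); and the presence of the
   **CycIm diagnostic ion**, the cyclic immonium ion of lactyllysine
   (C8H14NO2⁺, m/z 156.1019 computed from composition), which evidences an
   intra-peptide lactylated lysine.
4. **Cohort summaries** — per-site detection frequency across samples,
   intensity ranking (sites detected more than 10 times), and occupancy
   = I(lactylated) / (I(lactylated) + I(unmodified)).
5. **Conservation** — homologous-position mapping by BLOSUM62 global
   alignment, Poisson-corrected distances d = −ln(1 − p), Neighbor-Joining
   trees and bootstrap supports.

A synthetic-data module simulates centroided HCD spectra and multi-sample
cohorts with known per-site occupancy, intensity and localization ground
truth, so every stage is testable without any external download.

For whom: proteomics researchers who want a transparent, scriptable
implementation of diagnostic-ion-gated PTM mining, and method developers who
need a ground-truthed benchmark harness for site-localization and FDR
machinery.

## Worked example

```r
library(lactylmine)

run <- run_lactylome_pipeline(pipeline_config(seed = 3))
run
#> <lactylome_run>
#>   spectra 192 -> PSMs 192 -> lactyl 96 -> q<=0.01 96 -> AScore 96 -> flank 96 -> CycIm 93
#>   validated sites: 6

run$summaries[c("accession", "protein_position", "n_detected",
                "frequency", "summed_intensity", "median_occupancy")]
#>   accession protein_position n_detected frequency summed_intensity median_occupancy
#> 1      SYN1               11         12       100         61007958              0.5
#> 2      SYN2               11          9        75          5374520              0.3
#> 3      SYN2               31          6        50          3441692              0.4
#> 4      SYN3               12         12       100         12987734              0.7
#> 5      SYN4               10          6        50          2559096              0.2
#> 6      SYN4               32          3        25          2637689              0.9
```

The default configuration simulates a 12-sample cohort with six planted
lactyl sites. The report line shows the monotone gate chain: 192 spectra
(96 from lactylated precursors), all matched, all lactyl PSMs surviving the
q-value, AScore and flanking-ion gates, and 93 carrying the CycIm ion (the
diagnostic peak is emitted with probability 0.95 per spectrum). The summary
table recovers the planted truth: the ubiquitous high-intensity site SYN1:11
is detected in 12/12 samples (frequency 100%), tops the intensity ranking,
and its median occupancy equals the planned 0.50; every other site's
frequency and occupancy match its plan exactly.

Conservation of a site across a homolog family:

```r
fam <- simulate_homolog_family(seed = 11)
cr <- conservation_report(fam, reference = "reference",
                          reference_site = 97, n_boot = 1000, seed = 5)
all(cr$mapped_sites$conserved)   # TRUE: the planted lysine maps in all homologs
ape::write.tree(cr$tree)         # Newick with bootstrap supports as node labels
```

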