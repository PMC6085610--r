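# rflpfinder

Restriction enzyme site search and PCR-RFLP enzyme selection in R.

PCR-RFLP genotyping reads a genotype off a gel: amplify the region around a
sequence variation, digest with a restriction enzyme that cleaves one allele
but not the other, and compare fragment patterns. The design bottleneck is
choosing the enzyme. `rflpfinder` answers that question computationally: it
parses a REBASE-style ("parsed references" flat text) enzyme catalog,
locates recognition sites in DNA on both strands with a Boyer-Moore matcher
generalized to IUPAC-degenerate patterns, and judges which enzymes
discriminate the alleles of a variation.

An enzyme is reported **specific** for a variation iff

* its recognition site overlaps the variation in *some but not all* alleles
  (so the digest differs between genotypes), and
* it has *no background site* elsewhere in the template in any allele (a
  repeated site is cut in every genotype and is excluded outright).

Matching uses both classic Boyer-Moore rules — the bad-character shift and
the strong good-suffix shift — over an alphabet of 4-bit base masks, so a
text letter *t* matches a pattern letter *p* iff *t* ∈ bases(*p*); for
degenerate patterns, where letter compatibility is not transitive,
good-suffix shifts are conservatively disabled. A naive scanning matcher is
kept permanently as the independent oracle, and the test suite checks
`bm_search ≡ naive_search` on 10,000 randomized instances.

Supported input dialects: plain DNA, IUPAC-coded variation (`ACGGMTTT`),
and bracketed alleles (`ACGG[A/C]TTT`, `[A/C/G]`, `[A/C/G/T]`, indels
`[-/AGG]`), inline, as FASTA or one-per-line batch files.

## Worked example

No REBASE download is needed to try the package: `rebase_fixture()` writes a
synthetic catalog in the same flat dialect, always seeded with the enzymes
TspGWI (ACGGA) and BspGI (CTGGAC).

```r
library(rflpfinder)
fx <- rebase_fixture(2, seed = 1)      # $text is REBASE-dialect flat text
judge_rflp(parse_input("ACGG[A/C]TTTTTT"), fx$catalog)
#> <rflp_judgment> ACGG[A/C]TTTTTT | site 1, alleles A/C
#>   1 enzyme(s) with hits, 1 specific, 1 searched without hits
#>  enzyme pattern strand cut_alleles n_background_hits specific
#>  TspGWI   ACGGA      +           A                 0     TRUE
```

TspGWI cuts the A allele at the variation (site `ACGGA` spans positions
1–5, variation at position 5), does not cut the C allele, and has no other
site: it genotypes this SNP. Append a second copy of its site, though, and
the enzyme is excluded — both genotypes would be cut downstream:

```r
judge_rflp(parse_input("ACGG[A/C]TTTTTTACGGATTT"), fx$catalog)
#> <rflp_judgment> ACGG[A/C]TTTTTTACGGATTT | site 1, alleles A/C
#>   1 enzyme(s) with hits, 0 specific, 1 searched without hits
#>  enzyme pattern strand cut_alleles n_background_hits specific
#>  TspGWI   ACGGA      +           A                 2    FALSE
```

Plain site search (both strands, 1-based inclusive coordinates):

```r
find_sites("ACGGATTTTTT", fx$catalog)
#>   enzyme strand start end matched pattern
#> 1 TspGWI      +     1   5   ACGGA   ACGGA
```

Judgments restrict by enzyme class and availability
(`judge_options(include_iupac = FALSE, commercial_only = TRUE, ...)`),
classify into composite-IUPAC/general × commercial/non-commercial
(`classify_results()`), join full catalog records for the bench
(`rflp_report()`), and scale to SNP panels (`judge_rflp_batch()`, parallel
workers, order-stable output).

The same pipeline is scriptable through the installed CLI:

```sh
Rscript inst/scripts/rflphunt fixture --n 50 --seed 1 --out enzymes.txt
Rscript inst/scripts/rflphunt judge --seq 'ACGG[A/C]TTTTTT' --rebase enzymes.txt
Rscript inst/scripts/rflphunt batch --file snps.txt --rebase enzymes.txt --workers 4
```

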