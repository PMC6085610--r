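---
title: "Selecting allele-discriminating restriction enzymes for PCR-RFLP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting allele-discriminating restriction enzymes for PCR-RFLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpfinder)
```

## The problem

PCR-RFLP genotyping distinguishes the alleles of a sequence variation by
digesting the amplicon with a restriction enzyme that cleaves one allele but
not the other: after gel separation, the genotype is read off the fragment
pattern. The experimental design question is therefore *which* enzyme to
order. An enzyme is informative only if

1. its recognition site **overlaps the variation** in some but not all
   alleles (otherwise every genotype is cut, or none is), and
2. it has **no second site elsewhere in the amplicon** — a background site is
   cut in every genotype and destroys the diagnostic fragment difference.

`rflpfinder` automates this judgment against a catalog of restriction
enzymes in the REBASE "parsed references" flat-text format, on both strands,
for substitutions (di- to tetra-allelic) and indels, singly or in batch.

## Input model

Three sequence dialects are accepted by `parse_input()`:

* **plain** DNA over A/C/G/T — no variation;
* **IUPAC** — each degenerate letter (R, Y, S, W, K, M, B, D, H, V, N) is
  read as a substitution site whose alleles are the letter's base set;
* **bracket** — `[A/C]`, `[A/C/G]`, `[A/C/G/T]` for substitutions and
  `[-/AGG]` / `[AGG/-]` for indels.

We deliberately make the dialect explicit (with `auto` detection as a
convenience) rather than guessing whether a degenerate letter means "allele"
or mere base-calling ambiguity: in the iupac dialect every degenerate letter
is a variation site, and in the plain dialect degenerate letters are
rejected. Input is uppercased, and whitespace and digits are stripped first,
so sequence-viewer paste-ins work. Nonconforming characters are a typed
error naming the position, not a silent truncation.

Indel alleles realize as the empty string. No IUPAC letter encodes a length
polymorphism, so `bracket_to_iupac()` refuses indel and multi-base sites
instead of inventing notation. The bracket form accepts any insertion length
under the expansion cap; alleles are reported in canonical A\<C\<G\<T order
(deletion last) after transformations so outputs are deterministic.

**Coordinates.** All user-facing coordinates in this package are 1-based
inclusive, the native R and IRanges convention; only BED export converts to
the 0-based half-open browser convention. Keeping a single convention across
the API avoids the classic off-by-one pitfalls of mixing internal and
reporting layers.

## The catalog

`parse_rebase()` reads the REBASE-style flat file: eight tagged fields
(default tags `<1>`–`<8>`: name, prototype, microorganism, source,
recognition sequence, methylation, suppliers, references), blank-line
record separation, continuation lines folding into the preceding field. The
tag set is configurable through `rebase_dialect()` because only the file,
not its grammar, is standardized in practice. Entries with an unknown or
empty recognition sequence cannot participate in matching and are skipped
with a count; malformed entries are skipped with a warning record rather
than aborting a 4,000-entry parse. Enzyme names are not assumed unique:
duplicates are kept and distinguished by their recognition pattern.

Cut-site notation is stripped into offsets (`G^AATTC` → pattern `GAATTC`,
top-strand cut after base 1; `GGTCTC(1/5)` → cuts 7/11 counting from the
pattern start). Site *presence*, not the fragment map, decides RFLP
availability, so the offsets are stored for reporting but unused by the
judgment; two-sided `(a/b)PATTERN(c/d)` notation is accepted with the
upstream offsets kept separately.

Two classifications are derived per enzyme: *composite-IUPAC* vs *general*
(does the pattern contain a degenerate letter) and *commercial* vs
*non-commercial* (is the single-letter supplier set non-empty — any listed
supplier suffices).

Because a live REBASE download is neither versioned nor necessary for
testing, `rebase_fixture()` generates synthetic catalogs in the same flat
dialect, so the real parser is exercised end to end. The generator is
deterministic per seed, draws recognition lengths uniformly from 4–8 (the
mode of real catalogs), gives a configurable fraction of entries degenerate
letters and suppliers, and always seeds the two enzymes used in the worked
examples, TspGWI (ACGGA) and BspGI (CTGGAC). What the fixture does *not*
emulate: the long right tail of real recognition lengths (up to ~35 nt),
isoschizomer clustering, and realistic methylation strings — tests passing
on fixtures therefore certify the parsing/matching/judging machinery, not
any biological claim about a particular commercial catalog.

## Matching

Site search is Boyer-Moore with both classic shift rules. Preprocessing
(`build_tables()`) builds, per pattern of length $M$:

* the **bad-character** table — for each text letter, the distance from the
  rightmost pattern position (excluding the last) whose degeneracy set
  contains that letter, or $M$ if none; on a mismatch at pattern position
  $j$ against text letter $c$ the window advances by
  $\max(1,\; \mathrm{bc}[c] - (M-1-j))$;
* the **strong good-suffix** table — the rightmost re-occurrence of the
  matched suffix preceded by a *different* letter, falling back to the
  longest pattern prefix that is a suffix of the match.

The scan takes the larger of the two shifts, every shift is $\ge 1$, and at
most $N - M + 1$ alignments are visited (`bm_search(..., trace = TRUE)`
exposes the alignment sequence so this is testable, not just asserted).
The inner scan loop is C++ for throughput; tables are built in R where they
can be inspected.

**Degenerate patterns.** A text letter $t$ matches pattern letter $p$ iff
$t \in \mathrm{bases}(p)$ — compatibility-set matching, a single bitwise
AND on 4-bit base masks. This avoids the exponential alternative of
expanding a pattern into all concrete sequences before searching;
`expand_iupac_pattern()` is still exposed (capped) because the equivalence
*match(pattern) = union over match(expansions)* is the natural correctness
oracle and a useful export in its own right. Compatibility is not
transitive (`R` matches what `D` matches without `R = D`), which breaks the
equal-letter reasoning behind the good-suffix rule; for degenerate patterns
good-suffix shifts are therefore disabled and only bad-character shifts are
used — correctness over speed, and irrelevant to the common case since most
catalog patterns are concrete.

`naive_search()`, a vectorized position-by-position scanner sharing no code
with the Boyer-Moore path, is kept permanently as oracle and baseline; the
suite checks `bm_search ≡ naive_search` on $10^4$ randomized mixed
concrete/degenerate instances, plus an independent cross-check against
`Biostrings::matchPattern(fixed = FALSE)`.

`find_sites()` runs a whole catalog against a sequence: enzymes are filtered
*before* searching (recognition-length range, commercial-only,
include-IUPAC), the plus strand is searched with the pattern and the minus
strand with its reverse complement (reported in plus-strand coordinates),
overlapping occurrences are all reported, and enzymes longer than the text
are skipped silently. Results export as TSV, JSON or BED.

## The judgment rule

`judge_rflp()` formalizes "can this variation be genotyped by digestion":

1. one variation site is judged at a time (`site_index`); any other sites
   are held at their first allele — joint judgment over multiple sites is a
   combinatorial question the package deliberately does not answer;
2. optionally the template is first narrowed to a flanking window
   (`flank_radius`) around the site, which both speeds the search and scopes
   the background-site criterion to the amplicon a user would actually
   design;
3. each allele of the judged site is realized into a concrete sequence and
   searched under the option filters;
4. each hit either **overlaps** the realized allele span (half-open interval
   intersection; for a deletion allele, the insertion point must lie
   strictly inside the hit, i.e. at least one matched base on each side of
   the junction) or is a **background** hit;
5. an enzyme is **specific** iff some but not all alleles have a
   variation-overlapping hit *and* it has zero background hits in any
   allele. A hit on either strand counts; the verdict records the strand(s).

Point 5 merges two exclusion conditions — cutting every allele, and having
a repeated site elsewhere — because both make the digest uninformative. An
enzyme with a background hit is excluded outright even when its informative
hit is on the other strand; both sites end up in the same physical digest,
so strand separation cannot rescue it.

Verdicts carry the cut/uncut allele partition, per-hit tables, the
classification flags, and sort specific-first. `classify_results()` buckets
them into composite-IUPAC/general × commercial/non-commercial;
`rflp_report()` joins the full catalog record (microorganism, source,
recognition sequence, methylation, suppliers, references) for the bench.

Useful consequences that the suite verifies as properties rather than
examples: the specific set is invariant under reverse-complementing the
template and under allele reordering; a degenerate "variation" whose alleles
are identical never yields a specific enzyme; growing the catalog never
revokes an enzyme's specificity; and restricting to general enzymes returns
exactly the general rows of the unrestricted judgment.

## Batch runs and the CLI

`judge_rflp_batch()` maps the judgment over many templates, with optional
forked workers (`parallel::mclapply`); output order follows input order and
is byte-identical for any worker count, which the suite checks at the scale
of a realistic SNP panel (381 templates with 500-base flanks — about the
size at which one would batch-screen a candidate gene). A failing template
becomes an error record in its slot rather than aborting the run.

The `rflphunt` script (`inst/scripts`) exposes the pipeline as five
subcommands — `fixture`, `parse`, `search`, `judge`, `batch` — with TSV,
JSON and BED output and stage-labelled logging under `--verbose`.
Specification-nonconforming input exits with status 2 so pipelines can
distinguish bad input from runtime failure.

## Numerical and scale choices

* Allele-expansion cap: 256 combinations (a tetra-allelic site with three
  companion sites at worst); pattern-expansion cap: 1024. Both exist to turn
  accidental `N`-runs into a clear error instead of a memory blowout.
* Randomized suites: $10^4$ matcher-equivalence cases (text ≤ 200 nt,
  pattern ≤ 12 nt), $10^3$ expansion-equivalence patterns (expansion ≤ 64),
  500 strand-symmetry templates, 100 fixture round-trip seeds, one
  381-template batch — sizes chosen so the whole suite exercises every code
  path at realistic input shapes while staying fast enough to run on every
  change.
* Ties and ordering: hits sort by (start, enzyme, strand); verdicts by
  (specific desc, enzyme, pattern); allele transformations emit canonical
  A\<C\<G\<T order. No output depends on hash or locale ordering.

## Known limitations

* No fragment-length or digest-map computation: the judgment is site
  presence/absence, so near-equal fragment sizes that would co-migrate on a
  gel are not flagged. Cut offsets are parsed and reported for downstream
  tools.
* Methylation sensitivity is carried as an opaque string, not used to
  filter; a dam/dcm-blocked enzyme may be reported as usable.
* No primer design and no genomic flank retrieval — the input template is
  taken as the amplicon.
* The REBASE file must be supplied (or synthesized) by the user; the package
  neither downloads nor version-tracks it, so keep the catalog current
  manually.
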