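---
title: "viroscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{viroscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroscreen)
```

This vignette documents the models, parameters and design choices behind
`viroscreen`, in the spirit of a methods section: what each stage assumes,
which knobs matter, and what the synthetic test harness does and does not
demonstrate.

## The classification model

Virome annotation faces an asymmetry: viral reference sets are small and
biased, so a single search against a viral-only database produces false
positives (host or bacterial reads with incidental similarity), while a
search against a comprehensive multikingdom database is insensitive to
divergent viruses. `viroscreen` therefore uses a *tiered* design with a
confirmatory cross-check at each tier:

1. query representatives against a viral-only amino-acid database
   (translated search, most sensitive to divergent viruses);
2. cross-check each putative viral hit against a multikingdom amino-acid
   database;
3. route sequences with no viral aa evidence to a viral-only nucleotide
   query;
4. cross-check those against a polymicrobial nucleotide database;
5. merge into one annotation per sequence.

The cross-check rule is strict bitscore dominance: the verdict flips to
nonviral only when the best non-viral secondary hit has a strictly higher
bitscore than every viral secondary hit. Bitscore is used because it is
length- and composition-normalized and comparable within one search; the
rule is deliberately conservative — a tie keeps the viral verdict — and
it is monotone: adding a strictly worse non-viral hit can never flip a
viral verdict. The comparison statistic is configurable in principle but
pinned here so the partition and aa-precedence invariants are testable.

Two invariants define the routing contract. Every query receives exactly
one verdict in {viral, nonviral, unclassified}, so downstream count
tables conserve reads; and aa-tier verdicts (either way) are final —
a sequence with viral aa evidence never carries a nucleotide annotation.
Unclassified sequences are retained with a sentinel taxonomy rather than
dropped, for the same conservation reason.

## Taxonomy: dual-search LCA with top-hit reversion

Taxonomic assignment uses the lowest common ancestor over the secondary
(confirmatory) search's hit set rather than a single best hit. The hit
set is the top hit plus all hits with e-value within a factor
(`evalueFactor`, default 10 — common practice for dual-search LCA; the
exact window matters little because hit sets here are small and
concordant) of the top hit's.

Plain LCA fails at high ranks: evidence spanning bacteria and viruses
meets only at the root, and evidence spanning viral realms (a phage and a
vertebrate virus, say) meets at the virus root. In exactly those two
cases — the LCA equals the root or the virus root *and* the evidence is
not unanimous — the assignment reverts to the top hit's taxonomy and the
row is flagged (`augmented = TRUE`), preserving information that a plain
LCA would discard as "root". A genuinely open question is whether
unranked nodes directly beneath the root should also trigger reversion;
we restrict the trigger set to `{root, virus root}` because those are the
two degeneracies the model actually names, and a broader trigger would
silently re-annotate sequences whose LCA is a meaningful intermediate
clade. Both root ids are configurable (defaults 1 and 10239, the NCBI
convention).

Lineages are reported in the seven classical ranks. NCBI dumps label the
top division `superkingdom`; when no `kingdom`-ranked ancestor exists the
superkingdom fills the kingdom slot, which keeps the 7-column output
contract satisfied on real dumps. Absent ranks carry the literal sentinel
`"unclassified"` (grep-friendly, conventional). Merged-taxid files are
honored when supplied; hit tables referencing unknown taxids degrade to
the sentinel lineage with a warning instead of aborting, because real
taxonomies drift and a pipeline must not die mid-run. Baltimore
classification is treated as data, not algorithm: a packaged
family → group/nucleic-acid TSV compiled from public ICTV/Baltimore
definitions, joined case-sensitively on the family name, `NA` for
non-viral or unknown families.

## Dereplication and counting

Reads are dereplicated per sample by greedy centroid clustering: reads
are processed longest-first (ties broken lexicographically by read id,
making the procedure a pure function of the read set); a read joins the
first centroid with pairwise identity ≥ 0.97 over an alignment covering
≥ 0.80 of the centroid, else founds a new cluster. The thresholds mirror
the production clustering they stand in for. Identity is pinned as
matches / alignment columns with gap columns counting as mismatches —
without that definition the 97% threshold is untestable. A k-mer
prefilter (exact 16-mers, with a diagonal test that the candidate could
reach the coverage floor) skips hopeless centroid comparisons; at these
thresholds a qualifying pair always shares a seed, so the prefilter
cannot change results, only time. Production clusterings can be ingested
instead via a 2-column read → representative TSV; the bookkeeping
(counts, percentages, header encoding) is identical either way.

Seqtable FASTA headers encode `sample:index:count:percent` with the
percent rendered to one decimal; `decodeSeqtable()` inverts
`encodeSeqtable()` exactly. The percentage denominator is the post-host
read total when host removal ran upstream, else the raw total. Count
tables report raw counts and counts per million; per sample, raw counts
sum to the library total and CPM sums to 1e6 by construction.

## Host masking

The masking recipe shreds viral genomes into fixed 85-base windows with a
30-base overlap (step 55). "Average length 85" is implemented as a fixed
window with end truncation — deterministic, testable, and the average
emerges from the truncated tails. Fragments are located on both host
strands by exact 13-mer seeds plus banded extension, accepted at
aligned-region identity ≥ 90% with at most 2 indel *events* (gap
openings, not gap columns — the cap is about alignment shape, and a
column-based cap would conflate one 3-column gap with three separate
indels). Since extension is pattern-global, accepted placements cover the
whole fragment; the open question of full-fragment versus aligned-region
identity is thereby resolved to "both". Matched intervals are merged and
hard-masked with `N` (not soft-masked: downstream host mapping must
*fail* on masked regions, not optionally ignore them). Masking is
idempotent and length-conserving, and re-mapping the same fragments
against the masked host returns nothing — the property the recipe
exists for. External mappers can drive the same masking through 3-column
BED intervals.

## Contig tables

Contig abundances count each read once at its primary alignment
(secondary/supplementary SAM records are skipped; counting multi-mappers
would make `r_i` depend on aligner settings). RPKM is
`r_i × 1e9 / (R l_i)`; FPKM is the same over fragments, where a mate
pair (`/1`,`/2` suffixes) collapses to one fragment when both mates map
to the same contig and otherwise each mate counts; SPM is the TPM-style
rate normalization `1e6 (r_i/l_i) / Σ_j (r_j/l_j)`, which sums to 1e6
per sample and is invariant under uniform count scaling. Coverage percent
comes from the union of mapping intervals; GC is computed over A/C/G/T
only. Unmapped reads are pooled across samples with provenance retained
(the merged-assembly flow's input), and a read recorded as both mapped
and unmapped is a hard integrity error. The contig/read join
(`contigSeqTable`) is outer on the read side — one row per mapped pair,
sentinel lineage for reads absent from the bigtable — so its row count
always equals the mapped-pair count.

## The built-in aligner and its score proxy

The naive aligner exists so the classification contracts can be exercised
without an external aligner: exact k-mer seeds (13 nt / 5 aa), candidate
diagonals clustered within the indel budget, pattern-global extension
against a padded target window (nucleotide +1/−2 with gap open 2 /
extend 1; BLOSUM62 with gap open 11 / extend 1), one best hit per
(query, target). Its bitscore is a Karlin–Altschul-style proxy with fixed
constants (λ = 0.625, K = 0.41 nucleotide; λ = 0.267, K = 0.041 protein)
and its e-value is `m·n·2^−bit` over the database size. These are
*documented proxies*: internally consistent and deterministic, but not
comparable with any production aligner's statistics, which is why the
parse-time e-value ceiling (default 1e−3) and bitscore floor (default
30) are visible, configurable parameters. Translated search enumerates
all six frames under the standard genetic code; ambiguous codons
translate to X and stops to `*`, both scored by BLOSUM62.

## Synthetic study conditions

The mock community fixes the evaluation conditions: four viral genomes
(one per broad genome type) of 2 kb and two bacterial genomes of 3 kb,
200 reads per genome at 150 bp with 1% per-base substitutions, split
across two samples, seed 42. This is a reduced analogue of a
10^4-reads-per-genome benchmark design; the genome count and read depth
were chosen once so the whole pipeline runs in well under a minute on one
CPU while leaving several hundred distinct representatives per sample.
Genomes are random *codon-structured* sequences (sense codons only), so
each genome's frame-0 translation is an ORF-like protein and the toy
amino-acid databases are simply those translations — a deliberately
gene-dense caricature of viral genomes. The error model is
substitution-only (an indel knob exists but defaults to off) because it
keeps read→genome truth alignment trivial; quality strings are constant.

What passing tests on these fixtures shows: the routing, cross-check,
LCA, bookkeeping and normalization *contracts* hold, end to end, with
perfect family-rank recovery under 1% substitution noise. What it does
not show: performance on real data — no sequencing error structure, no
shared homology between the toy viral and bacterial genomes, no viral
dark matter, and reference databases that trivially contain the truth.
Sensitivity/FPR numbers from the harness characterize the
implementation, not the biology.

## Numerical and degenerate-input choices

* Hit ranking is totally ordered (bitscore ↓, e-value ↑, target id
  lexicographic), so every downstream product is invariant under
  permutation of input hit tables.
* Reverse-strand m8 rows (tstart > tend) are normalized to ascending
  coordinates with a strand flag at parse time and restored on write.
* Quadrant QC (identity × alignment length, defaults 70 aa / 90 nt /
  150 bases) classifies boundary values as the high/long side; the rule
  had to be pinned one way and ≥ is the convention that makes the
  printed cutoffs attainable.
* Empty secondary hit lists are a defined case (primary verdict stands),
  zero-match fragment mapping returns an empty interval set, and an
  empty mask-interval list is the identity on the host.
* Cluster processing order, dmp record syntax, and header encoding are
  all exact so that byte-level reproducibility holds: every generator
  and the CLI produce identical output for identical seeds.

## Problem sizes used in the checks

The shipped checks run at desk scale on one CPU: 1,000 random LCA
queries over ~50-node trees, 200 randomized routing fixtures, a 200-read
clustering oracle against an all-pairs brute force, a 10 kb plant-and-
recover masking fixture, and the 1,200-read end-to-end community run
twice to assert bit-reproducibility. These sizes were chosen as the
smallest at which the oracles are non-trivial (hundreds of distinct
clusters, all five routing paths exercised, both masking strands hit).

## Known limitations

* The greedy clusterer is quadratic in the worst case and intended for
  desk-scale data; production-scale dereplication should be ingested via
  the external-clustering interface.
* The naive aligner's statistics are proxies; thresholds tuned on them
  do not transfer to other aligners.
* FPKM pairing relies on `/1`,`/2` read-id suffixes; other mate-naming
  conventions count as single-end fragments.
* The Baltimore table covers common families; unlisted families join as
  `NA` by design rather than by fuzzy matching.
* Taxonomy handling assumes an NCBI-dialect dump; no name-based
  disambiguation is attempted.
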