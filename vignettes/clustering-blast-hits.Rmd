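---
title: "Clustering and annotating protein similarity-search hits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering and annotating protein similarity-search hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitclust)
```

## The problem

A protein BLAST search returns a flat ranking by score. In that ranking,
orthologs from distant species and fragments highly similar to the query
can sit far below the query's own paralogs, simply because shorter or more
diverged alignments score less. `hitclust` restructures the result: the
hit sequences are clustered on the fly, each cluster is annotated, and the
clustering can be redone instantly at any identity cutoff because the
search result is frozen in a session file. Clustering the *results* rather
than the *database* means the query was compared to every sequence — there
is no risk that similarity to a precomputed cluster representative
misrepresents similarity to the clustered sequences, and no need to guess
the right clustering granularity before searching.

## The clustering model

### Identity metric

Membership decisions use the percent identity of a global
Needleman–Wunsch alignment with BLOSUM62 and affine gap penalties
(opening 11, extension 1 per gapped position — the convention of the
underlying Biostrings aligner, where a length-`k` gap costs `11 + k`).
Identity is counted over all alignment columns **except terminal overhang
gap runs**, and the number of those columns is the alignment length `L`
used by the length-dependent threshold. Two consequences matter:

* a fragment aligned inside a full-length protein is judged only on the
  region it covers (an exact half-length fragment has identity 100%), and
* `L` shrinks with the overlap, so short overlaps face the steep part of
  the threshold curve.

The pair is always aligned in a canonical orientation (lexicographically
smaller sequence as pattern), which makes the statistic exactly symmetric
even when co-optimal tracebacks differ. Identity comparisons against the
threshold use plain `>=` with no epsilon, for determinism. Selenocysteine
(U) and pyrrolysine (O), absent from BLOSUM62, are scored as X; records
keep the original letters. Global alignment was chosen over local
(Smith–Waterman) identities because the terminal-overhang exclusion
already grants fragments the leniency they need while still penalizing
internal rearrangements.

### The threshold

A candidate joins a representative when identity reaches

> `max(c, R(L))`, with `R(L) = n + 480 · L^(−0.32·(1 + e^(−L/1000)))`

where `c` is the user cutoff (default 53%) and `n` an offset (default 0,
the twilight-zone curve itself). `R` is clamped to [0, 100]. The curve is
a *floor*: no user setting can undercut it, so a 20% cutoff still demands
~29% identity over a 100-column alignment. Numerically the curve decreases
from the 100% clamp down to a minimum of 19.51% at `L = 417` and is
non-monotone beyond (19.5–25% for very long alignments); the package
evaluates the closed form as stated everywhere and documents rather than
"fixes" this shape. In practice the default cutoff of 53% dominates the
curve for all `L` above ~35 columns.

### Two passes

* **Pass 1.** Sequences are sorted by decreasing length (ties broken by
  ascending accession, for determinism — the tie rule is a package
  choice). The longest becomes a representative; every remaining sequence
  within strictly 32 residues of its length (`diff 31` passes, `diff 32`
  fails; the strict reading follows the rule's wording) and above the
  threshold is absorbed; absorbed sequences leave the pool and the step
  repeats. A single scan per representative is performed; since the
  representative is fixed, re-scanning after each absorption would change
  nothing.
* **Pass 2.** Singletons are offered to the representatives of
  *multi-member* clusters on identity alone. The best match wins (highest
  identity, then lowest cluster index). Rescued members get pass number 2
  and a `2:` display label. Interpretive choices, made once and
  documented: singletons may not join other singletons (an "existing
  cluster" is read as a cluster that already demonstrated grouping), the
  pass is a single sweep rather than a fixpoint iteration, and recipients
  are fixed to the pass-1 multi-member set.

The result is a partition: every hit belongs to exactly one cluster, and
every membership carries a re-checkable certificate (identity to the
representative, alignment columns, pass number).

### Ordering, colors, annotation

Clusters are renumbered by the best BLAST rank among their members and
members are listed in rank order, so cluster 1 always contains the top
hit. Twenty fixed named colors label clusters 1–20; later clusters are
grey. Cluster annotation is computed from a per-protein table (an offline
TSV standing in for live UniProt lookups): the joint taxonomy is the
longest common prefix of the members' name-lineages (string-based, not
taxid-based, keeping the core offline); architectures are distinct
*ordered* domain lists with member counts (order matters — architecture,
not domain content; ties in count are broken by first appearance in
member rank order; members with no domain annotation contribute no
architecture entry); PDB identifiers are pooled as a set; the length
range always comes from the actual sequences, with the table's length
column reserved for consistency checks.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| identity cutoff `c` | 53 | % identity | fixed component of the threshold; tune per family |
| length rule | < 32 | residues | pass-1 gate separating fragments/variants from full-length homologs |
| e-value threshold | 1e-05 | – | search-time hit filter |
| matrix | BLOSUM62 | – | both the search and the identity alignments |
| gap penalties | 11 / 1 | score | matches the search defaults (Biostrings cost convention) |
| Rost offset `n` | 0 | % identity | shifts the floor curve; 0 is the twilight-zone curve |
| max hits | 20000 | hits | mirrors common web-server display limits |

Re-clustering (`recluster_session()`) only re-runs the two passes on the
frozen session, so sweeping cutoffs is cheap; on planted-family fixtures
the cluster count is non-decreasing in the cutoff (verified on fixtures,
not claimed as a theorem — the greedy order can in principle produce
exceptions).

## The synthetic-data generator

`make_family()` emulates a protein family as point substitutions (uniform
over the other 19 residues) around a uniform random seed sequence, plus
optional terminal truncations/extensions; `make_hitset()` assembles
independent families, a query (one family's seed), a collapsed hit table
covering all members, a matching annotation table (one lineage and one
two-domain architecture per family), and the planted truth partition.
Between-family identity is asserted below a bound (default 30%) with
bounded regeneration retries. Defaults (3 families × 5 members, 120
residues, 85% within-family identity, ≤5 residues of jitter) create the
regime the two-pass algorithm is designed for: within-family identity
far above the cutoff, between-family far below.

What the generator does **not** emulate: position-dependent substitution
preferences (no BLOSUM-informed mutation model), internal indels, domain
shuffling, or realistic phylogenetic correlation between families. A green
planted-partition test therefore establishes that the algorithm recovers
well-separated families and handles fragments as specified — not that it
resolves the genuinely hard regimes (identity near the cutoff, homology in
the twilight zone), where results legitimately depend on the cutoff the
user chooses.

## Numerical and degenerate-input choices

* Identity/threshold comparisons: exact `>=`, no epsilon.
* All tie-breaks fixed (length ties by accession; pass-2 ties by identity
  then cluster index; HSP collapse by bitscore, e-value, smallest subject
  start; report ties by bitscore, e-value, file order), so identical
  inputs give byte-identical outputs.
* Zero hits is a success: the pipeline writes a header-only report and an
  empty cluster list.
* An empty database means "no hits", not an error; an empty hit file
  after comments likewise.
* Sequences are validated against the 20 standard residues plus B, Z, X,
  U, O; one trailing `*` is tolerated and stripped; duplicate accessions
  are rejected at parse time.
* The session file is versioned JSON; an unknown schema version is
  rejected rather than guessed at.

## Worked example

```{r example, eval = FALSE}
specs <- replicate(3, family_spec(5, 120, 85, length_jitter = 5),
                   simplify = FALSE)
hs    <- make_hitset(specs, rng_seed = 1, fragment_family = 1)
paths <- write_hitset(hs, tempfile("demo"))
res <- run_pipeline(paths[["query"]], paths[["db"]],
                    hits_path = paths[["hits"]],
                    annotations_path = paths[["annotations"]],
                    out_dir = tempfile("out"))
length(res$clusters)   # 3: the planted partition
```

The planted half-length fragment `F1FRAG` fails the pass-1 length rule
(60 vs 120 residues), is rescued in pass 2 at 100% identity over its
span, and appears as `2:F1FRAG` in both reports.

## Known limitations

* The identity metric is a package decision: the underlying published
  method names the threshold curve but not the exact pairwise identity
  definition, so other implementations may draw cluster boundaries
  slightly differently near the threshold.
* Greedy clustering is order-dependent by construction; it does not
  optimize any global objective, and a different length ordering could
  yield a different (equally rule-respecting) partition.
* Pass 2 assigns each singleton independently; two fragments of the same
  protein may be rescued into different clusters if their best matches
  differ.
* Annotation is only as good as the supplied table; the optional UniProt
  fetcher is a best-effort convenience, never used by the core pipeline.
* All-against-representative alignment is O(n·k) global alignments; hit
  lists of tens of thousands of sequences will be slow in pure R — the
  intended scale is the few hundred to few thousand hits of a typical
  curated-database search.
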