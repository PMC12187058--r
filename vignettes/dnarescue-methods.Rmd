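---
title: "Models and methods behind dnarescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dnarescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnarescue)
```

`dnarescue` is a complete encode–channel–decode stack for DNA data storage
whose purpose is to squeeze error-free sequences out of reads that standard
pipelines discard: non-pass-filter (NPF) reads, reads failing the per-oligo
error check, and reads of abnormal length. This vignette explains the model
behind each component, the tunable parameters and their defaults, what the
synthetic channel does and does not emulate, and the numerical choices that
make everything deterministic.

## Code structure

One oligo carries 304 bits — a 32-bit droplet seed, a 256-bit payload, and
16 bits of Reed–Solomon parity — mapped two bits per base (A=00, C=01,
G=10, T=11) to 152 nt, flanked by 26-nt and 21-nt adapters for a 199-nt
synthesis product. The adapters shipped with the package are synthetic
placeholders with realistic lengths; real deployments substitute their
platform's sequences via `default_adapters()`-compatible lists.

**Inner code.** The (38,36) RS code over GF(2^8) has minimum distance 3 and
is used strictly for detection: all weight-1 and weight-2 symbol errors are
caught, and a random corrupted word slips through with probability about
2^-16. Detection-only is a deliberate division of labor — erroneous oligos
are cheap to re-derive from other reads or to treat as erasures, while
miscorrection would silently poison the outer decoder. The field polynomial
(0x11d) and the generator-root convention (first consecutive root exponent
0) are not dictated by the storage format; both are configurable in
`rs_params()`, and the defaults are the most common textbook convention so
that stored parity is reproducible.

**Outer code.** The LT code draws each droplet's degree from a robust
soliton distribution with c = 0.025 and delta = 0.001 — the convention of
fountain-code storage systems with ~12% redundancy at archive scale — and
its neighbor set by Floyd's sampling. The seed-to-selection map is a fixed,
versioned generator: a murmur3-style avalanche of the 32-bit seed feeding a
32-bit linear congruential generator (Numerical Recipes constants), inverse
CDF for the degree, Floyd's algorithm for the indices. This map can never
change silently between releases, because the seeds are physically stored
in the DNA; the avalanche step exists so that numerically close seeds give
independent droplets.

**Constraint screening.** Candidate droplets are rejected until the screened
region passes a homopolymer cap (runs of at most 3) and a 45–55% GC window,
both bounds inclusive. The screened region defaults to the 144 nt carrying
seed and payload — parity is computed after acceptance — because screening
before parity attachment is what keeps the accept/reject decision
independent of the inner code; `constraint_spec(screened_region =
"full_oligo")` screens all 152 nt instead. Candidate seeds are visited along
a Weyl sequence (odd golden-ratio stride 2654435761 modulo 2^32) starting
from a point drawn from `rng_seed`. A stride-1 search is superficially
simpler but has a failure mode: consecutive seeds share their high bits, so
a homopolymer inside the seed's own base image blocks the search for up to
2^17 draws. The full-period odd stride keeps determinism and seed
uniqueness while decorrelating successive candidates; acceptance runs at
roughly one in six candidates for random payloads.

## The synthetic read channel

`simulate_readset()` emulates post-merge reads directly; paired-end physics,
basecalling, and the chastity filter itself are out of scope. Each
attempted read draws a source oligo uniformly, a PF/NPF class (default PF
fraction 0.894, the reference run's share), a merged-length class from the
class-specific distribution, and an error multiplier.

The per-class marginal error rates and their burst structure default to the
values measured on a reference MiSeq run: substitutions 0.09% (PF) / 3.84%
(NPF), deletions 0.05% / 0.08%, insertions 0.01% / 0.04%, with run-length
bins (1, 2, 3–5, ≥6) realized as uniform over 3..5 and 6 plus a geometric
tail of ratio 1/2. Error events land at uniform positions with probability
rate/mean-run-length so that the *realized per-base rate* equals the
configured marginal rate; every event is recorded in a script that replays
bit-exactly, giving the tests a ground-truth audit trail.

Two features of real data are modeled qualitatively rather than measured:

- **Error concentration.** NPF errors cluster in a minority of bad reads.
  The package uses a two-component mixture: a fraction `f_bad = 0.05` of
  reads multiply their rates by `m_bad = 15`, and the remaining reads are
  scaled by (1 − f_bad·m_bad)/(1 − f_bad) so the marginal rate is
  preserved. Mean preservation is essential — the Table-level rates are
  marginal means, and a mixture that only inflated bad reads would roughly
  double them — which also caps `f_bad·m_bad` below 1 and is why the
  multiplier defaults to 15.
- **Length classes.** Reads are forced into their drawn length class:
  class-152 reads re-draw (or fall back to substitution-only) until the
  indel budget nets to zero, abnormal-length classes get one explicit
  closing indel, and the sub-145 class is truncated (those reads are
  discarded by preprocessing anyway, so their internal structure is
  arbitrary). Consequently indel rates conditional on an abnormal length
  class are higher than the marginals — which mirrors reality, since an
  abnormal length *implies* indels — and rate calibration is asserted on
  the raw channel (`corrupt_read()`) and on class-152 reads.

Merge failures are counted and dropped, so length-class fractions are
measured against attempted reads. Passing tests on this channel shows the
analysis machinery is correct under calibrated rates, bursts and
length classes; it does not certify behavior under position-dependent error
profiles, PCR-induced chimeras, or coverage skew, none of which are
generated.

## Preprocessing and triage

Merged reads are optionally trimmed: a read suffix that exactly matches a
prefix of the tail adapter with length ≥ 7 is removed (longest match wins).
Exact matching is a simplification of error-tolerant trimmers; with a
4-letter alphabet a 7-base spurious match occurs in about 6 reads per
100,000, which is negligible against the adapter contamination it removes.
`delete_last_base()` exists for raw-cycle inputs and is off for merged
reads. Triage then partitions reads: length-152 reads that pass detection
are already clean; length-152 failures are EDOL reads; lengths 145–153
(≠152) are AL reads; everything else is discarded. Detection is never run
on a read of the wrong length.

## Clustering

*Stage 1* groups identical length-152 reads; clusters sort by size
(descending, ties lexicographic) and their trivial consensus goes through
detection.

*Stage 2* is a greedy sphere sweep over abundance-ranked unique EDOL
sequences: a sequence joins the first existing center within edit distance
τe, else becomes a center. The default τe = 5 balances missing same-oligo
reads against merging different oligos; oligos differ by ≫ 5 after
constraint screening, so radius-5 spheres are effectively pure. The sweep
uses a banded distance with cutoff, so each comparison costs O(τe·152).

*Stage 3* pairs each AL read with EDOL centers under the adjusted distance
`edit(a,b) − |len(a) − len(b)|`, which discounts exactly the indels forced
by the length mismatch; the default τadj = 4 with optional per-type caps on
the canonical script's substitution/deletion/insertion counts. An AL read
joining several centers is assigned uniquely to the minimum adjusted
distance (ties to the earlier center in abundance order): unique assignment
keeps every read's evidence from being counted twice across clusters.

The per-type decomposition requires a canonical edit script; the package
fixes the backtrace tie order to match/substitution, then deletion, then
insertion, walking back from the end. Any fixed order satisfies
`del − ins = len(a) − len(b)`; fixing one makes per-type caps reproducible.

## Alignment and CAPMB consensus

Clusters of size ≥ 2 are aligned by a deterministic center-star
construction: every member is pairwise aligned to the center under the same
canonical backtrace, and gaps merge position-stably ("once a gap, always a
gap", insertions left-aligned within their slot). For small, centered,
near-identical clusters this is equivalent in practice to a heuristic
multiple aligner, and determinism is worth far more here than alignment
polish: consensus candidates must enumerate identically on every run.
Degapping any row always reproduces the member read exactly.

CAPMB then searches for a consensus that the inner code accepts:

1. If the aligned length exceeds 152, candidate sets of "null" columns of
   exactly the excess size are ranked by the product of weighted per-column
   gap frequencies (ties: lexicographic position tuples).
2. For each fixed null set, rows convert to 304-bit vectors; a residual gap
   abstains at its two bit positions rather than voting, because a gap is
   absence of evidence. Positions with no votes at all abort that null
   candidate.
3. Bit candidates start at the per-position weighted majority (a 50:50 tie
   resolves to bit 0) and continue in non-increasing product-of-frequency
   order via lazy k-best subset enumeration over the flip ratios; at most
   `max_split = 20` lowest-confidence positions are searched, the rest stay
   frozen at their majority value.
4. The first candidate passing the injected detector is the consensus. The
   detector is a plain callable on bit vectors (`make_rs_detector()` for the
   RS default), so any inner detection or correction code can stand behind
   the same search.

Budgets default to 128 null candidates and 1024 bit candidates per null
set. They bound worst-case work on hopeless clusters (garbage NPF reads can
tie at dozens of positions) and are configurable; exhausting them is a
normal outcome, returning the cluster's reads to the residual pool. Scores
are accumulated in log space; score ties are resolved by flip count, then
by an exact dyadic position encoding, so enumeration order is fully
deterministic and is verified in the tests against exhaustive enumeration.

## Decoding and experiments

Stage outputs S1, S2, S3 are deduplicated in stage order (first occurrence
wins), parsed into (seed, payload) droplets, and peel-decoded: degree-1
droplets resolve segments, resolved segments XOR out of the remaining
droplets, until a fixpoint. The fixpoint is order-independent, so the
"sequential" feeding matters only for deduplication. Partial recovery is a
first-class result (the unresolved segment count is reported).

`sampling_experiment()` measures reading cost: over an ascending grid of
sample sizes N it draws one stratified sample per N (PF/NPF proportions
preserved, identical across scenarios at a given N) and records the
smallest N at which each scenario's workflow decodes perfectly. Because a
given sample's full-workflow decoder input is a superset of its
stage-1-only input, and peeling is monotone in its droplet set, the full
workflow can never need more reads than the baseline on the same grid —
the reported gain is the reduction ratio against the first listed scenario.

## Problem sizes and desk-scale choices

The package's own validation runs at desk scale, chosen once: the
reference-scale encode (513,600 bytes → 16,050 segments → 18,000 screened
droplets, ~12% LT redundancy) for layout and screening checks; a 16 KB file
(K = 512) with 720 droplets at 20× read coverage and 10% NPF reads for
ten-seed end-to-end recovery; and a 1 KB file (K = 32, 120 droplets) on an
NPF-enriched channel (50% NPF) for ten-seed reading-cost comparisons. The
droplet overheads above 12% at small K are deliberate: the robust-soliton
peeling overhead K + 2R·ln(R/δ) does not amortize at desk scale — at
K = 512 it is ~26% of K, at K = 32 comparable to K itself — so small pools
carry proportionally more droplets for the designed pool to be decodable at
all. This is a property of fountain codes, not of the analysis workflow
under test.

## Known limitations

- The channel has no position-dependent error profile, no PCR/coverage
  skew, and no chimeric reads; calibration is to class-level marginals.
- Exact-match adapter trimming does not model trimmer error tolerance.
- Sphere clustering is a full banded-DP greedy sweep, not a trie-indexed
  search; it is quadratic in the number of unique EDOL sequences and sized
  for desk-scale pools (tens of thousands of reads), not full archive runs.
- Byte-level interoperability with any particular deployed archive is not
  claimed: the LT degree distribution, selection PRNG, and RS conventions
  are documented and configurable, but archives written by other tools fix
  their own.
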