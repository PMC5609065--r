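---
title: "Error-correcting molecular barcodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-correcting molecular barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exbtools)
```

## The problem

RNA-Seq counts molecules by counting reads, but PCR duplicates inflate the
counts. Unique molecular identifiers (UMIs) made of fully random nucleotides
("random-mers") tag each cDNA molecule so duplicates can be collapsed — yet
a random-mer carries no redundancy: a single substitution during PCR or
sequencing creates a tag that looks like a brand-new molecule. At low input
amounts, where each molecule is sequenced many times, these phantom
molecules dominate.

`exbtools` implements the alternative this package is built around:
*exponentially-expanded barcodes* (EXBs). Each read end carries three 6-bp
subunits drawn from a 64-word error-correcting code, giving
$64^3 = 262{,}144$ labels per end and $64^6 \approx 6.9\times10^{10}$
paired-end labels. Substitution errors in a subunit are detected and usually
corrected, so a molecule keeps its identity through amplification and
sequencing. An inline 6-bp random-mer on each end (12 bp combined) rides
along purely as an instrument for *measuring* how error-prone naive
random-mer counting would have been on the same reads.

## The barcode code

Subunits are codewords of a $[6,3,4]$ linear code over the four-element
field GF(4), with the base mapping A = 0, C = 1, G = $\omega$,
T = $\bar\omega$. Addition is characteristic-2 (A is the identity), and the
generator is in standard form $G = [I_3 \mid P]$: the first three bases of a
barcode spell its message, the last three are linear redundancy. Minimum
pairwise distance 4 means single substitutions are uniquely correctable and
double substitutions are detectable.

Many generator matrices attain these parameters, so the package fixes one
canonically: an exhaustive search over all $4^9 = 262{,}144$
standard-form matrices (`search_generator_matrices()`) keeps the 486 whose
code attains distance 4, and the default configuration freezes the
lexicographically smallest of them. Any such code is MDS with the same
weight distribution ($A_4 = 45$, $A_6 = 18$), so every distance-based
property — including the pair histogram $\{4\!: 1440,\ 6\!: 576\}$ — is
independent of which qualifying matrix is chosen. Arithmetic is over GF(4)
rather than integers mod 4: mod-4 multiplication is non-invertible and
cannot yield a distance-4 linear code of these parameters.

```{r code}
code <- build_code()
code
head(code$barcodes)
```

### Syndrome decoding

The check matrix $H = [P^\top \mid I_3]$ maps every observed 6-mer to a
3-symbol syndrome; codewords map to zero. Each of the 64 syndromes indexes a
coset whose minimal-weight members (coset leaders) are the candidate error
patterns under parsimony:

* the zero syndrome has the single weight-0 leader (status `exact`);
* 18 syndromes have a unique weight-1 leader (`corrected`);
* the remaining 45 syndromes each have exactly three weight-2 leaders
  (`ambiguous` — three equally plausible barcodes, always including the
  true one when the word is within two substitutions of it).

The covering radius is therefore 2 and every ACGT word decodes; the package
precomputes the full 4096-entry decode table at code construction.
Positions reading N are treated as erasures: all substitutions at those
positions are enumerated before syndrome decoding and candidates of minimal
substitution weight on the determined positions are kept. One N is always
uniquely resolvable (distance 4 corrects one error plus one erasure); more
than two Ns are uncorrectable. Ambiguity is *never* guessed at the subunit
level — resolution is deferred to the read pool (below).

## Adapter geometry

The inline prefix of each read is: 6-bp random-mer, subunit 1, scaffold A
(10 bp), subunit 2, scaffold B (9 bp), subunit 3, scaffold C (9 bp), then
the 19-bp transposase (mosaic-end) recognition sequence — 71 bp in total,
leaving 80 insert bases of a 151-bp read. Scaffold content is a free choice
of the assay; the shipped scaffolds are synthetic sequences with
near-balanced GC, frozen in the default config and fully overridable, and
the 10/9/9 split of the 28 scaffold bases is a package convention. The recognition sequence is
carried as `AGATGTGTATAAGAGACAG` on the rendered strand; its reverse
complement `CTGTCTCTTATACACATCT` is what a read encounters on 3'
read-through and is the trimming target.

Combinatorial assembly needs one oligo per barcode per subunit slot plus
two common oligos, $3 \times 64 + 2 = 194$ sequences (192 barcode-bearing).
The second common oligo is the reverse complement of the standard Illumina
read-2 primer site — again a documented synthetic convention.

## Read processing

Decoding extracts the six subunits of a pair at fixed offsets and
syndrome-decodes each. Grouping is two-pass:

1. Reads whose six subunits all decode `exact`/`corrected` are grouped
   under their 6-index key and the key pool is recorded.
2. Each ambiguous read (candidate keys = Cartesian product of per-subunit
   candidates) is matched against the pool: exactly one hit assigns the
   read there; zero hits make it a unique molecule under its
   lexicographically smallest candidate key (the tuple label is arbitrary —
   what matters is that the molecule is counted once); two or more hits
   discard the read, because a misassignment would corrupt counts on both
   sides. All discards are logged with reasons, and
   assigned + discarded = input holds exactly. Grouping is
   insertion-order invariant.

Consensus calling uses base calls only (no qualities — the output FASTA has
none): per position, the plurality base over covering members, with ties
emitted as N. Members can differ in length (real libraries do); the
consensus length is the lower-median member length, which resists
overextension by chimeric or truncated members. Only the insert is
collapsed — the prefix content is already captured by the key. Read-through
trimming locates the forward target anywhere in the consensus allowing
substitutions/indels up to 10% of its length (the conventional trimmer
default), cuts from the leftmost hit to the 3' end, and drops pairs
trimmed below 20 bases.

## Random-mer error characterization

Within a read group — PCR duplicates of one molecule — all 12-bp
random-mers should agree. `randmer_group_stats()` measures, per group with
more than one read, the number of distinct random-mers (exact identity, the
naive counting convention; `merge_distance = 1` reproduces distance-1
correction), the discordance flag, and the maximum pairwise substitution
distance. Random-mers containing N are counted as distinct species but
flagged, so they can be excluded in sensitivity analyses.
`inflate_consensus()` then emits one consensus record per random-mer
species — exactly what a random-mer-based pipeline would have counted —
so EXB-based and random-mer-based molecule counts can be compared on
identical reads.

## Poisson error models

Both channels model the count of barcode errors in a molecule's read-out
family as Poisson with mean $\lambda = e\,l\,m$ (per-base rate $e$, barcode
length $l$, exposures $m$), so $P(\text{error}) = 1 - e^{-\lambda}$.

* **Sequencing channel**: $m$ is the group size;
  $P = 1 - \exp(-e\,l\,m)$, the complement of the Poisson zero class
  $p_0 = e^{-\lambda}$. At $e = 0.00136$, $l = 12$, $m = 42$ this gives
  49.6%: the 50% discordance point.
* **PCR channel**: after each cycle every product duplex carries one newly
  synthesized strand, so all $2^i$ copies present after cycle $i$ receive
  fresh error chances (the semiconservative reading of per-cycle error
  accumulation). Hence
  $P = 1 - \exp\!\big(-e\,l\,\textstyle\sum_{i=1}^{c} 2^i\big)
     = 1 - \exp\!\big(-e\,l\,2(2^c-1)\big)$,
  equal to the sequencing channel evaluated at $m = 2(2^c-1)$. The
  simulator's amplification step implements exactly this mechanism
  (heritable errors on both duplication products), so closed form,
  branching Monte Carlo (`pcr_branching_sim()`), and the library generator
  agree within binomial noise.

`fit_seq_error_rate()` estimates $e$ by bounded one-dimensional
maximum likelihood on the binomial log-likelihood of per-group discordance
flags, rather than least squares on binned fractions — sparse large-size
bins would otherwise dominate (a weighted-least-squares mode is kept for
comparison). The likelihood depends on the data only through the
(size, flag) cell counts, so the nonparametric bootstrap (1000 replicates,
percentile 95% CI) resamples those cells; a likelihood-ratio statistic is
reported against a negligible-error null at the optimizer's lower bound
$e = 10^{-8}$ (the exact $e \to 0$ null has zero likelihood whenever any
group is discordant), with a boundary-corrected 50:50 chi-square mixture
p-value.

`expected_collision_rate()` contextualizes label reuse: a birthday
approximation $1 - (1-p_\text{eff})^{\,n-1}$ with
$p_\text{eff} = (1+\mathrm{cv}_1^2)(1+\mathrm{cv}_2^2)/K$, where skewed
per-end label usage raises pair-coincidence by $1+\mathrm{cv}^2$ per end.

```{r models}
seq_error_prob(0.00136, 12, 42)
pcr_error_prob(1e-6, 12, 10)
```

## The library simulator

`simulate_library()` is the package's ground-truth generator: each molecule
receives an independent adapter per end (uniform subunit usage by default;
a lognormal mode with target CV emulates skewed pools), a uniform random
insert (80 bp, matching the default insert capacity; FASTA-derived inserts
are supported), branching PCR (default 10 cycles, efficiency 1, so the
closed-form exposure $m = 2^c$ holds), multinomial read sampling with
replacement proportional to final copy numbers, and i.i.d. per-base
sequencing substitutions. All randomness derives from one master seed
through labeled per-phase substreams, so each phase is individually
reproducible under refactoring.

What the generator deliberately does **not** emulate: indels, quality-score
structure, GC amplification bias, fragment-position structure, transcript
abundance distributions, self-tagmentation chimeras, and 3' read-through
(reads never extend past the template, so trimming is exercised on
constructed fixtures instead). Passing tests therefore demonstrate the
correctness of decoding, grouping, consensus and the error models under a
clean substitution channel — not robustness to every artefact of real
libraries. One known simplification: when a mutated copy spawns a further
mutated descendant, the descendant re-renders its inherited error positions
independently, so the specific substituted base at a shared position may
differ between parent and child; both still differ from the template, which
is all the discordance statistics observe.

A note on coverage: with reads drawn with replacement, a molecule can
receive zero reads (probability $\approx e^{-d/n}$ at depth $d$ over $n$
molecules — about 4–5% somewhere in a 1000-molecule, 10×-depth library).
The zero-noise identity is therefore asserted as "one group per molecule
present among the emitted reads, with consensus equal to the true insert",
which is the property the pipeline controls.

## Problem sizes and numerical choices

The test suite runs entirely on generated data at sizes chosen to make
binomial error bars decisive: exhaustive decoder sweeps (all $64\times18$
single and all 8640 double corruptions), $10^4$-replicate Monte-Carlo
model checks (3-SE bands), $10^5$-group parameter-recovery fits at rates
spanning $5\times10^{-4}$–$5\times10^{-3}$ (20 seeded repetitions per rate,
requiring $\ge 90\%$ bootstrap-CI coverage), a $10^6$-read uniform-tagging
abundance run, and end-to-end libraries of 1000 molecules at 10× depth.
Optimizer tolerance is $10^{-10}$ on the rate; decode ties are never broken
silently (ambiguity is explicit); empty groups, singleton groups,
zero-length sequences and empty FASTA output are all exercised.

## Limitations

Indel-channel decoding (relevant to long-read platforms) is out of scope —
the decoder is substitution-only by construction. The pool-resolution rule
discards reads whose candidates match several observed keys; at extreme
depth with very small label spaces this could bias against highly
duplicated molecules, though at the designed $6.9\times10^{10}$-label scale
pool collisions are rare (see `expected_collision_rate()`). Alignment,
transcript quantification and differential expression are downstream of
this package's terminal outputs (trimmed consensus FASTA and molecule
tables) and are intentionally not reimplemented.
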