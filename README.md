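# exbtools

Error-correcting **exponentially-expanded molecular barcodes (EXBs)** for
single-molecule counting in RNA-Seq — and a measurement bench for the
errors that plague ordinary random-mer UMIs.

## The problem and the method

Counting molecules with random-nucleotide UMIs fails quietly: a single
substitution during PCR or sequencing turns one molecule into two. EXBs
replace randomness with structure. Each read end carries three 6-bp
subunits drawn from the 64 codewords of a **[6,3,4] linear code over
GF(4)** (bases A, C, G, T ↔ field elements 0, 1, ω, ω̄; generator in
standard form `G = [I₃ | P]`, check matrix `H = [Pᵀ | I₃]`). Minimum
pairwise distance 4 means:

- any **single substitution** per subunit is uniquely corrected by
  syndrome (coset-leader) decoding;
- any **double substitution** is detected and yields exactly three
  equal-parsimony candidates, resolved against the pool of barcodes
  actually observed in the library.

Three subunits give 64³ = 262,144 labels per end and 64⁶ ≈ 6.9 × 10¹⁰
paired-end labels, assembled combinatorially from just 194 oligos. A
6-bp random-mer per end (12 bp combined) is carried inline so that, within
each EXB read group (PCR duplicates of one molecule), random-mer
disagreement directly measures UMI error. Both error channels follow a
Poisson model `P(error) = 1 − exp(−e·l·m)`; the PCR channel accumulates
exposures over cycles (`m = 2(2ᶜ − 1)`), and the per-base rate `e` is
fitted from discordance data by binomial maximum likelihood with a
bootstrap CI.

The package covers the full path: code construction and syndrome decoding,
adapter layout and oligo enumeration, FASTQ decoding → read groups →
majority consensus → read-through trimming → interleaved FASTA, random-mer
error statistics and count inflation, the Poisson models and rate fitting,
and a seed-deterministic library simulator with ground truth.

## Worked example

```r
library(exbtools)

code   <- build_code()     # 64 barcodes, min distance 4
layout <- build_layout()   # 71-bp inline prefix, 80 insert bp at 2x151

# decoding one corrupted subunit
decode_subunit("AACCTC", code)   # one substitution from barcode index 1
#> $status: "corrected"   $candidates: 1   $n_corrected_positions: 1

# a small simulated library with sequencing errors
cfg <- sim_config(n_fragments = 50, depth = 500, cycles = 6,
                  e_seq = 0.003, seed = 7)
sim <- simulate_library(cfg, code, layout)
dec <- decode_reads(sim$reads$seq1, sim$reads$seq2, code, layout,
                    ids = sim$reads$read_id)
gr  <- group_reads(dec)
gr
#> EXB read groups: 50 groups from 500 read pairs ( 0 discarded )

evaluate_counts(gr, sim$truth)
#> Molecule counts: true 50 | EXB 50 | random-mer inflated 70 |
#> assignment accuracy 1.0000 | 0 reads discarded
```

Fifty molecules were sequenced to ~10× depth at a per-base error rate of
0.003. EXB counting recovers exactly the 50 true molecules (every read
group is one molecule), while naive random-mer counting on the very same
reads would have reported 70 — forty percent phantom molecules created by
substitutions in the 12-bp random-mer. The model predicts the effect:
`seq_error_prob(0.00136, 12, 42)` ≈ 0.496, i.e. a read group of 42
duplicates has a ~50% chance of containing a corrupted UMI even at typical
sequencer error rates.

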