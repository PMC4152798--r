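# wsrep — tandem repeats in weighted (probabilistic) sequences

Tandem repeats — two or more adjacent copies of the same DNA segment —
arise from replication slippage and unequal crossing-over, and the copies
diverge over time, so biologically relevant repeats are approximate.  One
principled way to model that approximation is the **weighted string**: a
sequence in which every position holds a probability distribution over the
alphabet, as produced by IUPAC-ambiguous bases, SNP annotations, or
base-calling uncertainty.  `wsrep` finds **all tandem repeats in a
weighted string** in O(n log n)-class time, for biologists and
string-algorithm folk who need exact, threshold-defined repeat calls on
uncertain sequence.

## The problem and the output

Given a weighted string *x* of length *n* and a cumulative weight
threshold 1/z ∈ (0, 1], a word *u* is a **valid factor** at position *i*
when ∏ᵢ π_{i+j}(u[j]) ≥ 1/z.  A repetition is reported as a quadruple
**(i, p, b, e)**: e ≥ 2 adjacent copies of a primitive word *u* of length
(period) *p* starting at 0-based position *i*; *b* lists the letter chosen
at each branching (black) position inside the first copy, which is what
makes the quadruple uniquely decodable (`reconstruct_v()`).

* `solve_problem1(ws, t)` — all repetitions in which **each copy** of *u*
  is a valid factor at 1/z (the headline problem);
* `solve_problem2(ws, t)` — all **valid repetitions**, where the entire
  span u^e has cumulative probability ≥ 1/z.

The pipeline: filter letters below 1/z and split at unsupported positions;
colour positions black/grey/white (black = no letter above 1 − 1/z, the
only branching positions); generate *extended factors* around black
positions so that every valid factor occurs in one of them; compute each
factor's maximal repetitions with a partitioning-equivalent O(n log n)
runs algorithm; cut them to the threshold with longest-valid-factor (LF)
arrays; and, for the per-copy problem, compose overlapping valid squares
generated at the auxiliary threshold 1/z² into maximal chains.  Brute
force oracles (`brute_force_problem1()`, `brute_force_valid_repetitions()`,
`naive_maximal_repetitions()`) define correctness in the test suite.  See
`vignettes/weighted-tandem-repeats.Rmd` for the full account.

## Worked example

The 8-position weighted string aab[(a,0.5)(b,0.5)][(a,0.5)(b,0.5)]bab at
threshold 1/2:

```r
library(wsrep)
ws <- weighted_string(list("a", "a", "b", c(a = 0.5, b = 0.5),
                           c(a = 0.5, b = 0.5), "b", "a", "b"))
solve_problem1(ws, 1/2)
#>   i p e   b   u prob
#> 1 0 1 2       a 1.00
#> 2 1 3 2 2:a aba 0.25
#> 3 2 1 4       b 0.25
#> 4 3 1 2 0:a   a 0.25
#> 5 3 1 3 0:b   b 0.25
#> 6 4 1 2 0:b   b 0.50
#> 7 4 2 2 0:a  ab 0.50
```

Row 2 is the classic branching case: choosing `a` at black position 3
(recorded by b = "2:a", offset 2 of the root) makes u = aba repeat as
v = abaaba.  Each copy has probability 0.5 ≥ 1/2, so it is reported here —
but the whole span has probability 0.25 < 1/2, so it disappears under the
stricter whole-span condition:

```r
solve_problem2(ws, 1/2)
#>   i p e   b  u prob
#> 1 0 1 2      a  1.0
#> 2 2 1 2      b  0.5
#> 3 4 1 2 0:b  b  0.5
#> 4 4 2 2 0:a ab  0.5
```

`prob` is always the cumulative probability of the whole reported span.

Files: `read_iupac_fasta()` expands IUPAC codes to uniform distributions
(M → A/C at 0.5), `read_probability_matrix()` /
`write_probability_matrix()` handle the native per-position TSV, and
`write_repetitions()` / `read_repetitions()` round-trip result tables.
`synthesize()` plants ground-truth repeats in random weighted strings for
recall testing.  A thin command-line wrapper lives at `exec/wsrep`
(subcommands `find`, `synth`, `oracle`).

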