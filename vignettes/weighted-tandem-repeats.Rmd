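---
title: "Detecting tandem repeats in weighted sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tandem repeats in weighted sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsrep)
```

## The model

A *weighted string* x of length n assigns to every position i a probability
distribution over a finite alphabet: `x[i]` is a set of pairs (s, pi_i(s))
with the pi_i(s) summing to one.  This models uncertain sequence data —
IUPAC-ambiguous bases in DNA (the code M becomes A and C at probability 0.5
each), single-nucleotide polymorphisms, base-calling uncertainty — as a
position probability matrix.

Presence of a concrete word is graded by a *cumulative weight threshold*
1/z in (0, 1]: the word u is a **valid factor** at position i when the
product of its per-position letter probabilities is at least 1/z.  A
**repetition** is a quadruple (i, p, b, e): e >= 2 adjacent copies of a
primitive word u of length p starting at i, where b records the letter
chosen at each branching position inside the first copy (without b the
letters of u would not be determined; see `reconstruct_v()`).  The package
solves two problems:

* `solve_problem1()` — **all repetitions**: each individual copy of u is a
  valid factor at 1/z (the main problem);
* `solve_problem2()` — **valid repetitions**: the entire span u^e is a
  valid factor at 1/z (a strictly stronger per-span condition, used as a
  sub-routine of the first problem and useful in its own right).

Both run in O(n log n)-class time for constant z, the same asymptotics as
computing all maximal repetitions of a plain string.

## Pipeline

**Filtering and splitting.**  Letters with probability below 1/z cannot
take part in any valid factor and are removed (`filter_letters()`; at most
z letters survive per position).  Probabilities are deliberately *not*
renormalised afterwards — validity is defined against the original
probabilities.  Positions left empty support no valid factor at all, so the
string is cut there (`split_unsupported()`) and each segment processed
independently, with results mapped back to original coordinates.

**Colouring.**  Each position is marked white (one certain letter), grey
(one letter with probability greater than 1 − 1/z, none certain) or black
(no letter above 1 − 1/z).  Black positions are the *branching* positions:
the only places where a valid factor can choose between letters, because
two letters can each exceed 1 − 1/z only if z < 2, and in that case the
filter already leaves a single letter per position.  Two boundary rules are
normative here: probability exactly 1 − 1/z is *not* "greater than", so
such positions are black; and a probability within tolerance of 1 counts
as certain even when zero-probability letters are also listed.

**Extended factors.**  `generate_extended_factors()` builds a set of
concrete strings guaranteed to contain every valid factor.  Scanning left
to right, grey and white positions contribute their single stored letter
(grey probabilities are treated as 1 *during generation only*), and black
positions branch, one continuation per stored letter.  Each black position
also seeds fresh factors: one per letter there and one "empty" factor that
starts collecting letters just after it.  A factor stops at the black
position whose inclusion would drop its black-letter product below the
working threshold.  Duplicated (start, letters) pairs arising from
different seeds are collapsed, keeping the earliest seed.  Any valid factor
contains at most ell = log z / log(z/(z−1)) black positions, so no position
of x lies in more than z^ell (2 ell + 1) extended factors and their total
length is linear in n for constant z; the test suite asserts these bounds
on random inputs of length 1000.  Factors wholly contained in longer ones
with the same start are *not* pruned — short factors generated at a black
position are part of the covering set's definition.

**Maximal repetitions of a plain string.**  `maximal_repetitions()` needs
an O(n log n)-class algorithm whose output is the full set of maximal
repetitions (primitively-rooted, not preceded or followed by another copy
of the root).  No installed package computes these, so the package
implements the period-anchor runs method, which is output-equivalent to
Crochemore's partitioning refinement: for every period p, anchor pairs
(j, j + p) with j a multiple of p are extended in both directions by
vectorised longest-common-extension comparisons; hits of total extension
at least p delimit maximal periodic intervals, intervals reached with
several periods keep the smallest (that minimal period is also the period
of every primitively-rooted repetition inside — a consequence of the
periodicity lemma, asserted by the primitivity tests); each interval
[s, t] with period p finally expands to the repetitions
(i, p, floor((t−i+1)/p)) for i in s..s+p−1.  The sum of n/p anchor pairs
is O(n log n); a brute-force enumeration oracle
(`naive_maximal_repetitions()`) arbitrates exhaustively over all binary
strings up to length 12 and on random strings over larger alphabets.

**Longest-valid-factor (LF) arrays.**  Extended factors may contain
invalid substrings (grey probabilities were ignored), so a maximal
repetition of a factor need not be a valid repetition.  `compute_lf()`
gives, for each offset of a factor, the length of the longest prefix of
that suffix whose cumulative probability — actual probabilities at *all*
positions, grey included — meets a threshold.  Since window ends are
non-decreasing, a two-pointer sweep with a running product computes the
array in linear time; after 64 division steps the product is recomputed
over the current window to stop floating-point drift from accumulating.
`break_into_valid()` then cuts each maximal extended repetition: scanning
occurrence starts j = i, i+p, ... it emits the longest valid repetition
`min(floor(LF[j]/p), copies remaining)` at each start, skipping emissions
whose span is contained in the immediately preceding one.  This reporting
convention (longest-at-each-start with containment suppression) is the
package's own choice where several overlapping fragments would be
admissible; it avoids duplicate fragments while the oracle-equivalence
tests confirm that every valid repetition's span remains covered.

**Composition (all repetitions).**  A repetition whose every copy is valid
is glued together from *squares* (e = 2) whose two halves are each valid.
The pipeline therefore reruns the machinery at the lowered threshold
k = 1/z² — chosen exactly so that a square of two 1/z-valid halves is
whole-span valid at k — splits the maximal extended repetitions into their
overlapping squares, and keeps the squares whose halves both pass LF′, an
LF array computed at 1/z on the same factors.  Surviving squares are
bucketed by (start, period) in an associative map (standing in for the
per-position linked-list arrays with perfect hashing of the original
construction; expected O(1) lookup is preserved, and a string has at most
log_phi(n) square prefixes so the number of distinct periods per start is
logarithmic).  Chains grow greedily over ascending starts: a square at
(i, p) extends with a compatible square at (i + p, p) — compatible meaning
the black-position letters agree on the overlap, which pins the entire
overlap since non-black positions store one letter — and consumed squares
are deleted, so every square joins exactly one chain (the conservation
test asserts sum(e − 1) over chains equals the square count).  Left
maximality is thus with respect to *valid* square extension, and the
exponent is maximal under appending another valid copy; the brute-force
oracle uses the same reading (extension by a valid copy), which the
package treats as the operational definition of "u^{e+1} does not occur".
Finally `report_all()` emits every suffix occurrence (i + kp, p, b_k,
e − k), since repetitions per the definition are right-maximal only.

**b-set convention.**  The composition pass colours at k = 1/z², which can
make positions black that are merely grey at 1/z (letters in
(1 − 1/z², 1 − 1/z]).  Reported b-sets are always recomputed against the
user's 1/z colouring, so quadruples from both solvers share one convention
and compare directly with the oracles; any letter of a kept square at a
1/z-grey position necessarily is that position's dominant letter, so no
information is lost.  b offsets are relative to the emitted repetition's
own start, recomputed after break-up and for every reported suffix.

## Numerical choices

Probability comparisons use a relative tolerance of 1e-9: a value within
tolerance of a bound meets ">=" and fails a strict ">".  Raw per-position
sums must be 1 within 1e-6 on ingest.  Thresholds are taken as given
numbers (1/2, 1/4, ...); ell is kept as a real number and used as a bound
only for z >= 2.  Output tables are deduplicated on the full quadruple and
sorted by (i, p, e, b) for byte-reproducible results.

## Oracles and what the tests show

Three brute-force oracles define correctness independently of the
pipeline: direct enumeration of maximal repetitions of a plain string, of
whole-span-valid repetitions, and of per-copy-valid repetitions (the last
two enumerate every concrete root over the stored letters).  The
all-repetitions solver is asserted *set-equal* to its oracle; the
valid-repetitions solver is asserted equivalent up to the break-up
reporting convention (every emission valid, every oracle span covered) —
cross-factor truncation can add a shorter emission alongside the full one,
which the convention permits.

Problem sizes in the suite are chosen to keep a pure-R run comfortable:
the plain-string equivalence is exhaustive over binary strings to n = 12
plus 200 random strings to n = 200 over alphabets of 2–4; the weighted
family over position types {certain, (0.5, 0.5), (0.75, 0.25)} at
thresholds 1/2 and 1/4 is exhaustive to n = 4 and randomly sampled (fixed
seeds) at n = 5..8, plus 200 random general instances to n = 12; the
structural bounds run on 100 random length-1000 strings.

## The synthetic generator

`synthesize()` emulates uncertain genomic sequence with planted tandem
repeats: a uniform random background, a requested fraction of uncertain
positions (intended letter 0.6, one random other letter 0.4 — black at any
threshold with z >= 2.5, grey for 2 <= z < 2.5), and planted repeats with
random primitive roots whose flanking letters are forced to break the
period, so the planted (start, period, exponent, b) is recovered exactly
and recall can be scored.  The number of uncertain positions inside any
single planted copy is capped so the copy stays valid at the requested
threshold (0.6^c >= 1/z).  What it does *not* emulate: realistic DNA base
composition or repeat length distributions, approximate copies that
differ by substitutions with certainty (only probabilistic uncertainty),
indel-mutated repeats, or position-dependent error profiles from real
base callers.  Passing recall tests therefore show the machinery is
sound, not that thresholds are well-calibrated for a particular
sequencing technology.

## Limitations

* The constant factor grows quickly with z (the z^ell branching of
  extended factors); the method is intended for constant, small z, as are
  all known approaches at this complexity.
* Output is the full set of repetitions, O(n log n) of them; a most
  compact runs-style representation for weighted strings is an open
  problem and out of scope.
* Don't-care letters and probability renormalisation are deliberately not
  supported; FASTQ-quality-derived and VCF-derived weighted strings are
  plausible extensions left out.
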