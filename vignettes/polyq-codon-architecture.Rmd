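---
title: "The codon architecture of polyglutamine stretches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The codon architecture of polyglutamine stretches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqscan)
```

## The problem

Glutamine is encoded by two synonymous codons, CAA and CAG. Although the
protein product is identical, the two codons behave very differently at the
DNA level: long runs of CAG are prone to expansion by replication slippage,
the mechanism behind polyglutamine (polyQ) disorders such as Huntington's
disease, while CAA interruptions stabilise a repeat. The arrangement of the
two codons inside and around a polyQ stretch therefore records something
about the mutational and selective forces acting on these regions.

`polyqscan` scans in-frame coding sequences (CDS) for maximal runs of
CAA/CAG codons and quantifies their architecture along six axes: codon
usage by stretch length, within-stretch codon position, nucleotide
similarity to the flanking codons, amino-acid context of the flanks, the
longest identical-codon run against an exact chance model, and four-codon
pattern composition. Each axis is one module with a small function surface,
and every module is validated against a synthetic transcriptome generator
whose ground truth is known exactly.

## Stretch detection and representation

A *stretch* is a maximal run of consecutive CAA/CAG codons in the frame-0
codon sequence of a transcript; runs of length one count. Sequences are
assumed to be CDS starting in frame (the Ensembl CDS convention) — no ORF
search is performed. A terminal stop codon is stripped by default so that a
stretch at the C-terminus reports a *missing* +1 flank rather than a stop
codon; stops carry no residue, and the amino-acid context analysis would
otherwise conflate "no neighbour" with "stop neighbour". The stripping is
counted in the dataset manifest, and `strip_stop = FALSE` restores the
alternative. Codons containing ambiguity letters (N and friends) are never
glutamine codons and terminate runs; this is conservative in that it can
split a stretch but never inflates one.

Each stretch row records its 0-based start, length, composition (a string
over `G` = CAG, `A` = CAA), CAA/CAG counts, purity class (`pure_CAG`,
`pure_CAA`, `mixed`), and the codons at positions −5…−1 and +1…+5, `NA`
past the transcript ends. Maximality guarantees the −1/+1 codons are never
CAA/CAG.

## Codon usage by stretch length

`usage_profile()` aggregates CAA/CAG counts per exact stretch length 1–6,
pools lengths ≥ 7 into a `>6` class (long stretches are rare enough that
exact-length denominators become unstable), and reports an overall
background class `bg`. Fractions are always accompanied by their raw
counts. The pooling threshold is a parameter (`pool_threshold`, default 6)
so sensitivity to the pooling choice can be checked.

## Within-stretch codon position

In a stretch of $L \ge 2$ codons, the codon at 0-based index $i$ has
relative position $i/(L-1)$: 0 at the N-terminal end, 1 at the C-terminal
end. `relative_positions()` pools positions across all stretches of length
≥ `min_length` (default 4 — below that, a codon's position carries almost
no information) into one sample per codon identity, and
`compare_positions()` applies the rank test. Pooled codon-level samples are
the default because they weight each codon equally; per-stretch mean
aggregation (`per_stretch_means = TRUE`) is provided for the reading in
which each stretch is one observation. Both modes answer slightly different
questions; for the biases the generator can inject, they agree in direction.

## Flanking-codon similarity

`hamming()` is the plain Hamming distance on 3-mers (0–3 mismatched
positions). `flank_distances()` compares the −1/+1 flank codon against the
stretch codon *adjacent* to it (first codon for −1, last for +1): that is
the codon whose single point mutation could have produced the flank, which
is the mechanistic question being asked. For pure stretches the choice is
immaterial; for mixed stretches it is a genuine decision, and
`reference = "mean"` (average distance over all stretch codons) is
available for comparison. Because flanks of a maximal stretch are never
CAA/CAG, distances to present flanks always lie in 1–3; the test suite
verifies this exhaustively on tens of thousands of scanned stretches.
Stretch length is recorded on every distance record so length-stratified
replications are possible, although length plays no role in the defaults.

## Amino-acid context

`context_table()` translates the ±5 flank codons (standard genetic code;
any ambiguous codon becomes `X`) and tallies them per position, purity
class and length bin (4–7 vs ≥ 8 codons). `top_non_q()` reports the most
frequent amino acid excluding glutamine — context positions are often
themselves Q, which would drown the rest of the signal — and excluding `X`.
Ties are broken alphabetically and flagged rather than hidden. Because
"enriched" can mean raw frequency or proteome-normalised frequency, the
raw-frequency winner is the default and the enrichment ratio against
`proteome_aa_usage()` is reported alongside when a background is supplied;
both readings are one argument apart.

## The longest-run chance model

The null question: if the $L$ codons of a stretch were chosen
independently, CAG with probability $p$, how long would the longest run of
consecutive CAG codons be? `max_run_pmf()` computes the exact distribution
by dynamic programming over the pair (current trailing run $r$, maximum run
so far $m$):

$$
P_{i+1}(0, m) \mathrel{+}= P_i(r, m)\,(1-p), \qquad
P_{i+1}(r+1, \max(m, r+1)) \mathrel{+}= P_i(r, m)\,p .
$$

The boundary identities $\Pr(M_L = L) = p^L$ and $\Pr(M_L = 0) = (1-p)^L$
hold exactly, and the DP is tested against brute-force enumeration of all
$2^L$ weighted codon assignments for every $L \le 12$ at a grid of $p$
values, to $10^{-12}$. The DP is capped at $L = 64$ (cost grows as $L^3$
and stretches anywhere near that length do not occur); beyond it,
`generate_random_stretch()` provides a Monte-Carlo null.

The observed-vs-random comparison follows the cohort construction:
`random_cohort()` draws exactly one random stretch per observed stretch, of
identical length, at the CAG probability of the *length class* containing
it (the `>6` pooled class for lengths ≥ 7; `exact_length_usage = TRUE`
switches to exact-length usage). `compare_observed_random()` then rank-tests
observed against random maximum runs per codon and length bin (4–5, 6–7,
≥ 8). The null draws codons i.i.d. rather than permuting observed codons —
the two differ exactly when within-stretch arrangement is non-random, which
is the effect under study; a permutation variant would condition it away.

One calibration subtlety is worth stating. The pipeline's cohort uses the
usage *estimated* from the observed stretches, as the analysis it
reproduces does. That plug-in couples the two cohorts: when the observed
sample happens to be CAG-heavy, its random partner is too, so the
comparison is mildly *conservative* (measured type-I rate ≈ 0.015 at
nominal 0.05 for cohorts of 150 stretches). It never overstates
significance. `calibrate_type1()` therefore draws both cohorts i.i.d. at
the known generating usage when checking that the comparison machinery
itself is calibrated (rate ≈ 0.05), and the plug-in behaviour is documented
here rather than "corrected", since it is the construction being
reimplemented.

## Four-codon patterns

`quadruplets()` decomposes a stretch into its $L-3$ sliding windows of four
codons, written over `G`/`A`; `quadruplet_profile()` pools windows per
length bin and normalises over the 16 patterns. All stretches of length
≥ 4 contribute by default, so `GGGG`/`AAAA` windows from pure stretches are
part of the denominator; `restrict_to_mixed = TRUE` keeps only mixed
stretches, in which `GGGG` can still occur as a window but never as a whole
stretch. Both views are useful: same-composition patterns (e.g. `GGAA` vs
`GAGA`) are comparable free of usage bias either way, which the property
tests exploit via exchangeability under i.i.d. codons.

## Rank statistics

Every comparison uses the two-sided Mann–Whitney U test:
exact null when the pooled sample size is ≤ 20 with no ties, otherwise the
normal approximation with tie and continuity corrections. The reported U is
the minimum of the two one-sided statistics; direction is carried by the
group means, as in the figures this reproduces. When every pooled value is
identical the statistic has zero variance and the test reports $p = 1$ (no
evidence) rather than `NaN`. Stars follow the usual convention (`***`
< .001, `**` < .01, `*` < .05). P-values are deliberately *not* adjusted
per comparison — matching the per-panel stars of the analyses this package
reproduces — but every comparison table carries a Benjamini–Hochberg column
for transparency.

## The synthetic generator

`synthetic_spec()` + `generate_dataset()` produce transcriptomes whose
statistical structure matches what the analysis assumes, with exact ground
truth:

* **Stretch lengths** default to a truncated geometric with ratio 0.5 on
  1…30: 87.5 % of stretches have length 1–3 and under 1 % have length ≥ 8,
  the heavy-tailed shape real transcriptomes show.
* **Codon usage** defaults to a constant $P(\text{CAG}) = 0.75$ per length
  class — the mammal-like usage used in the worked probability examples —
  and accepts any per-class map (e.g. rising usage with length).
* **CAA placement** uses a single-parameter exponential position weight:
  CAA positions are drawn with weight $\exp(\beta \cdot i/(L-1))$. $\beta =
  0$ reduces exactly to i.i.d. codons; $\beta = 3$ gives the strong
  C-terminal CAA shift used in the power checks.
* **Flank similarity** is a probability that the +1 flank of a pure-CAG
  stretch is drawn from the seven sense codons at Hamming distance 1 from
  CAG instead of uniformly from all 59 non-Q sense codons.
* **Context emissions** optionally pin amino-acid distributions at chosen
  flank positions per length bin.
* **Filler codons** are uniform over the 59 non-glutamine sense codons, so
  with the default `bg_q_rate = 0` the injected stretches are provably the
  only CAA/CAG runs and detector output can be compared to ground truth
  exactly; a positive `bg_q_rate` sprinkles chance Q codons to exercise
  maximality handling. Transcripts are 100–400 codons with on average two
  stretches each, separated by at least one filler codon, with a terminal
  stop appended.

Generation is a deterministic function of the spec including its seed, and
restores the caller's RNG state.

What the generator does *not* emulate: real codon-usage tables outside the
Q codons, gene structure, GC heterogeneity, paralogy (e.g. polyploid
genomes), or any dependence between neighbouring stretches. Passing tests
therefore demonstrate that the *pipeline* measures what it claims under the
stated model — not that any particular biological claim holds in real data,
where those unmodelled features exist.

## Numerical and testing choices

* Exact/approximate rank-test switch at pooled $n = 20$; below it and
  tie-free, p-values are exact and tested against full rank-split
  enumeration for all sample-size pairs with $n_a + n_b \le 10$.
* The DP is validated to $10^{-12}$ against enumeration; probabilities are
  never renormalised (the sum-to-one check is an assertion, not a fix).
* Degenerate inputs: empty FASTA yields an empty dataset with a warning;
  empty stretch tables yield typed empty results; empty comparison groups
  are marked missing rather than dropped.
* Test problem sizes: calibration runs 2000 neutral replicates per
  comparison stage (150–200 stretches each); power runs 100 replicates of
  500 stretches; detection exactness runs 100 random generator
  specifications; the flank-bound check scans two datasets totalling over
  10⁴ stretches. These sizes make binomial error on the measured rates
  small relative to the asserted bands.

## Limitations

* Only pure CAA/CAG runs are analysed; interrupted Q-rich regions
  (e.g. CAG-CAT-CAG) are out of scope by design.
* The chance model is i.i.d. codon choice within a stretch; it does not
  model slippage dynamics, expansion rates, or phylogenetic dependence
  among species.
* Flank similarity is a proxy for mutational history, not a reconstruction
  of events.
* The `>6` usage pooling and the 4–7/≥8 context bins are conventions kept
  for comparability; both are parameters where the code allows it.
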