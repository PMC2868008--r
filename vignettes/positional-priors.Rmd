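---
title: "Motif discovery with position-specific priors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif discovery with position-specific priors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifem)
```

## The problem

Transcription-factor binding sites are short, degenerate words scattered
through much longer regulatory sequences. Given a set of sequences suspected
to share such a signal -- typically the regions pulled down by a ChIP
experiment for one factor -- motif discovery asks for the position weight
matrix (here called a PSPM, \(\theta\), with entries \(f_{a,k}\) = probability
of letter \(a\) at motif column \(k\)) that best explains a recurring site.
Because real motifs carry barely more information than is needed to locate
them, auxiliary evidence matters. This package implements the classic
three-phase EM search for motifs under the OOPS (exactly one site per
sequence) and ZOOPS (zero or one site per sequence) models, extended so that
a *position-specific prior* (PSP) -- a per-position prior probability
\(P_{i,j}\) that a site of width \(w_0\) starts at position \(j\) of sequence
\(i\), plus a per-sequence no-site mass \(P_{i,0}\) -- informs every phase.
Conservation scores, nucleosome occupancy, discriminative signals against a
negative sequence set, or any other evidence can be summarized as such a
prior; inside the search the prior is the only interface.

## The sequence model

For each sequence \(X_i\) of length \(L_i\) the missing data are indicators
\(Z_{i,j}\) of a site starting at \(j\) (on either strand in double-stranded
mode). The model parameters are \(\phi = \{\theta, \gamma, \mathbf P\}\):
the motif PSPM \(\theta\), the probability \(\gamma\) that a sequence
contains a site (fixed at 1 under OOPS), and the prior \(\mathbf P\), which
EM holds fixed. A PSP must satisfy \(0 \le P_{i,j} \le 1\), \(P_{i,j} = 0\)
for \(j > L_i - w_0 + 1\) (sites must fit), and
\(P_{i,0} + \sum_j P_{i,j} = 1\); OOPS forces \(P_{i,0} = 0\). When both DNA
strands are searched the prior is required to be strand-symmetric; the
package stores only the forward array and assigns a reverse-strand site the
prior of its leftmost forward coordinate, which realizes the symmetry
exactly without duplicate storage.

**Combining \(\gamma\) with the prior (ZOOPS).** The E-step uses
\[
\Pr(Z_{i,j}=1) = \gamma\,\frac{P_{i,j}}{1 - P_{i,0}}, \qquad
\Pr(\text{no site}) = 1-\gamma,
\]
halving the positional mass across strands in double-stranded mode. The
positional *shape* therefore comes from the prior while the site *frequency*
is estimated by EM through \(\gamma\). This factorization reduces to the
OOPS case at \(\gamma = 1, P_{i,0} = 0\) and to the classic uniform-prior
model when the PSP is uniform; it was chosen because it keeps the two kinds
of information (where a site would be; whether there is one) separately
controllable.

**Renormalizing the prior to other widths.** A PSP is tied to the width
\(w_0\) it was built for. When the search considers \(w > w_0\), the prior
of a width-\(w\) site is the geometric mean of the priors of the first
\(c = \min(w - w_0 + 1,\, w_0)\) width-\(w_0\) sites it contains, after
which positional values are rescaled by a per-sequence constant. The
normalization constant preserves \(P_{i,0}\) and rescales the positional
mass to \(1 - P_{i,0}\): the user's encoded site/no-site balance is kept,
and the constraint set is restored. For \(w < w_0\) the prior is used
unchanged, so trailing positions that the input prior never described keep
prior zero even though they become legal starts -- the input carries no
information about words starting there. If renormalization annihilates every
positional value of a sequence (possible when the prior contains many exact
zeros), that sequence falls back to a uniform prior over its legal
positions, with a warning.

## The three phases

**Phase I, starting points.** Every mask-free subsequence of the data is
converted to a starting PSPM (probability \(\beta = 0.55\) on the word
letter, the remainder spread evenly; \(\beta\) must exceed the uniform 0.25
to be informative and 0.55 is a moderate default that does not overcommit to
the seed word). For each starting model, every legal site is scored by
likelihood times prior; the best site per sequence is kept, and (ZOOPS) the
per-sequence winners are ranked by posterior and prefixes of length \(t\)
evaluated for \(t \in \{2, 4, 8, \dots\} \cup \{n\}\) (powers of two capped
at \(n\); a geometric schedule because the useful resolution in \(t\) is
relative, not absolute). A candidate site set is scored by the *weighted*
log-likelihood ratio
\[
\mathrm{LLR} = \sum_k \sum_a c_{a,k} \log_2 \frac{f_{a,k}}{p_a},
\]
where the count contribution of each site is its prior scaled so the largest
prior in its sequence is 1, \(f = c / N_{wt}\), and \(p_a\) is the
zero-order background. High-prior sites therefore shape the starting-point
choice even before EM runs. Because the starting model puts a single
probability \(\beta\) on each word letter, a site's likelihood depends only
on its Hamming match count with the seed word; the implementation exploits
this with bit-packed windows and popcount matching in C++, which is what
makes the exhaustive scan affordable.

**Phase II, EM.** The E-step computes posteriors
\(Z_{i,j} \propto \Pr(X_i \mid Z_{i,j}=1, \theta)\Pr(Z_{i,j}=1)\), normalized
per sequence together with the no-site term (the likelihood ratio against
the background model uses the full-order background conditionals within the
site window, contexts taken from the whole sequence). The M-step
re-estimates \(\theta\) from posterior-weighted letter counts with a
background-proportional Dirichlet pseudocount \(\delta_a = 0.01\,p_a\)
(avoids zero probabilities; proportionality to the background makes the
regularization composition-neutral), and under ZOOPS re-estimates
\(\gamma = \tfrac1n \sum_i (1 - Z_{i,0})\), clamped to \([1/n, 1]\).
Iteration stops when \(\max |\Delta\theta| < 10^{-3}\) or after 50
iterations -- ordinary EM settings at this problem scale; the recorded
objective (log likelihood plus the Dirichlet log prior) is non-decreasing
per MAP-EM theory and is checked to 1e-8 relative tolerance in the tests.

**Phase III, significance.** Sites are the positions with the largest final
posteriors (OOPS: argmax per sequence; ZOOPS: per-sequence winners sorted by
posterior, each prefix of length \(\ge 2\) scored). A site set is scored by
the product of per-column p-values of the column LLR -- each column's null is
`nsites` i.i.d. draws from the zero-order background, solved exactly by
multinomial-composition enumeration up to 200 sites and by a 2048-bin
discretized-score accumulation above that -- converted to a motif p-value via
the distribution of a product of independent uniforms,
\(\rho \sum_{i<k} (\ln 1/\rho)^i / i!\), and multiplied by the number of ways
to place that many sites: \(\binom{n}{t} \prod_{\text{chosen}} (s\,m_i)\)
for ZOOPS and \(\prod_i (s\,m_i)\) for OOPS (\(s\) strands,
\(m_i = L_i - w + 1\); unordered placements, computed in log space). The
candidate with the smallest E-value across widths and site counts is
reported. On weak data this Bonferroni-style placement count makes large
site sets expensive, so reported site counts can be small even when the
posterior ranks many true sites highly; the E-value is then honest about the
weak significance. Discovery is a pure function of its inputs: candidates tie
toward the smaller width and earlier sequence position, and starting words
with equal Phase I scores (common, since many seed words elect the same
site set) tie toward the strand-canonical word -- the lexicographic minimum
of the word and its reverse complement -- so that reverse-complementing the
input elects the mirrored winner rather than an arbitrary one.

**Multiple motifs.** After a motif is reported, each position's retention
weight is multiplied by \(\prod_d (1 - Z_{i,j-d})\) over reported sites
covering it ("probabilistic erasing"); subsequent rounds multiply the prior
by these weights and renormalize per sequence, so certain sites cannot be
rediscovered while uncertain ones are only damped.

## Evaluation metrics

The scaled Euclidean distance between equal-width motifs,
\(D = \tfrac1w \sum_i \lVert f_{\cdot i} - g_{\cdot i}\rVert_2 / \sqrt 2\),
lies in \([0,1]\). Between motifs of unequal width the minimum of \(D\) over
all alignments with overlap at least the shorter width, and over both
orientations, is reported; the per-alignment distance averages over the
*overlap* columns (the minimum-overlap rule implies a per-overlap
computation; normalizing by the shorter motif's full width would double-count
unaligned columns). A reported motif lacking a width-6 window of mean
information content of at least 1 bit (against a uniform background) is
assigned the maximal distance 1.0 -- this filter rejects low-complexity
matrices that would otherwise align well by chance, and it is applied to the
reported motif only. Discovery success means distance strictly below 0.25.
Motif quality on sequence sets without a gold standard uses the average
motif affinity (AMA): the mean over all legal positions and strands of the
motif-versus-background likelihood ratio of each window (an AMA of 1 is
background level). Pairs of configurations are compared by the Spearman rank
correlation between AMA and an external binding score, and by a two-sided
exact sign test over paired samples (two-sided because either configuration
may win).

## The synthetic data generator

`generate_dataset()` emulates a ChIP-derived positive set: `n = 50`
background sequences of length `L = 200`, of which `floor(0.5 n)` receive
one site at a uniformly random legal position on a random strand, sampled
from the planted PSPM and mutated per position with probability 0.16. With
the default consensus `TGACTCAG` this yields an effective planted motif of
about 1.11 bits of information per column -- about 8.9 bits in total, close
to the \(\log_2(2 \times 193) \approx 8.6\) bits needed to specify a site
location, i.e. a deliberately weak motif at the edge of detectability, the
regime in which positional priors matter. `generate_psp()` builds the
matching informative prior: mass `concentration` on the true start, spread
\(j-1, j, j+1\) with weights 1:2:1 (a site's neighborhood is almost as
likely under an imperfect external signal), the remainder uniform;
sequences without sites get a uniform prior and, under ZOOPS,
\(P_{i,0} = \texttt{concentration}\). At `concentration = 0` this is exactly
the uniform prior.

What the generator does *not* emulate: positional biases of real ChIP peaks
(sites concentrated near peak centers), higher-order background structure
and repeats, motif variants on both flanks, or correlated errors in the
prior (a real conservation-based prior is wrong in structured ways, not by
uniform dilution). Passing the synthetic benchmarks therefore demonstrates
correctness of the machinery and the direction of the prior's benefit, not
field performance on ChIP data.

## Problem sizes and numerical choices

The bundled checks run discovery over widths 7-9 around the planted width 8
on 30 datasets per configuration -- wide enough to exercise width
renormalization and width selection; the yeast-scale protocol of widths 7-12
adds nothing methodologically at these sequence lengths. Reverse-complement
equivariance is asserted to within 1e-6 in aligned distance rather than
literal equality: mirroring the input reorders floating-point accumulations,
which can move EM fixed points by amounts of that order. The equivariance
check runs at widths at or above the prior's design width: below \(w_0\) the
prior is used unchanged (forward-anchored by definition), which breaks
mirror symmetry by construction, as does the \(c \le w_0\) cap for motifs
wider than \(2 w_0\). Column p-values are
exact (enumeration) up to 200 sites; the lattice approximation above that is
accurate to a few percent on the log scale at its default 2048 bins.
`0 log 0 = 0` throughout; all motif significance arithmetic is done in log
space; E-values are reported as `log10` alongside a clamped linear value.

## Known limitations

Only OOPS and ZOOPS are supported -- the any-number-of-repeats model has no
prior mechanism here. The Phase I bit-packed kernel supports motif widths up
to 32 on DNA (12 on protein). Priors wider than the sequences, or priors
that zero out every position of a sequence under OOPS, are errors by
construction. AMA uses within-window background chaining, so its order-k
null differs slightly from the E-step null at window boundaries. The
E-value's placement count treats sequences as exchangeable and ignores
overlap between candidate placements; it is a ranking device and an upper
bound on significance, not a calibrated p-value.

## A worked example

```{r example}
d <- generate_dataset(n = 20, len = 100, seed = 3)
prior <- generate_psp(d$sites, d$seqs, w0 = 8, concentration = 0.8,
                      model = "zoops")
res <- discover_motifs(d$seqs, psp = prior, model = "zoops",
                       minw = 7, maxw = 9)
res
aligned_distance(res$motifs[[1]]$pspm, d$motif)
```
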