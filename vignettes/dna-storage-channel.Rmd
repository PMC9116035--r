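---
title: "Modeling the DNA data storage channel and choosing code redundancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the DNA data storage channel and choosing code redundancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dnachannel)
library(dplyr)
```

## The problem

Storing digital data in synthesized DNA passes a file through a noisy
physical channel: oligonucleotides are synthesized in many erroneous copies,
decay in storage, are amplified by PCR with per-sequence bias, sub-sampled
into a sequencing library, and finally read out with platform-specific
errors. Two error classes reach the decoder: a designed sequence can be
*lost* outright (no reads recovered), or its voted consensus can carry
*within-sequence errors*. Error-correcting redundancy — a fountain code
across sequences plus Reed–Solomon (RS) parity within each sequence — must
be budgeted against exactly these two classes, and over-budgeting wastes
information density. Because wet-lab iterations are slow and expensive, this
package simulates the channel end to end and uses the simulated noise
profile to pick the redundancy level in silico.

## Pool representation and the two primitives

A pool is a *variant table*: reference sequence `i` exists as error types
`e_i1, e_i2, ...` with copy numbers `n_i1, n_i2, ...`. A variant is
identified by a canonical edit string (0-based positions in
original-reference coordinates, substitutions applied before deletions
before insertions, see `?parse_edits`), which makes variant identity
well-defined and order-independent. The representation scales to $10^7$
molecules because only distinct error types occupy rows.

Every stage is a composition of two primitives:

* **Error generation** (`generate_errors()`): each molecule independently
  acquires new edits at per-base probabilities given by a substitution
  matrix `T_sub`, a deletion rate `P_del` and an insertion rate `P_ins`.
  The implementation splits off the molecules that acquire at least one
  edit with a single binomial draw per variant
  (success probability $1-(1-p)^L$) and only simulates those: each affected
  molecule draws its number of edited positions from a truncated binomial,
  positions uniformly without replacement, and the event type from the
  normalized `(substitution, deletion, insertion)` mass at that position.
  For the flat preset rates this is distributionally identical to naive
  per-molecule simulation; for base-dependent `T_sub` the position choice
  is homogenized over the reference composition (the rate presets shipped
  here are flat, so nothing is lost). Molecule counts are conserved exactly
  and asserted on every call.
* **Distribution change** (`change_distribution()`): every copy number is
  replaced by an independent draw from a count-conditional law —
  binomial thinning for decay/sampling/dilution, branching growth for PCR,
  multinomial allocation for reads. Variants that hit zero are dropped;
  references whose total hits zero are lost.

## Stage models and their parameters

Published per-stage error rates in the DNA-storage literature are
heterogeneous across platforms and chemistries, so there is no single
correct set of numbers to ship. The defaults below were chosen once from
typical reported ranges (array synthesis total error about 1/200 nt,
deletion-leaning; NGS substitution-dominated around $10^{-3}$/nt) and then
*fixed at design time* so that the default channel exhibits the canonical
noise structure of array-synthesis/NGS storage experiments: a converged
lost count of a few per mille at a 0.1% sampling ratio, and a voting-error
profile dominated by single-error sequences. They are package defaults,
not measurements; every one is a `channel_config()` knob.

| stage      | parameter                  | default | meaning |
|------------|----------------------------|---------|---------|
| synthesis  | `mean_depth`               | 5000    | expected copies per design |
|            | `count_distribution`       | binomial| initial copy-number law (`prob = 0.5`); negative-binomial toggle for wider pools |
|            | rates (sub/del/ins per nt) | 0.003 / 0.0015 / 0.0005 | coupling-failure errors |
| decay      | `survival_prob`            | 0.99    | per-molecule survival in storage |
|            | rates                      | sub 0.001, deamination-weighted (C→T, G→A ×8) | damage |
| PCR        | `cycles`                   | 10      | amplification cycles |
|            | `efficiency`               | 0.8     | mean per-cycle duplication probability |
|            | `bias_sigma`               | 0.03    | SD of the per-sequence efficiency (drawn once, truncated to [0,1]) |
|            | `dilute`                   | TRUE    | thin back to the pre-PCR molecule count |
| sampling   | `ratio`                    | 0.001   | fraction of the pool carried to sequencing |
| sequencing | `depth`                    | 30      | mean reads per surviving reference |
|            | rates                      | `ngs_rates()` (sub 1e-3, indels 1e-4); `nanopore_rates()` preset for high-error platforms | read errors |

Two modeling choices deserve emphasis because the underlying laws are not
published:

* **PCR** is a per-cycle Galton–Watson branching process
  ($n \leftarrow n + \mathrm{Bin}(n, e_i)$) with the efficiency $e_i$ drawn
  once per reference — this reproduces the persistent between-sequence
  amplification bias that skews the copy-number distribution, which a
  memoryless per-cycle noise would not. The post-PCR **dilution** mirrors
  the aliquot taken after amplification in real protocols; it keeps the
  pool at a bench-realistic scale so that a sampling *ratio* has its usual
  meaning. Without it, ten cycles multiply the pool ~357-fold and any fixed
  ratio would imply absurdly deep sampling.
* **Sampling** uses independent binomial thinning rather than exact
  hypergeometric draws; at pool sizes vastly exceeding sample sizes the two
  are indistinguishable, and thinning is O(variants).

`run_channel()` chains the stages with child seeds derived deterministically
from one base seed (`derive_seed()`), so any run, replicate or droplet is
individually replayable; stages can be skipped or the chain stopped early
for single-stage study.

## Voting and the error profile

Reads are combined per reference by positional plurality (`vote()`). Only
reads of exactly the reference length enter the tally: positional voting is
ill-defined across lengths, so indel-carrying reads are excluded under the
default `strict` mode (a `length` mode voting at the plurality read length
exists but is off by default). A reference with no qualifying reads is
LOST. Ties break by the fixed order A < C < G < T — arbitrary, but
deterministic. One consequence of the strict rule worth knowing: a
reference whose few surviving molecules all carry an indel is counted as
lost even though reads exist; with deletion-leaning synthesis rates this
contributes a visible share of `N_l` at low sampling ratios.

`summarize_run()` returns the lost count $N_l$, the histogram $N_e(i)$ of
references with exactly $i$ voting errors (the partition
$\sum_i N_e(i) + N_l = M$ is asserted on every run), the byte-error
histogram (4 nt = 1 byte under the 2-bit code; a byte is erroneous if any
of its bases is), per-stage copy-number snapshots and the mean depth.

## Redundancy design

With payload $L_d$ bytes per sequence, $N$ data chunks, fountain decoding
overhead $\beta$, and the simulated profile $(N_l, N_e)$, the information
density at RS capacity $k$ (i.e. $L_{RS} = 2k$ parity bytes correcting
$\lfloor L_{RS}/2\rfloor = k$ byte errors) is

$$D(k) = \frac{L_d}{L_d + 2k}\cdot
  \frac{N}{(1+\beta)N + N_l + \sum_{i > k} N_e(i)},$$

and `choose_rs_length()` returns $L_{RS} = 2\,\mathrm{argmax}_k D(k)$
(smallest $k$ on ties). Two conventions required a decision:

* **Tail index.** The capacity rule discards a sequence only when its byte
  errors *exceed* $k$; a printed-form variant that discards already at
  exactly $k$ is available as `tail = "printed"`, but the capacity rule is
  the default because discarding correctable sequences is inconsistent
  with the stated RS capacity.
* **Scale.** All terms of the across-sequence factor must be commensurate
  with $N$: droplets needed are counted per $N$ chunks, so `error_profile()`
  rescales the measured $N_l$ and $N_e$ by `n_chunks / pool_size`, i.e.
  losses enter as per-sequence *rates* times $N$. This matters here because
  the test pool (2000 strands) is deliberately much larger than the chunk
  count ($N = 461$); without rescaling, the density would depend on that
  arbitrary ratio.

The failure probability at fountain overhead $\alpha$ follows from two
fitted laws. The total lost count $N_{tl}$ (lost plus RS-uncorrectable) over
replicates is fitted as Poisson — many rare independent losses — with the
rate rescaled per overhead as $\lambda = p_{tl}(1+\alpha)N$. The droplets
needed for decoding, $(1+\beta)M$, measured by feeding droplets one by one
into the peeling decoder, is right-skewed and fitted as a Gumbel
location–scale family by maximum likelihood (an Anderson–Darling statistic
is attached; on skewed synthetic data the Gumbel fit beats a normal one
under that statistic, which is the package's model-comparison test). The
permitted lost count $J = (1+\alpha)M - D$ is the reflection of the
droplets-needed variable; its pmf is obtained by half-integer
discretization, truncated at the $1-10^{-6}$ quantile and renormalized,
with the mass of $J < 0$ counted as certain failure. Then

$$p_f(\alpha) = P(J < 0) + \sum_{j \ge 0} f_J(j)\, P(N_{tl} > j).$$

Failure occurs when more sequences are lost than the code permits; this
"exceedance" form is monotone non-increasing in $\alpha$ (asserted along
every scan), which is what makes an acceptable $\alpha$ range well-defined.
`choose_alpha()` scans a grid and returns the contiguous range meeting the
target success probability.

## The fountain fixture

All inputs are generated in code: `generate_file()` produces seeded
pseudo-random bytes (9 KB in the shipped experiments), `lt_encode()` splits
them into $M$ 20-byte chunks and emits droplets whose degree follows a
robust soliton law and whose member set is reproducible from the droplet's
own 32-bit seed. `droplets_to_dna()` lays out each droplet as
`4-byte seed | 20-byte payload | L_RS parity bytes` at 2 bits/base
(A=00, C=01, G=10, T=11), giving the 104 nt strands used throughout. The
parity bytes are an interleaved XOR fold — *placeholder* check bytes, since
RS correction is modeled by capacity counting (`rs_recoverable()`), which is
exactly the granularity the density and failure expressions need; no
finite-field decoding is performed.

Decoding is peeling-only (belief propagation), the standard Luby-transform
decoder; `lt_min_droplets()` feeds droplets one at a time and reports the
count at which all chunks resolve, one sample of $(1+\beta)M$. Two
consequences are documented deliberately:

* Peeling needs noticeably more droplets than an inactivation/Gaussian
  elimination decoder. At $M = 461$ the observed overhead is
  $\beta \approx 0.17$ with a heavy right tail — an intrinsic property of
  peeling at this scale, not a tuning failure.
* The soliton parameters default to $(c, \delta) = (0.03, 0.3)$, chosen by
  a design-time scan as the setting minimizing the *high-reliability*
  overhead (mean plus upper quantile) at the $M \approx 500$ scale used
  here. Very small $c$ with large $\delta$ makes $R \le 1$ (no spike), and
  peeling then stalls; such settings are rejected with a diagnostic rather
  than silently producing enormous overheads.

## What the generator does and does not emulate

The synthetic channel reproduces: uneven initial copy numbers, persistent
per-sequence PCR bias, stochastic decay, loss concentrated in the sampling
bottleneck, coverage skew inherited by sequencing, and flat per-base error
rates per stage. It does not emulate sequence-context effects (homopolymer
or GC-dependent rates, the main omission for Nanopore data), PCR chimeras,
primer-site effects, strand orientation, or clustering ambiguity (reads
stay linked to their true reference, as the model's output contract
specifies). Passing tests therefore validate the model's internal
consistency and its stated distributional laws — not that any specific
wet-lab platform matches the default rates.

## Numerical choices and degenerate inputs

* Counts are doubles throughout (PCR exceeds integer range); a configurable
  ceiling (default $10^{12}$) guards overflow with a warning.
* Edit-script ties in `seq_diff()` resolve substitution > deletion >
  insertion, leftmost-first, so scripts are canonical and reproducible.
* Degenerate droplets-needed samples (zero variance) fall back to a point
  mass with a warning instead of a singular Gumbel fit.
* The truncation bound `t_max` of the failure sum defaults to the
  $1-10^{-6}$ quantile of the permitted-lost law; a residual above $10^{-4}$
  triggers a warning carrying the truncation mass.
* Problem sizes in the shipped tests were chosen to exercise the full study
  conditions where it matters (ten replicates of the 2000-strand channel,
  ten fountain decodings at $M=461$) and reduced sizes elsewhere (e.g.
  skewness checks at $M = 200$ over 120 decodings), with seeds fixed
  throughout.

## Known limitations

* Flat per-base rates only; no per-position or context-dependent profiles.
* RS behavior is capacity counting; miscorrection below capacity and
  decoder failure modes are not modeled.
* The peeling decoder's overhead at small $M$ dominates the feasible
  fountain overhead $\alpha$; designs relying on $\beta \lesssim 0.1$ at
  $M \approx 500$ require an elimination-capable decoder outside this
  package's scope.
* Voting excludes indel reads by design; consensus recovery of references
  dominated by indel-carrying molecules would require alignment-based
  consensus (out of scope).

## A compact worked run

```{r worked, eval = FALSE}
file <- generate_file(9216, seed = 42)
droplets <- lt_encode(file, chunk_size = 20, n_droplets = 2000, seed = 42)
refs <- droplets_to_dna(droplets, L_RS = 2)

run <- run_channel(refs, channel_config(), seed = 7)
s <- summarize_run(run)
s

needed <- lt_needed_samples(file, n = 10, base_seed = 43)
plan <- redundancy_plan(list(s), needed, n_chunks = attr(droplets, "M"),
                        payload_bytes = 20)
plan
autoplot(plan)
```

The chunk is not evaluated when building this vignette (a full run takes
about a minute); the README shows a complete run with its actual printed
output.
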