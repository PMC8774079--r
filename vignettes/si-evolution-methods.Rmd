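---
title: "Models and methods for S-RNase self-incompatibility evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for S-RNase self-incompatibility evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slocusevo)
```

# The biological problem

Type-1 gametophytic self-incompatibility (SI) is built on an S-locus that
couples a pistil-expressed cytotoxic S-RNase to a cluster of
pollen-expressed S-locus F-box (SLF) genes. Under collaborative non-self
recognition, the SLFs of one S-haplotype jointly detoxify the S-RNases of
*other* haplotypes but never their own, so self pollen is rejected and
cross pollen accepted. `slocusevo` implements the quantitative machinery
around four questions about this system: how specific individual SLFs
are (transgenic competitive-interaction genetics), how probable
detoxification must be for the system to function (closed-form
probability models), how the S-locus and its degenerate duplicates look
in genomes (locus annotation), and how SI has been lost and regained
across flowering-plant history (route classification and ancestral-state
reconstruction).

# Pollination genetics and specificity inference

A haploid pollen grain with S-allele $s$ growing through a style with
S-RNases $\{a, b\}$ succeeds iff both RNases are detoxified. The
endogenous repertoire of $s$ covers every nonself allele (the complete
collaborative network within a species — deviations can be declared
explicitly per haplotype) and never $s$ itself; a transgene adds a fixed
target set. Introducing an SLF transgene whose targets include one of the
plant's own S-RNases therefore breaks down SI for exactly the pollen class
carrying the matching S-allele: this is competitive interaction.

For a heterozygous $S_3S_{3L}$ parent self-pollinated with a hemizygous
single-locus transgene, `predict_progeny()` enumerates the four pollen
classes ($S_3$/$S_{3L}$ × with/without transgene, each ¼ under independent
segregation), keeps the compatible ones, renormalizes, and crosses them
with the maternal alleles:

```{r progeny}
predict_progeny(c("S3", "S3L"), detox_spec("tg", "S3L"))
predict_progeny(c("S3", "S3L"), detox_spec("tg", c("S3", "S3L")))
```

A transgene detoxifying only $S_{3L}$ yields no $S_3S_3$ progeny and a
1:1 ratio of the other two genotypes; one detoxifying both gives the
Mendelian ¼:½:¼. `infer_specificity()` inverts this: among the three
non-empty target subsets it selects the maximum-multinomial-likelihood
model and attaches an exact multinomial goodness-of-fit p-value. Two
design choices matter here:

* **Ties break toward the smaller target set** (parsimony): a larger
  target set never fits strictly better when the observed classes are a
  subset of its support, so the minimal adequate specificity is reported.
* **The exact p-value** sums the probabilities of all outcomes no more
  probable than the observed table — full enumeration of compositions for
  totals ≤ 200 (a 21-seed family has 253 outcomes), Monte Carlo with a
  fixed internal seed beyond that. No installed package offers an exact
  multinomial test, so the enumeration is implemented here and checked
  against the exact binomial test in the two-class case, where the two
  definitions coincide.

The model assumes zero transgene escapes (every self-progeny carries the
transgene, as observed), presence/absence of a single segregating
transgene locus unlinked to the S-locus, and ignores copy-number
variation — all the downstream inferences use only which genotype classes
appear and in what ratio.

# Detoxification probability closed forms

With $n$ SLF types each independently detoxifying a given S-RNase with
per-pair probability $P_R$, a pollen grain detoxifies that RNase with

$$P_n = 1 - (1 - P_R)^n,$$

and is accepted by a heterozygous style (two RNases, both required) with
probability $P_n^2$. `estimate_p_r()` wraps the exact binomial machinery
(point estimate, Clopper–Pearson interval — chosen over Wald because the
trial counts are small), and `aggregate_specificity_calls()` turns a
collection of per-transgene target sets into the success/trial counts
that feed it. The packaged cross-taxon calls aggregate to 22 detoxified
pairs in 26, giving $\hat P_R = 0.846$, single-SLF style acceptance
$0.85^2 \approx 72\%$, two-SLF acceptance $\approx 96\%$, versus only
$25\%$ at the within-species value $P_R = 0.5$ — the quantitative core of
the argument that the ancestral single-SLF system needed a broad
detoxification range to be viable. Percentages are reported rounded
half-up to integer percent; internal values stay unrounded (squaring the
rounded 0.98 or the unrounded 0.9775 lands on the same integer).

One published value is deliberately not reproduced: a χ² statistic of
7.38 (P = 0.0066) quoted for the 22/26-versus-5/26 contrast. The standard
1-df goodness-of-fit statistic for that contrast is 71.56, and for a
0.5 null it is 12.46; no standard construction we are aware of yields
7.38 from these counts. `goodness_of_fit()` computes the standard test
(no continuity correction) and always emits a companion exact binomial
p-value, since an expected count of 5 is borderline for the χ²
approximation. The conclusion (the cross-taxon rate is decisively higher
than the within-species expectation) is unchanged under every variant.

`simulate_acceptance()` and `population_cross_compatibility()` provide
two independent stochastic checks of the closed forms: per-pair Bernoulli
simulation at the SLF level, and exact enumeration of pollen ×
heterozygous-style combinations over random detoxification matrices,
which converges to $P_R^2$.

# Type-1 locus annotation

Gene classification (which genes are T2 RNases of Class I/II/III, which
F-boxes fall in the SLF subfamily) is an *input*; homology search is out
of scope. The annotation rules are:

* **Scaffold filter** — genes on scaffolds shorter than 1 Mb (the
  smallest linkage region resolvable for these loci) are dropped;
  boundary-inclusive.
* **Pseudogene detection** — a CDS with an in-frame stop codon strictly
  before its final codon, in frame 0 as annotated (no 6-frame scan).
  Codons containing N are never stops; a trailing partial codon is
  truncated with a warning.
* **Linkage window** — an F-box gene is linked to an RNase anchor when
  the gap between their gene spans (0 if overlapping) is at most 3 Mb,
  boundary-inclusive, strand ignored. Span gap rather than midpoint
  distance is used because "within 3 Mb" most naturally bounds the
  separating interval; the two conventions differ only for very long
  genes. The window is anchored per-RNase; anchors sharing a linked
  F-box merge into one locus, which keeps each F-box in at most one
  locus without requiring an F-box-to-F-box chaining rule.
* **Typing** — Class III RNase + ≥1 SLF-family F-box → type-1 S-like
  locus; Class I/II RNase + ≥1 F-box → Class I/II linked locus; an RNase
  with no linked F-box, or a Class III RNase linked only to non-SLF
  F-boxes, → orphan RNase (the "S-like RNase with no linked SLFs" trait).
* **Activity** — a locus is active iff it retains ≥1 functional RNase
  and ≥1 functional SLF; "functional" means non-pseudogene and, when
  expression data are supplied, at least 1 TPM in the relevant tissue
  (style for RNases, stamen for F-boxes). The 1-TPM threshold is
  configurable: the source observations report "low expression" without
  a numeric cutoff, and 1 TPM is the conventional detected/not-detected
  line.
* **S-locus promotion** — a genome scan alone cannot distinguish the
  functional S-locus from its S-like duplicates, so when the species
  shows type-1 SI the locus with the most intact SLFs is promoted (ties:
  larger span, then scaffold name). Rationale: the functional S-locus
  carries the large SLF cluster (megabase-scale versus tens of kb for
  degenerate duplicates).

Coordinates are 0-based half-open internally; GFF3 I/O converts at the
boundary. One observable limitation: because loci are anchored on RNases,
an S-RNase *deletion* (SLF cluster with no RNase) is invisible to
`call_loci()`; `summarize_genome()` therefore accepts the S-RNase status
as an explicit argument for species where it is known externally.

# Loss and regain routes

SI can be lost through duplication of the S-locus (R1 — the two resident
haplotypes detoxify each other), deletion/inactivation of the S-RNase
(R2), or deletion of the whole locus (R3); it can be regained by
silencing the duplicates (a), deleting them (b), reactivating the S-RNase
(c), or evolving a new SI system (d). `infer_routes()` encodes the
published per-species reasoning as an ordered decision table over (SI
phenotype, WGD count, type-1 locus inventory, S-RNase status); the first
matching rule wins, mirroring the narrative precedence, and anything
unmatched is returned as UNCLASSIFIED rather than an error. WGD/WGT
events are inputs from the literature, not inferred. Route c is
representable but never emitted — no analyzed species requires it.

Two documented judgment calls: (1) self-compatible species retaining
duplicate *active* type-1 loci are classified as loss-by-duplication
(R1), although the source narrative labels them Route 2 — by the
framework's own definitions retained duplication is Route 1, and the
packaged fixture records the narrative label alongside; (2) species
described only tentatively as having one degenerated duplicate are
carried with a `provisional` flag. A GSI species with two type-1 loci is
genuinely ambiguous between regain routes a and d; the call records both
alternatives.

# Ancestral-state reconstruction

SI trait evolution is modeled as a K-state continuous-time Markov chain
with the F81-type kernel

$$P_{ij}(t) = e^{-\mu\rho t}\,[i=j] + (1 - e^{-\mu\rho t})\,\pi_j,
\qquad \mu = \frac{1}{1 - \sum_k \pi_k^2},$$

on a rooted dated tree (branch lengths in Myr; multifurcations handled
natively; missing tips contribute all-ones partials). The likelihood uses
Felsenstein pruning with per-node rescaling; marginal posteriors use the
standard up/down (outside) algorithm; both are verified against explicit
enumeration over all internal-node assignments on trees of up to 6
leaves and 8 states, to 1e-10 relative error.

Free parameters and their estimation:

* **π** — observed tip frequencies with a pseudocount of 1 per state
  (default), or joint maximum likelihood on the simplex. The pseudocount
  keeps unobserved states reachable, which matters for an 8-state
  alphabet scored on ~20 families.
* **ρ** — a single rate scaling, estimated by bounded 1-D maximum
  likelihood (golden-section search, on the log-rate scale so the
  saturation plateau does not trap the search) on
  $[10^{-6}/h,\ 10^{3}/h]$ with $h$ the tree height; the bounds bracket
  everything from effectively frozen to fully saturated. With all tips identical the rate is
  unidentifiable and is returned at the lower bound with a warning.
* **State selection** — alongside full posteriors and MAP states
  (ties broken by alphabet order, deterministically), a threshold-fraction
  rule keeps every state with posterior ≥ ½ × the node maximum. This is a
  deliberate simplification of the published Brier-score subset selection;
  the full posteriors are always emitted so downstream users are not
  bound by it.

The default 8-trait alphabet (`si_trait_alphabet()`) codes genomic
S-locus configurations from "Class I/II RNases with no linked F-boxes"
through "type-1 linked", the type-2/3/4 systems, down to "absent". A
single 8-state character is the default encoding; per-trait binary
characters can be run by recoding the tip table, since nothing in the
machinery is specific to the 8-state alphabet. The packaged family tree
and trait table are *synthetic stand-ins* (plausible topology and dates,
not a published tree) used for demonstration and determinism tests only;
per-node posterior values on real data are not claimed.

# Synthetic data and what passing tests mean

All recovery tests run on generator output with saved ground truth:

* `gen_genome()` plants type-1 loci (an RNase inside a cluster of SLFs),
  Class I/II loci, orphan RNases and decoy F-box clusters on scaffolds
  with every pair of planted blocks separated by more than the linkage
  window, injects in-frame premature stops at a configurable per-gene
  rate, and emits stop-free CDS otherwise. Defaults: 3 scaffolds, 4
  type-1 loci, 3–10 SLFs per locus, 15% pseudogene rate, 0.9–3 kb CDS.
  The SLF count is deliberately below the real 9–37 range: planted loci
  must sit > 3 Mb apart on each scaffold, and no annotation rule is
  sensitive to cluster size beyond one.
* `gen_detox_matrix()`, `gen_progeny()` and `gen_trait_history()` sample
  exactly the models the analysis assumes (independent Bernoulli pairs,
  multinomial progeny, forward F81 simulation).
* One global seed fans out to fixed per-component child seeds, so every
  dataset is independently reproducible.

Because the generators match the model assumptions exactly, passing
recovery tests demonstrates internal correctness — that annotation,
specificity inference and reconstruction invert their own generative
models — not robustness to real-genome complications (fragmented
assemblies, mis-classified genes, introns, expression noise, tree error).
Problem sizes were chosen as the smallest that make the statistical
checks sharp: 100 random trees (≤ 6 leaves, ≤ 8 states) for the
enumeration oracle, 100 replicates of 50-tip trait histories for
parameter/state recovery, 1,000 simulated progeny families of 20 for
specificity recovery, 100 synthetic genomes for locus recovery, and 10⁵
Monte-Carlo pollinations per parameter point.

# Known limitations

* Endogenous SLF repertoires default to complete nonself coverage;
  partial networks must be supplied explicitly.
* No protein-level SLF–S-RNase modelling, no tetraploid genetics, no
  fitness dynamics of detoxification-range narrowing.
* Locus annotation cannot see S-RNase deletions (RNase-anchored) and
  does not search for type-2/3/4 loci.
* The route table covers the phenotype × inventory combinations observed
  in the 22-species compilation; configurations outside it are
  UNCLASSIFIED by design.
* Only the F81 kernel is implemented; no model comparison, joint
  reconstruction, or tree/date inference.
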