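---
title: "Modeling modes of thought in labeled Hilbert spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling modes of thought in labeled Hilbert spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantmind)
```

## The model

quantmind represents a mental entity — a concept, a percept, a belief about
the world — as a superposition state $|\Psi\rangle = \sum_i a_i
|\phi_i\rangle$ over a *labeled orthonormal basis*. Each label names one
definite interpretation, feature, or instance; the complex amplitude $a_i$
encodes how strongly that interpretation contributes, and $|a_i|^2$ is the
Born probability that a question asked in the label basis resolves to it.
This is the standard quantum-cognition modeling idiom (Aerts & Gabora 2005;
Busemeyer & Bruza 2012): no claim is made that brains are quantum systems,
only that the algebra of states, operators, and projective measurement
captures contextuality and ambiguity better than a fixed sample space.

Three assumptions are baked into the container types and are worth stating
plainly:

* **Orthonormal features.** Basis labels are treated as mutually exclusive
  and self-typical ($\langle a|a\rangle = 1$). When features are *not*
  mutually exclusive (a blanket is warm *and* rectangular), projections onto
  feature subsets are approximations; the package applies them exactly as
  written and leaves the non-orthogonal generalization out of scope.
* **Normalizable amplitudes.** Every operator in the package (elaboration,
  context projection) is non-unitary, so outputs are renormalized by
  default. `renormalize = FALSE` exposes the raw images for display, since
  the intermediate forms of the formalism are conventionally written
  unnormalized.
* **Label-basis measurement.** `collapse()` measures in the state's own
  label basis. Arbitrary Hermitian-observable eigendecomposition is not
  exposed: every question in the modeled case studies is a projector onto
  interpretation labels, and restricting measurement to that case keeps the
  measurement contract simple and exactly testable.

### Operators for conceptual change

Two operations model the arrival of new information. When the information
$|A\rangle$ overlaps the current state, *elaboration* applies $\hat U_A =
\hat I + |A\rangle\langle A|$, adding the new information weighted by its
relatedness $\langle A|\Psi\rangle$. When the overlap is negligible
(operationalized as $|\langle A|\Psi\rangle| < 0.05$ — the formalism gives
no cutoff, so the package makes the trigger explicit and configurable), the
fact is acquired but not integrated, and the joint representation is the
tensor product $|\Psi\rangle \otimes |A\rangle$. Tensor composites answer
single-factor questions ($\hat O \otimes \hat I$) with a definite
distribution, while a cross-factor question $\hat O_s \otimes \hat O_d$ can
force contradictory answers; `joint_question()` flags this as an
unanswerable (incompatible) question when the declared contradictory label
pairs carry at least half the marginal product mass. The 0.5 default
threshold reads "majority of the answer mass is contradictory"; it is a
package convention, not a fitted value.

Separability of a joint state is decided by the Schmidt (rank-one)
criterion: the joint amplitude matrix is separable iff its second singular
value, normalized by the total Schmidt weight, is at most `tol` (default
1e-6). This is the operational form of $a_{ij} = a_i^A a_j^B$ and is robust
to global phase. The default tolerance sits far above double-precision
noise (~1e-15 after an SVD) and far below any psychologically meaningful
entanglement, so the verdict is stable on both sides.

Contexts and questions are projectors $\hat C = \sum_{i \in L}
|i\rangle\langle i|$ onto goal-relevant labels, optionally with positive
weights when features relate to the concept by degree. Applying a context
trims every irrelevant component; a state orthogonal to the context
subspace raises an annihilation error rather than returning a zero vector.

### The three measures

For a fixed environment — an observation set $\{|O_n\rangle\}$, a context,
and a divergence observable $\hat B$ — the package computes three numbers
per state:

* **Abstractness** $\gamma_A$. The expectation of the observation projector
  $\hat\alpha = \sum_n |O_n\rangle\langle O_n|$ measures groundedness in
  direct experience. The package *reports* abstractness as
  $1 - \langle\hat\alpha\rangle$, so that a state with no observational
  support scores 1 and a purely perceptual state scores 0; the raw
  expectation is available as `observation_mass()`. This sign convention
  makes the case-study transitions read correctly (forming an abstraction
  moves *away* from observations, so abstractness rises) and keeps the
  identity `abstractness + observation_mass = 1` exact.
* **Divergence** $\gamma_D$. The standard deviation
  $\sqrt{\langle\hat B^2\rangle - \langle\hat B\rangle^2}$ of a
  salient-feature observable: how widely the thought spreads over what
  could come to mind next. In projector mode ($\hat B$ a projector onto a
  *proper* subset of salient labels) this reduces exactly to
  $\sqrt{p(1-p)}$, which is convenient for testing but capped at 1/2; the
  projector onto a complete basis is the identity and measures nothing, so
  the constructor rejects it. Weighted mode assigns each label a real
  eigenvalue and measures spread over that grading, which is the mode the
  Earth case study uses.
* **Context-specificity** $\gamma_C$. The expectation
  $\langle\psi|\hat C|\psi\rangle$ of the context projector, exactly as the
  formalism defines it: the fraction of the thought already inside the
  context subspace. Note the gloss "degree to which a context changes
  thought" describes the *complement*; the package implements the formula
  as printed and exposes `context_shift()` ($1 - \gamma_C$) separately
  rather than guessing intent.

The three measures are mathematically independent in the sense that each can
be moved while the other two stay fixed: redistributing mass among labels
that agree on observation/salience/context membership moves exactly one
expectation. The test suite constructs such families explicitly and checks
variation of at least 0.3 on the moving axis against drift below $10^{-9}$
on the pinned axes.

For a two-factor composite, the profile is measured on the first factor via
$\hat O \otimes \hat I$: the first factor is the operative mental
representation, and knowledge held unintegrated in the second factor does
not alter the mode of thought until it is integrated. This choice is what
makes the dual-model stage of the case study read correctly — acquiring an
isolated fact leaves abstractness and divergence essentially where they
were.

### Arrow tables

`delta_profile()` quantizes profile differences into the qualitative arrows
(↑, ↓, −) used in conceptual-change tables, with a default tolerance of
0.05 per dimension. The tolerance reflects that the case-study arrows are
qualitative claims; 0.05 is large enough to absorb the incidental drift a
renormalizing operator causes on untouched dimensions and small enough that
every claimed change must be a real movement.

## The Earth-shape case study

`child_i_fixture()` and `child_j_fixture()` replay two children's paths
from no model of the Earth's shape to a spherical-Earth model, following a
classic developmental study of children's mental models (Vosniadou & Brewer
1992, *Cognitive Psychology* 24, 535–585; the packaged
`earth_model_frequencies.csv` tabulates the mental-model counts by school
grade). Child i passes through Flat → Disk → Dual (an unintegrated
flat-plus-sphere composite) → Sphere; child j through Flat → Hollow and a
chain of planet-related elaborations that culminate in projecting the
PLANET concept onto the EARTH concept, then grounding Mars in pretend play
with a red balloon.

Both children share one twelve-feature basis (six direct observations, six
abstractions), one observation set, one pretend-play context, and one
weighted divergence observable whose eigenvalues grade each feature by its
*remoteness from the core of the earth concept*. Remoteness is
concept-relative, not a synonym of abstractness: flat ground underfoot is a
core percept (eigenvalue 0) and "flat" is a near-core abstraction of it,
while a red balloon is a concrete object yet a remote associate of the
Earth — it only enters earth-related thought through the pretend-play
analogy. Divergent thought is precisely thought that activates such remote
associates, so spread over this grading is the divergence measure.

The case study states qualitative claims: the direction each of
$\gamma_A, \gamma_D, \gamma_C$ moves at each of 5 + 9 steps. The numeric
amplitudes in the fixtures are package constants, chosen once so that every
recorded arrow is reproduced under the default 0.05 tolerance and then
frozen; regression tests pin all 42 arrow cells. The arrows, not the
magnitudes, are the modeled content — no magnitude in the fixture should be
read as an empirical estimate.

Three fixture decisions deserve a note:

* The hollow-earth step for child j is recorded as a *decrease* in
  divergence, and the fixture follows the record as printed (the new hollow
  component is anchored on core ground-and-sky features, so spread
  contracts even though the step is representational redescription).
* The pretend-play step appears in both trajectories (social learning for
  child i, representational redescription for child j). For child i it is a
  low-weight elaboration that changes no measure beyond tolerance; for
  child j it is a genuine context projection onto {red, balloon, mars},
  which is why it is the only step in either table that moves
  context-specificity. Because the context contains the concrete balloon
  and red observations, the step also *decreases* abstractness — pretend
  play turns the abstract planet into something a child can hold.
* The two trajectories share their start state, and both end in a
  Sphere-tagged model whose reported abstractness exceeds the initial Flat
  model's. Their *final recorded states* cannot have matching profiles,
  since child j's last state is a transient, fully context-bound
  pretend-play thought ($\gamma_C = 1$) while child i's is not. The package
  therefore compares the two children at the point where the spherical
  model forms (child i after step 4, child j after step 6), treating the
  pretend-play projection as a momentary thought rather than a revision of
  the stored model.

## The synthetic generator

`random_concept()`, `random_context()`, and `random_trajectory()` generate
the structure the formalism assumes — a feature basis, an observation
subset, salience-weighted amplitudes — with controlled statistics, so every
operation is property-testable without external data. Squared amplitudes
(not amplitudes) are symmetric-Dirichlet distributed via normalized gamma
draws: concentration well below 1 yields peaked, convergent-like states and
large concentration yields near-uniform, divergent-like states, while
keeping the real-weight reading of typicality. Phases are zero by default
with an option for uniform random phases. Defaults (12 features, 6
observations, concentration 1, context size 3, 6 steps) mirror the scale of
the Earth-shape basis: big enough that compaction, context projection, and
spread measures all have room to act, small enough that a thousand draws
cost nothing. Every generator call is a pure function of its config,
including the seed.

What the generator does *not* emulate: human-plausible feature norms,
correlated feature semantics, or amplitudes fitted to behavioral data.
Passing property tests on generated concepts demonstrates the algebra's
invariants (normalization, projector idempotence, Born frequencies, range
bounds), not empirical adequacy of any particular concept model.

## Numerical choices

* Normalization and hermiticity checks use a 1e-9 tolerance: loose enough
  for accumulated double-precision error on 12-dimensional chains of
  operations, tight enough to catch any real modeling mistake.
* Salience orderings break ties lexicographically by label, so compact
  forms are deterministic.
* `compact_form()` compares cumulative mass against the threshold with a
  1e-12 slack so that thresholds of exactly 1.0 (or sums that should be
  exactly attained) are not defeated by rounding.
* Variances are clamped at zero when they fall within `[-1e-12, 0)` from
  rounding; anything more negative signals a broken operator.
* Born sampling takes one explicit integer seed per call and restores the
  caller's RNG state afterwards (via `withr`), so stochastic tests are
  reproducible and the package never leaks RNG state.

## Limitations

* Mixed states, density matrices, Fock-space composites, and continuous
  Hilbert spaces are out of scope; composites are plain two-factor tensor
  products.
* How entanglement would *arise* dynamically between mental
  representations is not modeled: the package represents and tests
  entangled joint amplitudes but only constructs separable ones itself.
* Cross-concept inner products default to literal label identity; real
  semantic alignment between bases must be supplied as an explicit
  correspondence table.
* The three measures are not claimed to exhaust the modes of thought, and
  nothing here fits them to human data.

## References

* Aerts, D. & Gabora, L. (2005). A theory of concepts and their
  combinations. *Kybernetes* 34, 167–221.
* Busemeyer, J. & Bruza, P. (2012). *Quantum Models of Cognition and
  Decision*. Cambridge University Press.
* Vosniadou, S. & Brewer, W. F. (1992). Mental models of the earth: A study
  of conceptual change in childhood. *Cognitive Psychology* 24, 535–585.
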