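---
title: "Turning Machines: model, dynamics and shape compilers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turning Machines: model, dynamics and shape compilers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnfold)
```

## The model

A Turning Machine is a chain of `n` monomers on the triangular grid.
Positions are integer axial pairs with basis `x = (1,0)`, `y = (0,1)` and
the derived third axis `w = (-1,1)`; the six unit directions are indexed
0..5 anticlockwise from east, so index arithmetic modulo 6 is rotation by
multiples of π/3. Monomer `i` points at monomer `i+1`; the last monomer
points nowhere. Each monomer carries an integer state, its remaining
turning number: positive states turn anticlockwise and decrement, negative
states turn clockwise and increment, state 0 is inert.

A rule application at monomer `i` rotates its direction by ±π/3 and
rigidly translates all later monomers (its *head*) by the unit vector two
steps around the direction tuple from the monomer's current direction
(anticlockwise two steps for positive states, clockwise for negative).
The move is *blocked* — not applicable — when the translated head would
overlap the *tail* (monomers up to and including `i`): chains must stay
self-avoiding at all times. A configuration with nonzero states but no
applicable rule anywhere is *permanently blocked*. A program *folds* (or
"computes") its target configuration when every maximal trajectory ends in
the all-zero-state configuration; since each rule application removes
exactly one unit from the total remaining work `sum(|s|)`, all
trajectories are finite and foldability is exactly "the target is
reachable and no reachable configuration is permanently blocked".

Two conventions deserve note, both chosen here and applied consistently:

* **The last monomer.** It has no direction, so a rule applied to it is a
  pure counter decrement with an empty head; we allow it (it is never
  blocked). Consequently a final configuration requires its counter, too,
  to reach zero.
* **Mixed signs.** The engine takes the turning sense per monomer from the
  sign of its initial state, so programs mixing anticlockwise and
  clockwise monomers run fine; the strong foldability guarantees below are
  stated for the regimes where they are proven, and `explore()` answers
  other instances per-instance.

## Canonical encoding

A configuration of a fixed program is represented by its move-count vector
Δs: entry `i` counts rule applications received by monomer `i`, bounded by
`|s0[i]|`. Geometry is always derived: monomer `i`'s direction is its
initial direction rotated by `sign(s0[i]) * Δs[i]`, and positions are
prefix sums from the origin (the first monomer never moves). This keeps
the state space discrete and hashable — reachability analysis enumerates
integer vectors, never floating-point geometry — and reconstruction
validates self-avoidance exactly. The `turn_angle` at an interior monomer
is the signed difference of consecutive direction indices folded into
−2..2 (a value of ±3 would mean a doubled-back, self-intersecting chain),
and on every reachable configuration the sum of turn angles between two
monomers equals their move-count difference; the test suite checks this
identity exhaustively on small machines, along with the half-plane
invariant for states ≤ 3 and the bound `|Δs[i] - Δs[i+1]| <= 2` for
uniformly-oriented machines. That adjacent-gap bound concerns pairs of
monomers that both have directions; the pair involving the last monomer is
excluded (its counter is frozen at 0 in line machines, so the final gap
trivially reaches `s`).

## Continuous-time dynamics

Every applicable move carries an independent rate-1 exponential clock: a
configuration with `k` applicable moves holds for an Exp(k) time and then
applies one uniformly. `sample_trajectory()` simulates this by thinning:
proposals arrive at the total rate of *nonzero-state* monomers, a proposal
on a blocked monomer is a null event, and memorylessness guarantees the
holding-time law in each configuration is exact. This makes the per-event
cost proportional to one blocking test instead of a full applicability
scan; permanent blocking is detected by a full scan after a run of
rejected proposals (the scan does not perturb the law — it only decides
termination). Waiting times accumulated after the last real move are
discarded, so absorption times are exact. Each trajectory uses an RNG
stream derived from a master seed by counter, so runs are reproducible
singly and in batches.

`exact_expected_time()` avoids sampling entirely: the reachable space is a
DAG graded by total move count, so the first-step equations
`E[c] = (1 + Σ E[c']) / k(c)` solve in one backward sweep in topological
order. For machines that can block, the value returned is the expected
time to absorption (target or blocked) together with the probability of
reaching the target; the tests cross-check sampled means against exact
values at three standard errors, and against closed forms — a single-turn
line of `n` monomers is a race of `n-1` independent unit-rate clocks, so
its completion time has mean `H_{n-1}`, and the three-monomer double-turn
machine is the maximum of two Gamma(2,1) variables with mean 11/4.

## Reachability and foldability

`explore()` runs breadth-first search over move-count vectors from the
initial configuration, classifying terminal vectors as target or
permanently blocked. Witnesses are reported in BFS order, so the first is
a blocked configuration of minimal total moves; `want_path` additionally
returns a concrete move sequence reaching it, replayable with
`replay_moves()`. The default state cap (5e6 vectors) turns the verdict
into an explicit "unknown" (`truncated = TRUE`) rather than a guess.
Frontier deduplication keys on the exact integer vector; geometry is
recomputed per expansion, trading memory for speed.

At `n = 7` this machinery characterises line rotation exhaustively: the
machines with uniform states 1..5 fold on all of their reachable spaces
(64 to 6,140 configurations), while the state-6 machine — a full 2π
rotation — has 8,129 reachable configurations including two permanently
blocked coils, and smaller 2π machines (n ≤ 6) still fold. The blocking
probability under the CTMC is small (about 0.35% at n = 7), which is why
foldability needs model checking rather than simulation.

## Shape compilers

**Zig-zag paths.** A positive zig-zag path steps only in `+x, -x, +y, +w`
(a negative one mirrors through the x-axis). The compiler assigns each
monomer the number of π/3 turns from east to its folded direction —
`+x→0, +y→1, +w→2, -x→3`, or `+x→0, -w→-1, -y→-2, -x→-3` for the
clockwise mirror, the ordering that clockwise rotation from east visits.
All such programs fold on every trajectory, with states bounded by 3, and
the boustrophedon raster of the n×n square is the canonical instance.

**y-monotone shapes.** Every row of such a shape is one contiguous
segment. The traversal rasters rows alternately west→east and east→west,
extending each row sideways by exactly the points needed to meet the turn
into the adjacent row; connectivity of consecutive rows on the triangular
grid guarantees the extensions are contiguous and the row-to-row step is
always `+y`. Extension points are the folding error; each lies adjacent to
a perimeter point of the shape and no perimeter point absorbs two of them,
so the error is bounded by the perimeter length (checked on 100 random
fixtures, against both the shape's perimeter and the folding's). Thin
crosses show the bound is needed: they are y-monotone but have no
Hamiltonian path (verified exhaustively at arm length 2), so zero error is
impossible.

**Factor-2 scaled shapes.** For an xy-connected y-monotone shape with a
*yw-separator* — a chain of shape points from bottom row to top row moving
`+y` or `+w` each step, found by forward interval marking and leftmost
backtracking — the doubled shape folds with zero error. The compiler cuts
the doubled shape along a column pair `C'`/`C'' = C' + (1,0)` that is a
yw-chain splitting every row into non-empty left and right parts, then
traverses the left piece top-to-bottom (a negative zig-zag, clockwise
states) and the right piece bottom-to-top (positive states), joined along
the bottom row; the two lobes provably cannot block each other across the
cut. The cut candidate follows the separator geometry (y-parallel segments
split cells 2+2; w-parallel segments 1+3 or 3+1 according to which side
the shape continues on), followed by a feasibility pass — an interval
sweep over all yw-chain cuts — that repairs corner cases where the literal
case rules would produce an invalid chain. The pass also exposes a real
limitation: some shapes with a separator admit *no* valid cut at all
(narrow rows stacked along consecutive w-segments force the cut to drop
two columns in one row, e.g. rows `{0}, [-2,0], [-3,-2], [-4,-3]`);
`compile_scaled()` reports these as `NoValidCut`, and the
`separator_random` fixture generator guarantees cut feasibility by
construction, tracking the forward intervals while it samples rows.

**Spirals.** The k-turn 1-gap spiral is a union of nested almost-
rectangles with `8k^2 + 6k + 2` points and exactly two degree-1 points,
the inside start `(0,0)` and the outside start `(2k+1, -2k)`. Only two
families of programs can possibly fold it: inside-to-outside sequences
(base value ≡ 0 mod 6, arm runs of lengths 1, 2, ..., 4k+1 increasing by
2 at even and 1 at odd steps) and outside-to-inside sequences (base ≡ 3
mod 6, arm runs of lengths 4k+1 down to 1 decreasing by 1 at even and 2
at odd steps). Run lengths equal arm edge counts; the final monomer has no
direction and repeats the innermost value. Both canonical programs trace
the spiral exactly (checked for k ≤ 3 in both orientations), and changing
any single directed monomer's state by ±1 rotates that monomer's folded
direction, making the unique target either self-intersecting or a
different point set — the necessity probe verifies all such perturbations
fail.

## The spiral blocking scripts

For k ≥ 2 the spiral is nonetheless unfoldable: each of the six sign
cases of the canonical sequences has a reachable permanently blocked
configuration. `spiral_blocking_trajectory()` plays one deterministic
trajectory per case and then *verifies* the block by exhaustive
reachability from the end configuration (a configuration is itself a
fresh machine instance — the model is memoryless — so the continuation
space is explored directly): the target must be unreachable and the
designated monomers must never move again in any reachable continuation.

The scripts are built from the mechanism that makes each case fail. The
all-positive inside-out case folds its innermost coil first, creating a
pocket, then rolls the high-state tail prematurely into it (three-move
roll steps walking back along the chain) until the whole chain jams. The
mixed-sign cases exploit the contiguous zero-state run the canonical
sequence must contain: prescribed sweeps bring the flanking segments to
rest against it and the two sides then close like a pincer. The
all-negative outside-in case sweeps the outer arms into a C shape whose
remaining arm can only wrap clockwise into the blocked region. The
all-negative inside-out and all-positive outside-in cases fold the
outermost arms into place first; the innermost coil, which needs the most
turning, then wedges into a tight blocked cluster — the chain-level
reflection of the impossible 2π line rotation. Closing phases
intentionally run until no scripted move applies (the jam forming is the
result); prescribed phases are strict, and any rejection there raises
`ScriptInapplicable`. We verified during development that the tight inner
coil cannot be wound while the long tail stays straight — a bounded
exhaustive search over that subspace is empty — which is why every script
repositions tail material before or while the inner coil wedges. All six
cases verify at k = 2 and k = 3.

Whether the k = 1 spiral is foldable is left open here as an experiment:
`explore(spiral_program(1))` answers it per-instance within a state cap.

## Synthetic fixtures and what they show

`synthesize_shape()` generates the test families: squares, width-1
crosses, random y-monotone shapes (rows sampled as random segments with
triangular-grid adjacency between consecutive rows), separator-guaranteed
variants, and spirals. These exercise the geometry of the model — they are
not models of any physical polymer: passing tests demonstrate the
combinatorial claims (foldability verdicts, error bounds, timing laws)
under the model's idealised kinetics, and say nothing about real molecular
noise, flexible bonds or agitation, which are outside the model.

Problem sizes are chosen so that exhaustive checks stay exhaustive: full
reachability is used up to ~10^5 vectors (lines to n = 7–8, squares to
4×4, the smallest scaled instances), sampling takes over beyond that
(8×8 squares with 100 seeds, 300 seeds for a scaled fixture, 2000
trajectories per point for the logarithmic-growth check at n = 16, 64,
256, where the middle mean must sit within 10% of the outer means'
average since ln 64 is the midpoint of ln 16 and ln 256). Seeds are fixed
throughout; every randomised test is deterministic.

## Numerical and design choices

* Integer-only model arithmetic; the Cartesian projection
  `(x + y/2, y·√3/2)` exists only in renderers and plots.
* Enumeration order is increasing monomer index everywhere a deterministic
  order is needed; stochastic choice lives solely in the CTMC sampler.
* `explore()`'s cap yields NA verdicts, never guesses; witnesses are
  shortest-first.
* The line-rotation target is the ray at angle sπ/3 from the origin
  (direction index `s mod 6`), so the 2π target coincides with the initial
  line — consistently with the encoding, a target is just the
  configuration with every counter exhausted.
* `compile_scaled()` prefers the separator-derived cut and deviates only
  where the feasibility sweep requires it; ties resolve toward the
  separator value.

## Limitations

The engine answers foldability for mixed-sign programs only per instance;
no symmetry reduction is attempted in the search (a possible
optimisation); the scaled compiler covers scale factor 2 with the
yw-separator and cut-feasibility preconditions, not general scaling; and
the timing analysis reports expected absorption times — tail bounds and
variance analyses are out of scope.
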