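# turnfold

Turning Machines are a minimal model of algorithmic molecular robotics: a
chain of monomers sits on the triangular grid, each monomer carrying an
integer *turning number* `s`. Monomers fire asynchronously; a monomer in
positive state decrements it while turning anticlockwise by π/3, rigidly
dragging ("translating") every later monomer in the chain, and a negative
state turns clockwise. Volume exclusion applies: a move whose translated
head would overlap the rest of the chain is *blocked*. The chain starts as
an east-pointing line; programming it means nothing more than writing down
one integer per monomer. The scientific questions are which shapes the
chain folds into on *every* execution order (foldability), and how long
folding takes under the natural continuous-time Markov chain semantics
(every applicable move fires at rate 1).

`turnfold` is a simulation and verification toolkit for this model, for
researchers in molecular programming, self-assembly and reconfigurable
robotics:

* **Rule engine** — configurations are encoded canonically as per-monomer
  move-count vectors Δs (geometry is derived by prefix sums, all in
  integers); applicability, blocking, turn angles and folding error
  against a target shape.
* **Dynamics** — seeded CTMC trajectory sampling, completion-time
  statistics, and *exact* expected absorption times by a backward sweep
  over the reachable DAG (`E[c] = (1 + Σ E[c']) / k(c)`).
* **Reachability** — exhaustive breadth-first search over the reachable
  configuration space: a program "computes its target configuration" iff
  the all-zero-state target is reachable and no reachable configuration is
  permanently blocked; blocked witnesses are returned in shortest-first
  order.
* **Compilers** — line rotations `L(n,s)`, zig-zag paths (direction → state
  table `+x→0, +y→1, +w→2, -x→3` and its clockwise mirror), boustrophedon
  n×n squares, y-monotone shapes (error bounded by perimeter length),
  factor-2 scaled shapes with a yw-separator (zero error), and k-turn
  1-gap spirals with their canonical turning-number sequences and the six
  scripted blocking trajectories showing spirals are unfoldable for k ≥ 2.

Headline results the package reproduces at desk scale: a line of any
length can rotate by up to 5π/3 (states 1..5) on all trajectories, in
O(log n) expected time, but a full 2π rotation (state 6) permanently
blocks from 7 monomers on; squares and zig-zag paths fold with zero error;
spirals have a traversal yet are unfoldable.

## Worked example

```r
library(turnfold)

# 5*pi/3 line rotation of 7 monomers: foldable on every trajectory
explore(line_program(7, 5))
#> Reachability of 'L(7,5)': 6,140 reachable configurations
#>   target reachable: TRUE; permanently blocked witnesses: 0
#>   foldable on all trajectories: TRUE

# the 2*pi rotation is not: exhaustive search finds blocked witnesses
r6 <- explore(line_program(7, 6))
r6
#> Reachability of 'L(7,6)': 8,129 reachable configurations
#>   target reachable: TRUE; permanently blocked witnesses: 2
#>   foldable on all trajectories: FALSE
tm_configuration(line_program(7, 6), r6$blocked_witnesses[2, ])
#> Turning Machine configuration (7 monomers, program 'L(7,6)')
#>   moves : 0 2 3 4 5 6 0
#>   states: 6 4 3 2 1 0 0
#>   PERMANENTLY BLOCKED: nonzero states, no applicable rule

# single-turn lines complete in harmonic-number expected time
exact_expected_time(line_program(9, 1))$expected_time
#> [1] 2.717857        # = H_8 = 1 + 1/2 + ... + 1/8

# an 8x8 square folds with zero error, quickly
sq <- compile_zigzag(square_path(8))
completion_time_stats(sq, 200, seed = 1)
#> Completion over 200 trajectories: mean time 7.6333 (sd 1.5743),
#> mean steps 91.0, target fraction 1.000
```

The reachable-configuration counts are exhaustive enumerations of the
move-count vectors; the blocked witness above is the classic jammed
hexagonal coil (residual states 6,4,3,2,1,0,0) that stops the 2π rotation.
The mean of 91 steps equals the total turning work of the square program,
and every one of the 200 seeded trajectories reached the square exactly.

A thin command-line wrapper is installed at `inst/cli/tmfold.R` with
subcommands `simulate`, `verify`, `compile`, `shape` and `render` (SVG or
ASCII chain sketches); see `?cli_main`.

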