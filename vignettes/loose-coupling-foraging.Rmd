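---
title: "Modelling individual and collective foraging with loose coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individual and collective foraging with loose coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`swarmforage` simulates a social foraging task in which ten agents search a
200 × 200 toroidal arena for a single target at a time, then consume it
together. The task is built so that *independent* movement helps detection
(spread agents cover more ground) while *collective* movement helps
consumption (agents that travel together land on a found target together),
creating a search–consumption tradeoff. The question the model probes is
whether *loose coupling* — partial, fluid attachment between agents —
outperforms either extreme.

Every agent moves at a constant speed of 1 pixel per tick. Its direction is
the (renormalized) sum of up to three components, each evaluated from the
previous tick's snapshot:

* **Correlated random walk (CRW, always on).** The new heading is the old
  heading plus a turn $\theta_N = \theta_R - \theta_L$ with
  $\theta_R, \theta_L \sim U(0, 180)$ degrees, i.e. a symmetric triangular
  turn distribution on $(-180, 180)$ weighted toward zero (SD
  $180/\sqrt6 \approx 73.5^\circ$). Movement is diffusive with mild
  directional persistence.
* **Flocking (alignment).** The vector sum of the unit heading vectors of
  all neighbours within the vision radius $d_v = 22.5$ px. The sum is not
  normalized, so its magnitude grows with the number of aligned
  neighbours; a large flock therefore dominates the unit-length noise term
  and travels quasi-ballistically.
* **Distancing (generalized Lennard-Jones).** Each neighbour $j$ within
  $1.5\,d_v$ contributes
  $-\left[(s/d_{ij})^{4} - (s/d_{ij})^{3}\right]\hat d_{ij}$ with
  preferred separation $s = 15$ px: strong repulsion below $s$, exact zero
  at $s$, and a weak attraction that fades beyond $s$. The 4/3 exponent
  pair is a deliberately softened version of the classic 12/6
  Lennard-Jones form.

Switching flocking and distancing on or off gives the four movement
conditions: `random` (CRW only), `flocking`, `distancing` and
`loose_coupling` (all three).

Two further mechanisms couple agents to the task:

* **Visual chaining.** An agent that has the target inside its vision
  radius is *flagged*. Any unflagged agent that sees a flagged agent (but
  not the target) heads straight for it, as it would for the target. Flags
  are not transitive and persist until the trial closes.
* **Shared consumption.** A target is a 2 × 2-pixel block worth 500
  consumption units. An agent within the block (distance
  $\le \sqrt2/2$ px of its centre) stops and consumes 1 unit per tick;
  $k$ co-consuming agents finish a fresh target in $500/k$ ticks. When the
  target is exhausted the trial closes, a new target spawns uniformly at
  random, and all flags reset; agents resume from where they stand.

A session is 13,500 ticks. The batch runner reproduces the standard
design of 60 sessions per condition.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `L` | 200 px | arena side (periodic boundaries) |
| `n_agents` | 10 | foraging group size |
| `d_v` | 22.5 px | vision radius; one agent views ~4% of the arena |
| `s` | 15 px | preferred separation (inside `d_v`) |
| `rep_exp`, `att_exp` | 4, 3 | repulsion/attraction exponents |
| `cutoff_factor` | 1.5 | distancing neighbourhood bound, ×`d_v` |
| `speed` | 1 px/tick | constant movement speed |
| `target_units` | 500 | consumption units per target |
| `consumption_rate` | 1 | units per agent per tick |
| `session_ticks` | 13,500 | session length |
| `arrival_radius` | $\sqrt2/2$ px | "on the target" threshold |
| transient exclusion | 14 ticks | dropped at each trial start in entropy |

All defaults are the study's standard conditions and are exposed through
`sim_params()`, `rule_params()` and the YAML/CLI configuration surface.

## Measurement suite

* **Search, consumption and trial time.** Search time runs from trial
  start to the first tick at which any agent has the target in view;
  consumption time from the first arrival to exhaustion (at most 500
  ticks); trial time is the full span. The few ticks an agent spends in
  transit between first sighting and first landing belong to the trial but
  to neither component, so search + consumption can slightly undercount
  the trial span; the per-trial table reports all three explicitly.
* **Grouping entropy.** For a perspective agent, the per-tick number of
  other agents in view is pooled over all search phases (dropping the
  first 14 ticks of each trial, when agents still cluster at the previous
  target, and every tick from first detection onward). One agent, chosen
  per session, is removed from every count so the support is always 0–8,
  which keeps sessions with an externally controlled slot comparable.
  Shannon entropy (natural log) of that distribution measures
  fission–fusion diversity: 0 for a permanently unified group, up to
  $\log 9 \approx 2.2$ for maximally varied groupings. The session value
  averages the per-agent entropies of the nine retained perspectives.
* **Area search rate.** Unique pixels whose centres fell inside some
  agent's vision disk during a trial's search phase, divided by the search
  time, as a percentage of the 40,000 pixels — computed per agent and
  averaged (individual) or over the union of all agents (collective).
  A "visited" variant that counts only physically entered pixels is
  available behind a switch; "viewed" is the default because the vision
  disk is what operationally detects targets.
* **Finding/consuming proportions.** For any designated agent: the share
  of completed trials it detected first, and its share of all consumed
  units. For exchangeable autonomous agents both centre on 0.1.

## Numerical and design choices

Positions are continuous; "pixels" matter only to the coverage metrics.
Angles are degrees everywhere; conversion to radians is internal to the
trigonometric calls. Minimum-image displacements live in
$[-L/2, L/2)$ with the tie at exactly $L/2$ broken toward $-L/2$, so the
convention is deterministic. Updates are synchronous: visibility, flags,
chaining cues and all movement components are evaluated from the previous
tick's snapshot before anyone moves. The resultant of the movement
components is rescaled to the constant speed; if it cancels exactly the
agent keeps its previous heading. Pair distances are clamped to a floor of
$10^{-6}$ px inside the distancing rule, so coincident agents never divide
by zero. Membership of the vision and distancing neighbourhoods uses
strict inequality. When several agents first see the target on the same
tick, the lowest agent id is recorded as first detector; among equally
near flagged agents the lowest id is chained to. On the closing tick each
consumer takes `min(rate, units/k)`, so consumed units balance exactly
against targets.

Choices the source description leaves open, fixed here once:

* Session initialization is uniform at random (positions and headings),
  from the session seed. A target may spawn inside someone's view; rare
  zero-search-time trials are therefore possible and are skipped by the
  area-rate denominator.
* An agent keeps its flag until the trial closes even if the target later
  leaves its view.
* A chaining agent heads straight to its cue; no CRW noise is added on
  those ticks.
* The controlled slot (human stand-in) has its self-direction replaced by
  the policy's heading and feels no flocking/distancing pull, but chains
  to a visible target or flagged agent exactly like an autonomous agent —
  and autonomous agents treat it as a normal neighbour.
* The support-equalization agent removed from entropy counts is chosen
  once per session, deterministically from the seed
  (`(seed mod n) + 1`), so summaries are reproducible from the seed
  alone; across sessions the choice varies like a random draw.
* The trailing, never-detected portion of a session contributes its
  post-transient ticks to grouping entropy (it is genuine search) but not
  to time or area averages (it has no detection, hence no denominator).

The engine's inner loop is compiled (Rcpp); a pure-R `step_world()`
implements the identical update on the identical RNG stream and the test
suite cross-checks the two tick-for-tick, which guards the compiled path
against drift. Both consume exactly `2 * n_agents` uniforms per tick plus
two per target spawn, so the stream is a pure function of the seed.

## What the generator emulates — and what it does not

Sessions generated by this package are the *simulation-only* arm of the
study design: ten autonomous agents, no human player. The controller hook
mirrors the interface a human had — an observation limited to the vision
radius, a desired heading in return — and ships with deliberately simple
scripted policies (`ballistic`, `sweep`). Scripted policies have no
memory of where they have been and no strategic adaptation, so passing
tests about controller plumbing says nothing about reproducing *human*
intervention effects; those require actual players.

Two emergent properties of the implemented equations deserve note, because
they shape what directional patterns the package reproduces. First, the
weak Lennard-Jones attraction shell (between $s$ and $1.5\,d_v$) makes
clusters cohesive: agents that meet — especially the co-consumers left
standing together when a trial closes — tend to stay loosely bound rather
than disperse, because escaping the shell requires diffusing ~19 px
against a persistent inward bias. Pure-distancing groups therefore search
markedly more slowly than pure-CRW agents in this implementation. Second,
because the flocking sum is unnormalized, large aligned groups are very
stable, and adding distancing (loose coupling) produces spaced, locally
aligned formations rather than fully independent fission–fusion at the
scale one might expect. The headline orderings — loose coupling fastest
on trial and search time, highest grouping entropy with flocking lowest,
and higher collective area search rate than flocking — are asserted over
many seeded sessions in `tests/testthat/test-acceptance.R`, and the
absolute throughput of the simulation (targets per session) is recomputed
by `scripts/acceptance.R`; the implementation reproduces the qualitative
structure more faithfully than any particular printed magnitude, as is
typical when a model is rebuilt from its published description alone.

## Problem sizes used in the checks

The acceptance checks run the full design (4 conditions × 60 sessions ×
13,500 ticks) for time-based measures, a 2-condition × 20-session design
for the coverage measures (their rasterization is the expensive step), and
closed-form or brute-force oracles at small sizes (arena 60 for coverage
oracles, $10^4$–$10^5$ draws for distributional checks). These sizes were
chosen to keep a complete run in the order of minutes on a single core
while leaving the directional comparisons well resolved.

## Known limitations

* No inferential statistics: the runner emits tidy per-session tables for
  external analysis; ANOVA/post-hoc machinery is out of scope.
* One target at a time; no variable speeds; no non-square or
  non-periodic arenas.
* The human-subjects side of the original task (real-time rendering,
  mouse control, occluded display) is out of scope; the controller hook
  is its only trace.
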