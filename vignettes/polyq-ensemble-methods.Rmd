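---
title: "Methods: secondary-structure kinetics, interactions and dimer landscapes for polyQ ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secondary-structure kinetics, interactions and dimer landscapes for polyQ ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqens)
```

`polyqens` analyses conformational ensembles of huntingtin exon-1 style
constructs: the 17-residue N17 domain, a polyglutamine tract, and a
C-terminal tail (the minimal P5 polyproline stretch or the full
proline-rich domain).  This vignette documents the models behind each
analysis, the tunable parameters, the synthetic-data generator's scope,
and the numerical and design choices a maintainer would want written
down.

## Constructs and regions

`construct_spec()` assembles sequences as N17 + polyQ + tail, with the
four-residue motif at N17 positions 14–17 rewritable to one of the
variants `LKSF` (wild type), `LKAA`, `LLLF` (helix-promoting) or `LKGG`
(helix-disrupting).  The N17 and PRD reference sequences are editable
package constants; the only hard-tested sequence constraint is that the
default motif reads `LKSF`.  Residue numbering is 1-based and inclusive
everywhere.

`default_regions()` partitions a construct into `n_terminal_n17` (3–10),
`central` (11–17), `polyq` (18 to 17+n) and `tail`.  Two conventions for
the "central" (nucleating) region circulate — 11–17 and an extended
11–23 that reaches into the first polyQ residues.  The package defaults
to 11–17 and exposes `central_end = 23` for the extended reading, so
either convention can be analysed without code changes.

## Secondary-structure statistics

All secondary-structure analyses consume frames × residues matrices of
DSSP codes.  "α-helical" means DSSP `H` only by default: 3₁₀ (`G`) and π
(`I`) helices are excluded so that helical fractions are directly
comparable to NMR-derived α-propensities; every function takes a `codes`
argument for other conventions.

The SS-map is defined as `P[i, L]` = probability that residue `i` lies
in a *maximal* contiguous helical run of *exactly* length `L`.  This
convention was chosen over the cumulative (≥ L) alternative because it
yields an exact conservation law, `Σ_L P[i, L] = f_H(i)`, which the test
suite verifies to machine precision against an independent run-scanning
oracle; the cumulative map is available via `cumulative = TRUE` and is
the upper tail of the exact-length map.

Ensemble profiles (`ss_fraction_ensemble()`) report the mean of
per-trajectory fractions and the standard error of the mean across
trajectories, the convention for independent simulation replicas.  A
single trajectory yields SEM 0 with a warning rather than `NA`, keeping
downstream arithmetic total.

Chemical-shift comparison: `scsd()` computes
`(δCα − δCα,rc) − (δCβ − δCβ,rc)` against a Wishart-style random-coil
reference shipped as an editable constant; glycine (no Cβ) uses the Cα
term only and is *flagged*, not dropped, preserving profile continuity.
`shift_rmsd()` is the per-nucleus RMSD over the residues common to two
tables.

## Helix-initiation kinetics and the Monte Carlo statistic

A residue's initiation time in one trajectory is the time of the
earliest frame in which it is helical, with frame `k` (1-based) assigned
time `k · Δt`.  This convention is a package choice — the earliest
possible initiation time is one frame interval, never zero.  Residues
never helical in a trajectory are undefined there; means and standard
errors use only the trajectories where the residue is defined, and
fully-undefined residues are flagged and excluded from region averages
with a loud warning (exclusion, not imputation, is the conservative
choice).

`mc_region_compare()` quantifies whether one region initiates before
another: each residue's time is modelled as Normal(mean, SEM), each of
`n_trials` (default 10⁶) trials draws every residue, averages within
regions with equal weights, and the output is the fraction of trials
with avg(A) < avg(B) plus the distribution of Δt = avg(B) − avg(A).
Negative sampled times are allowed — the normal model is taken
literally, without truncation.  Under that model the difference of
region averages is itself normal, so
`P = Φ(Δμ / sqrt(Σse²_A/m_A² + Σse²_B/m_B²))`;
`analytic_region_compare()` implements this closed form and the test
suite requires agreement within three binomial standard errors.  With
all SEMs zero the statistic degenerates to a deterministic comparison
(P ∈ {0, ½, 1}).

## Interactions

*Hydrogen bonds.*  `detect_hbonds()` applies the standard geometric
criterion — donor–acceptor distance ≤ 0.35 nm and H–D–A angle ≤ 30°,
both configurable — with donors identified as N/O/S atoms owning a
hydrogen within 0.12 nm.  Inputs without hydrogens are rejected with a
pointer to the precomputed-table route (`read_hbond_table()`).

*Bifurcated hydrogen bonds.*  `bifurcated_hb_occupancy()` counts, per
glutamine residue `i`, the eligible frames in which the sidechain bond
`i → i−4` and the backbone bond between `i` and `i−4` coexist *in the
same frame* (a same-frame reading of "coexist"; no tolerance window).
Eligible frames are those with strictly more than 30 % helical residues,
confining the statistic to helical conformers.  Zero eligible frames
yield a flagged undefined result rather than 0/0.  Occupancies above 5 %
are conventionally called prevalent.

*Contacts.*  Two residues are in contact in a frame when any two heavy
atoms lie within 0.6 nm; a pair counts once per frame no matter how many
atom pairs qualify.  Intramolecular maps enforce sequence separation
`|i−j| > 3`; intermolecular maps average over all ordered chain pairs.
The same binary contact definition is reused for the per-frame
`contact_count()` order parameter, keeping contact semantics consistent
package-wide.

*β-conformers.*  Frames with strictly more than 4 residues coded `E` are
extracted (`> 4`, so an exactly-4 frame never qualifies) and classified
`n17_direct` when any β residue lies within N17, `polyq_internal`
otherwise.  Isolated β-bridges (`B`) do not count toward the threshold
but bridge-containing frames are tallied separately, since a lone bridge
is a qualitatively different (weaker) motif.

## Dimer landscapes

*Inter-helical angle.*  Each helix axis is the dominant principal axis
of its Cα coordinates, oriented N→C.  Before the fit the trace is
smoothed with a one-turn (four-residue) moving average: the raw Cα trace
of a helix that does not span whole turns has a centroid slightly off
axis, which tilts the principal axis by 1–2°; the smoothing suppresses
this wobble below ~0.4° at any length.  A first-to-last-Cα
`atom_vector` mode is provided for comparison with tools that define the
axis from an atom pair (it is exact only when the end residues share a
helical phase).  Angles near 0° are called parallel and near 180°
antiparallel, with the 90° boundary as the labeling convention.

*PMF.*  `pmf2d()` histograms two order-parameter series (default bin
widths: 2 contacts, 10°), converts to `F = −ln(P/P_max)` in kT (global
minimum exactly 0), and reports empty bins as `NA` rather than a capped
value — the data say nothing about their height, and a cap would
fabricate barrier heights.  Renormalizing `exp(−F)` over occupied bins
reproduces the input histogram to machine precision, which is the
invariant the tests check.

*Association events.*  `association_events()` segments a contact-count
series with a hysteretic two-state machine: bound → unbound when the
count drops below `unbound_threshold` (default 1, i.e. complete loss of
contacts), unbound → bound at `bound_threshold` (default 10 residue
pairs).  The defaults are package choices, always echoed in the output;
the hysteresis gap suppresses spurious events from frames fluctuating
around a single cutoff.

## The synthetic-data generator

The generator replaces unavailable MD trajectories with processes that
have the statistical structure the analyses assume.  It is explicitly
*not* an MD surrogate: no energetics, no solvent, no residue-specific
propensities.

`gen_ss_trajectory()` is a stochastic lattice process: while no helix
exists, a nucleus of ≥ 4 consecutive residues appears inside the
nucleation region with probability `k_nuc` per frame; each helix end
then independently extends (`p_ext`) or retracts (`p_ret`) one residue
per frame, and a helix shorter than four residues dissolves.  Defaults —
nucleation in the central region 11–17, `k_nuc = 0.01`, `p_ext = 0.30`,
`p_ret = 0.25`, 5000 frames at 1 ns/frame, single nucleus (a
`max_nuclei` flag allows more) — were chosen once to reproduce the
qualitative phenomenology of N17-polyQ kinetics: helices nucleate
centrally within a few hundred ns and propagate bidirectionally, so
first-passage (initiation) times grow with distance from the nucleation
site.  The slight growth bias (`p_ext > p_ret`) makes long helices
persistent, mirroring the observation that central-region helices are
stable while distal residues become helical late.  What the generator
does *not* emulate: residue-dependent propensities (prolines helicize as
readily as glutamines), helix fraying statistics, 3₁₀/π codes, or any
coupling between replicas.  Passing tests therefore demonstrate
correctness of the *analyses* under controlled truth, not realism of the
process.

`gen_beta_frames()` selects frames independently with probability
`beta_fraction` and recodes the designated strand ranges to `E`,
emulating transient two-stranded β-sheets at the ~0.5–2 % populations
reported for expanded polyQ constructs; the injected population is
binomial by construction, which is what the recovery tests assume.

`gen_dimer_coords()` builds two ideal Cα-trace helices (3.6
residues/turn, 0.15 nm rise, 0.23 nm radius — textbook values; only
relative geometry matters) at a requested inter-helical angle and
separation.  `gen_hbond_fixture()` emits backbone `i → i−4` records
every frame and sidechain records on designated frames, giving
bifurcated-bond occupancies known by construction.

All generators are bit-reproducible from their seed (`withr::with_seed`,
leaving the caller's RNG state untouched).

## I/O conventions

Coordinates are stored in nm; PDB Å are divided by 10 on read, so the
0.6/0.35 nm cutoffs apply directly.  The canonical secondary-structure
input is a documented plain-text matrix (one line per frame, one DSSP
character per residue; a CSV dialect is auto-detected) — exotic
tool-specific dialects are left to upstream converters.  Multi-model PDB
reading goes through `bio3d`; a minimal multi-model PDB writer is
included because `bio3d` writes single models only, and round-trip tests
read its output back through `bio3d`.  Readers reject malformed input
with line-numbered messages; every writer's output is accepted by its
paired reader.

## Problem sizes and limitations

The test suite and `scripts/acceptance.R` run at sizes chosen to make
the statistical checks sharp while keeping a full run fast on one CPU:
ensembles of 5 trajectories × 5000 frames for kinetics (Monte Carlo
statistics at 10⁶ trials), 10 000 frames for β-population recovery, 100
fuzzed matrices (≤ 50 residues, ≤ 500 frames) for the SS-map oracle, and
20-frame × 30-residue ensembles for the contact-map oracle.

Known limitations: `detect_hbonds()` is O(frames × hydrogens ×
acceptors) and intended for small systems — production H-bond tables
should come from dedicated trajectory tools via `read_hbond_table()`;
the contact code holds one frame's atom-distance matrix in memory;
trajectory formats other than multi-model PDB require upstream
conversion; and the Monte Carlo statistic inherits the normality
assumption of its model — for strongly skewed initiation-time
distributions (few replicas, rare nucleation) the normal model is an
approximation, which is why the Δt histogram is reported alongside the
single probability.
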