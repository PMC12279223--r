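# polyqens

Trajectory-ensemble analysis of huntingtin exon-1 (Httex1) polyglutamine
constructs.

Httex1 — the N17 amphipathic domain, a polyQ tract (pathogenic above ~36
repeats in Huntington's disease) and a C-terminal proline-rich domain — is
intrinsically disordered, and its aggregation behaviour is governed by how
α-helices nucleate in N17 and propagate into the polyQ tract, by transient
N17/polyQ interdomain contacts, and by the stability of N17-mediated
dimers.  `polyqens` provides the analysis stack used to dissect these
questions from molecular-dynamics ensembles:

- **Secondary-structure statistics** from DSSP code matrices: per-residue
  helical fractions with replica standard errors, and **SS-maps** —
  `P[i, L]`, the probability that residue *i* belongs to a maximal helical
  segment of exactly length *L*, whose row sums conserve each residue's
  helical fraction (`Σ_L P[i, L] = f_H(i)`).
- **Helix-initiation kinetics**: per-residue initiation times (earliest
  frame with a helical code, `t_i = k · Δt`), and a Monte Carlo
  region-comparison statistic.  Each residue's time is modelled as
  `N(t̄_i, se_i)`; trials draw all residues, average within regions, and
  report `P(central < polyQ)` and the distribution of
  `Δt = t_avg(polyQ) − t_avg(central)`.
- **Interactions**: geometric hydrogen-bond detection (donor–acceptor
  ≤ 0.35 nm, H–D–A ≤ 30°), bifurcated-hydrogen-bond occupancy (Gln
  sidechain *i* → backbone *i−4* coexisting with the backbone *i* → *i−4*
  bond, on frames with > 30 % helicity), heavy-atom residue contact maps
  (any heavy-atom pair ≤ 0.6 nm, `|i−j| > 3` intramolecularly), and
  transient β-conformer extraction (frames with > 4 `E` residues).
- **Dimer landscapes**: inter-helical angle (principal-axis fit of the
  Cα trace), minimum distances, 2D potentials of mean force
  `F = −ln(P/P_max)` in kT over contact-count × angle order parameters,
  and hysteretic association/dissociation event segmentation.
- **Synthetic data**: generators for nucleation–propagation DSSP time
  series, ideal-helix dimer coordinates at controlled angle/separation,
  rare β-sheet frames at a controlled population, and hydrogen-bond
  coexistence fixtures — all bit-reproducible from a seed.

## Worked example

```r
library(polyqens)

sp <- construct_spec(polyq_length = 16, tail = "p5")   # N17-Q16-P5
sp
#> N17(LKSF)-Q16-P5 construct, 38 residues

regs <- default_regions(sp)       # central = 11-17, polyq = 18-33, ...
trajs <- lapply(1:3, function(s)
  gen_ss_trajectory(helix_kinetics_params(seed = s), sp))

prof <- ss_fraction_ensemble(trajs)     # per-residue helicity +/- SEM
round(prof[16:18, ], 3)
#>    residue  mean   sem
#> 16      16 0.911 0.019
#> 17      17 0.911 0.018
#> 18      18 0.910 0.018

it <- initiation_times(trajs)
mc <- mc_region_compare(it, regs$central, regs$polyq,
                        n_trials = 1e6, seed = 42)
mc
#> Monte Carlo region comparison (1,000,000 trials, seed 42)
#>   delta_t = avg(B) - avg(A): mean 104.2 ns, sd 62.8 ns
#>   P(region A initiates before region B) = 0.9516
```

Helices were generated with nucleation confined to the central region
(residues 11–17), and the kinetics analysis recovers that design: the
central region initiates before the polyQ tract with probability 0.95,
and polyQ lags by ~104 ns on average.  `ss_map(trajs)` summarizes the
same ensemble as a helical-length cooperativity map, and the interaction
and dimer functions operate analogously on hydrogen-bond tables and
coordinate ensembles (see the vignette source under `vignettes/`).

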