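# msmshift

Markov state model (MSM) analysis of sodium-driven population shifts between
the active (E) and inactive (E\*) conformations of chymotrypsin-family
proteases — and of any system with a slow two-state exchange conditioned on a
binary environmental variable.

Serine proteases such as thrombin equilibrate between an active form E and an
inactive form E\* in which W215 occludes the substrate cleft; Na⁺ binding at
the 215–229 loop stabilizes E and shifts the equilibrium.  Quantifying that
shift from trajectory ensembles requires a long chain of statistics:
activation-state featurization (the W215–catalytic-triad distance WCT, the
R221a–triad distance RCT, the G193–G216 Cα distance GG, the D221 φ torsion
PhiD, residue-wise loop centers of mass, and a binary Na⁺ coordination
indicator with a 3.8 Å double-anchor cutoff), TICA, k-means microstates,
reversible MSM estimation at a validated lag, PCCA++ lumping into two
metastable states, stationary probabilities π with bootstrap confidence
intervals, mean first passage times (mfpt), MSM-weighted observable
distributions, free-energy surfaces `F = −kT ln ρ`, and circular ψ-dihedral
entropies.  `msmshift` implements that chain end to end.

At its statistical core sit three estimators, each validated against an
independent oracle in the test suite:

* the **reversible maximum-likelihood transition matrix**: maximize
  `∑ c_ij log T_ij` subject to detailed balance `π_i T_ij = π_j T_ji`, via
  the self-consistent iteration `x_ij ← (c_ij + c_ji) / (c_i/x_i + c_j/x_j)`
  on symmetric pair weights;
* **PCCA++** memberships from the inner-simplex construction on the dominant
  π-orthonormal right eigenvectors, with coarse probabilities
  `π_A = ∑_i χ_iA π_i`;
* **mfpt** from the linear system `m_i = τ + ∑_j T_ij m_j`, `m = 0` on the
  target, source-averaged under the restricted stationary distribution — on
  any strictly two-state model this obeys
  `mfpt(A→B)/mfpt(B→A) = π_A/π_B` exactly.

Because multi-microsecond MD datasets are not portable, a first-class
synthetic-dynamics module supplies ground truth: overdamped Langevin dynamics
on a sodium-tilted double well (plus a targeted, ramped-restraint sampler
emulating TMD seeding), a deterministic embedding into toy 3D loop
structures so every geometric feature is computable, and a brute-force
`reference_solution()` (Boltzmann quadrature + discretized master equation)
that the pipeline's estimates are checked against.

## Worked example

Ten sodium-on trajectories of the synthetic double well, featurized through
the structural embedding, analysed at lag 20 frames with 50 microstates:

```r
library(msmshift)
spec <- potential_spec()           # sodium-tilted double well (defaults)
feats <- lapply(1:10, function(s) {
  lt  <- thin_latent(simulate_overdamped(spec, sodium_state = 1,
                                         n_steps = 2e5, seed = s), 100)
  ens <- embed_latent_to_structures(lt)
  cbind(compute_activation_features(ens), na = na_bound_indicator(ens))
})
pip <- run_msm_pipeline(feats, lag = 20, n_tics = 4, n_clusters = 50,
                        seed = 7, dt_frame = 0.1, n_boot = 25)
pip
#> MSM pipeline: 50 microstates (of 50), lag 2 time units
#>   coarse populations: 0.326, 0.674
#>   mfpts: 1_to_2 = 8.44, 2_to_1 = 17.1
pip$bootstrap
#> Bootstrap ensemble: 25 resamples kept, 0 skipped
#>   state 1: pi = 0.326 [0.244, 0.408]
#>   state 2: pi = 0.674 [0.592, 0.756]
reference_solution(spec, sodium_state = 1)$populations
#>     E Estar
#> 0.691 0.309
```

State 2 is the E state (its frames carry positive PhiD): the pipeline
recovers the ground-truth E population 0.691 within the bootstrap interval
[0.592, 0.756], and the mfpt ratio 17.1/8.44 ≈ 2.0 tracks the population
ratio.  Running the same analysis with `sodium_state = 0` flips the majority
state (E ≈ 0.38): the sodium-induced population shift, recovered from
trajectories alone.  `msm_report(pip, "sodium_on")` writes a JSON + Markdown
summary; `implied_timescales()` and `ck_test()` provide the lag-selection
and Markovianity diagnostics.

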