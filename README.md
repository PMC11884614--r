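# idpcrit

Scale-free spatio-temporal correlation analysis for the conformational
dynamics of intrinsically disordered proteins (IDPs).

IDPs lack a fixed native structure and fluctuate continuously among
conformations. Near a critical point, a fluctuating system shows scale-free
correlations in both time and space, and several signatures of that state
can be read directly off conformational trajectories:

- **1/f noise.** The power spectrum of the end-to-end distance R_ee(t),
  computed as the Fourier transform of its time autocorrelation
  (equivalently the periodogram, by Wiener–Khinchin), follows
  S(f) ∝ f^(−β) with β ≈ 1 — between white noise (β = 0) and Brownian
  noise (β = 2). `power_spectrum()` + `fit_exponent()` estimate β by
  least squares in log–log coordinates, optionally after `log_bin()`.
- **Power-law residue domains.** Transient residue clusters are detected
  per frame as connected components of the 2-core of the contact graph
  (contact: any-atom distance < 0.35 nm, sequence neighbors i, i±1
  excluded; domains of size ≥ 5 retained). Pooled sizes follow
  P(s) ∝ s^(−τ); finite-size scaling P(s, N) ∝ s^(−τ) G(s/N) collapses
  distributions from chains of different length N
  (`decompose_domains()`, `size_distribution()`, `scaling_collapse()`).
  Domain mass scales with extent as Rg ∝ s^(1/d_f)
  (`fractal_dimension()`; d_f ≈ 2 for random-walk-like domains).
- **Collective residue motion.** After removing whole-molecule translation
  and rotation (all-atom Kabsch superposition), per-residue velocities
  u_i = Δx_i/Δt are correlated pairwise, C(r) = ⟨cos θ_ij⟩ binned by pair
  distance; the correlation length ξ is the first zero crossing of C(r),
  and curves plotted against x = r/ξ collapse (`correlation_function()`,
  `correlation_length()`, `rescale_curve()`).
- **Single-molecule FRET.** Efficiency traces convert to inter-dye
  distances through E = 1/(1 + (R/R0)^6) (Förster radius R0 ≈ 5 nm) and
  feed the same spectral machinery (`distance_from_efficiency()`,
  `fret_power_spectrum()`).
- **Control system.** A coarse-grained HP heteropolymer (one bead per
  residue, harmonic bonds, Ashbaugh–Hatch λ-scaled Lennard–Jones
  non-bonded interactions, BAOAB Langevin integration in compiled code)
  provides a polymer with IDP-like global dimensions whose dynamics
  nevertheless fall short of 1/f at low frequency
  (`generate_hp_sequences()`, `simulate_hp_polymer()`).

Everything is exercised on synthetic data from the package's own
generators (`colored_noise()`, `planted_domain_frame()`,
`power_law_sizes()`, `gaussian_chain()`, `hinge_motion_pair()`), so the
full pipeline is testable at desk scale. Trajectories are tidy tibbles
(one row per atom per frame, nm coordinates), results are tibbles or small
S3 objects with `tidy()`/`glance()`/`autoplot()` methods, and multi-MODEL
PDB / XYZ / TSV readers and writers cover the standard formats.

## Worked example

```r
library(idpcrit)

# --- 1/f analysis of coarse-grained heteropolymer dynamics ---------------
seqs  <- generate_hp_sequences(L = 73, frac_H = 0.5, n = 4, seed = 7)
specs <- lapply(1:4, function(k) {
  traj <- simulate_hp_polymer(seqs[[k]], n_steps = 81920, save_every = 40,
                              seed = 70 + k)
  power_spectrum(end_to_end_series(traj))
})
fit_exponent(log_bin(average_spectra(specs)))
#> Spectral power-law fit: beta = 1.2311 (r^2 = 0.9531, 16 points, f in [0.00488, 0.391])

# --- residue domains on a conformation with planted clusters -------------
fr  <- planted_domain_frame(60, clusters = list(5:16, 30:38), seed = 1)
dec <- decompose_domains(fr, cutoff = 0.35, min_size = 5)
size_distribution(dec, N = 60)
#> Domain size distribution: 2 domains, N = 60
#>   fit refused: fewer than 20 pooled domains
domain_prone_region(involvement_profile(dec))
#> $start [1] 1   $end [1] 20   $mean_involvement [1] 0.6

# --- velocity correlation length of a two-block hinge motion -------------
hinge <- hinge_motion_pair(n_block = 15, separation = 3, displacement = 0.2,
                           seed = 2)
correlation_length(correlation_function(hinge, bin_width = 0.2))
#> [1] 1.700
```

The fitted β reflects the chain's conformational memory over the sampled
window (short runs sit above the long-run low-frequency exponent; see the
vignette). The two planted clusters are recovered exactly as domains of
sizes 12 and 9 — too few to fit τ, which the distribution object reports
instead of guessing. The hinge's zero crossing at 1.70 nm falls between
the block radius (0.6 nm) and the block separation (3 nm), as it must for
two counter-moving rigid bodies.

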