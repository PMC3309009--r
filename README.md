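# armtf — single-trial time-frequency estimation of multi-joint arm impedance

`armtf` estimates the time-varying joint stiffness `K(t)` and damping
`C(t)` (2×2 matrices, Nm/rad and Nm·s/rad) of a planar two-link arm from
the free oscillation that follows **one** brief force impulse — during
posture or mid-reach — instead of averaging many perturbed repetitions as
classical regressive methods must.

The idea: after a 5 N / 20 ms impulse, the limb rings at its two damped
modal frequencies. Writing the deviation dynamics about the reference
trajectory as

```
M(q_r) δq̈ + C(t) δq̇ + K(t) δq = Jᵀ F_pert(t)
```

and normalizing with the (known) inertia square root, the free response in
ρ = M^½ δq is a sum of two decaying modes with instantaneous resonant
frequencies ω_d,j(t) and amplitudes A_j(t). A **reassigned spectrogram**
(0.75 s Kaiser window, β = 3, 2.5 ms hop) resolves those ridges with
super-resolution; Savitzky–Golay smoothing (3rd order, 0.25 s) turns them
into continuous tracks; the free-vibration relations

```
σ_j = − d ln A_j / dt,   ω_n,j² = ω_d,j² + σ_j²,   ζ_j = σ_j / ω_n,j
```

give instantaneous natural frequencies and damping ratios, and the
amplitude-ratio eigenvectors U(t) (with cross-correlation phase lags ψ_j
for non-classically damped systems) close the inverse modal problem:

```
K̂(t) = M^½ U diag(ω_n²) U⁻¹ M^½,   Ĉ(t) = M^½ U diag(2ζω_n) U⁻¹ M^½.
```

The package also ships the validation apparatus: a two-link arm simulator
with Kelvin–Voigt (time-varying gains, optionally rotated damping),
Poynting–Thomson (muscle–tendon) and Duffing (hardening) viscoelastic
fields, impulse/pulse/servo perturbations, constant-SNR and
signal-dependent noise, three classical regressive baseline estimators,
and a factorial experiment runner scoring percentage RMS errors against
the imposed profiles.

## Worked example

Postural hold at (0.4, 0) m, stiffness doubling sigmoidally after the
perturbation at 2.5 s, noise-free:

```r
library(armtf)
params <- arm_params_default()
traj  <- reference_trajectory(trajectory_spec(start = c(0.4, 0), mode = "posture"),
                              params, fs = 4000)
model <- kv_reference(gK = gain_profile("sigmoid"))   # stiffness doubles after 2.5 s
pert  <- perturbation_spec("force_impulse", direction = octant_direction(3))
rec   <- simulate_record(model, traj, pert)
est   <- estimate_impedance(rec)

df <- as.data.frame(est)
subset(df, mask & t > 3.49 & t < 3.52)[1, 1:11]
#>     t    k11    k12    k22   c11   c12   c22    wn1    wn2    z1    z2
#> 3.491 50.565 24.494 66.772 0.461 0.108 0.227 17.395 38.292 0.084 0.065

impedance_errors(est, rec)   # %RMSE vs the imposed profiles, 2.6-5 s
#>   k11   k12   k22   c11   c12   c22
#>  1.20  0.94  0.94 13.09 10.00  7.37
```

At t = 3.5 s the imposed stiffness is (k11, k12, k22) = (51.4, 24.9, 68.4)
Nm/rad (gain 1.741): the single-trial estimate above tracks all three
coefficients to about one percent, and the damping coefficients
(imposed 0.42/0.10/0.22 Nm·s/rad) to within roughly ten percent —
damping always being the harder quantity, since it lives in the amplitude
decay rather than the ridge position.

A thin command-line front end wraps the same functions
(`inst/cli/armtf simulate|estimate`, YAML configs; see `?read_config`),
and `run_experiment()` sweeps methods × gain profiles × noise levels ×
posture/reach into a long error table.

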