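# DomainOrient

Quantifying the relative orientation and movements of quasi-rigid
domains in large biomolecules over a molecular dynamics trajectory.

## The problem and the method

Protein assemblies such as a T-cell receptor bound to a peptide–MHC
with a CD8 coreceptor move as sets of deformable, quasi-rigid domains.
To track how two domains reorient relative to each other one wants a
body-fixed axis triad per domain — but the obvious choice, a per-frame
PCA of the domain's Cα coordinates, is unreliable: eigenvector
orientation is sign-ambiguous and can flip ~180° between nearly
identical frames, and for near-cylindrical domains the second and
third eigenvectors can swap roles.

`DomainOrient` instead anchors each domain's PCA triad **once**, at
the domain's *central frame* — the frame k minimising the summed
pairwise superposition RMSD Σⱼ RMSD(Vₖ, Vⱼ) — fixes the eigenvector
orientations against chosen atom pairs (v₃ = v₁ × v₂), and transports
the triad to every frame with the rotation from a Kabsch least-squares
fit of the central-frame coordinates onto the frame coordinates:

    T_V(f) = R_V(f) · T_V(k_V),     R_VW(f) = T_W(f) · T_V(f)ᵀ

Sign flips between frames are impossible by construction. Per frame
the package reports the inter-domain centre distance d(f), the
directional cosines vᵢ·wᵢ, and x-convention Euler angles

    α = arccos( r₃ᵧ / √(1−r₃ᵤ²) ),  β = arccos r₃ᵤ,  γ = arccos( r₂ᵧ / √(1−r₃ᵤ²) )

(rᵢⱼ read from the rows of R_VW; r₃ᵤ ≡ r₃z), plus autocorrelation
functions, Pearson correlations with Fisher-z confidence intervals,
a complex-assembly tool that grafts a structure onto another by
superposition on a shared domain, and a synthetic two-helix trajectory
generator with exact ground truth for validation.

## Worked example

Two ideal α-helices 3 nm apart; the second rolls sinusoidally (±40°)
about its long axis while both carry 0.02 nm Gaussian coordinate
noise. The pipeline is: build reference axes per domain, then the
orientation series for the pair.

```r
library(DomainOrient)

sim <- generateTwoDomainTrajectory(
    motionSpec(sigmaNm = 0.02),                          # domain V: static
    motionSpec(angleType = "sinusoid", amplitudeDeg = 40,
               periodFrames = 123, sigmaNm = 0.02),      # domain W: rolling
    nFrames = 300, seed = 7)

refV <- buildReferenceAxes(sim$trajectory, sim$selV)
refV
#> ReferenceAxes for domain "V": central frame k = 16
#> AxesTriad (columns v1 v2 v3), det = 1
#>         [,1]   [,2]    [,3]
#> [1,] -0.0207 0.6181 -0.7858
#> [2,] -0.0038 0.7860  0.6183
#> [3,]  0.9998 0.0158 -0.0139
#> eigenvalues (nm^2): 1.22861, 0.02971, 0.02667

refW <- buildReferenceAxes(sim$trajectory, sim$selW)
os <- computeOrientationSeries(sim$trajectory, refV, refW)
head(as.data.frame(os), 3)
#>   frame time_ns  d_nm cos1   cos2   cos3 alpha_deg beta_deg gamma_deg
#> 1     1     0.5 2.989    1 0.6651 0.6651     46.14   0.8255         0
#> 2     2     1.0 2.995    1 0.7246 0.7246     56.36   1.2497         0
#> 3     3     1.5 3.002    1 0.7412 0.7412     49.19   0.9548         0
```

Reading the output: v₁ of the helix lies along z (third row ≈ 1) with
the first eigenvalue carrying almost all variance, as expected for a
helix. Because W rolls about the *shared* first axis, cos1 stays at 1
while cos2 = cos3 trace cos θ(f); the relative rotation sits at gimbal
lock (β ≈ 0), so the whole roll appears in α and γ is 0 by convention.
The signed roll series recovers the prescribed motion to

```r
rel <- rollAngleSeries(sim$trajectory, refW) -
       rollAngleSeries(sim$trajectory, refV)
sqrt(mean((rel - (sim$truth$thetaW -
                  sim$truth$thetaW[centralFrame(refW)]))^2))
#> 1.78   # degrees RMSE at sigma = 0.02 nm
```

Association statistics work on any orientation observable, e.g. the
published correlations of helix-rolling with and without the
coreceptor:

```r
fisherCI(0.79, 503)   # 0.7546973 0.8207411
fisherCI(0.6, 406)    # 0.5338500 0.6588506
ciOverlap(fisherCI(0.79, 503), fisherCI(0.6, 406))   # FALSE -> significant
```

A command-line front end (`inst/scripts/domor`) wraps the same
functions: `domor simulate`, `domor central-frame --domain "59-83"`,
`domor orient`, `domor distance`, `domor acf`, `domor corr`,
`domor interface --cutoff 0.8`, `domor graft`. Selections use the
grammar `a-b(,a-b)*` of 1-based inclusive Cα index ranges, renumbered
consecutively across all chains (see `tcrPmhcCd8Domains()` for the
packaged TCR/pMHC/CD8 definitions).

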