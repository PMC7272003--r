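---
title: "Transition-path sampling for membrane helix dimerization: models and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-path sampling for membrane helix dimerization: models and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helixtps)
```

# The problem

Two single-pass transmembrane helices associating in a lipid bilayer face
a landscape with (at least) three metastable states: unbound helices (U),
a nonspecifically bound encounter complex (I), and the native dimer (B)
locked in by its specific packing interface. The membrane's viscosity
makes the waiting times in these states enormous compared to the time
actually spent crossing the barriers between them. Dividing-surface
transition-path sampling turns that disparity into an advantage:
configurations are harvested *at* a putative transition-state surface
(from umbrella-sampling runs that are needed anyway for the
thermodynamics), and short trajectory pairs launched from them either
commit to two different states — a transition path — or fall back. The
package implements this strategy end to end, and ships synthetic dynamics
with known kinetics so that each estimator can be checked against
brute-force truth. All synthetic work uses reduced units: lengths in
"nm", energies in units of $k_BT$, and time in the units implied by the
diffusion coefficients.

# Collective variables

The interhelical distance RMSD over the native contact pairs,
$$D_\mathrm{RMS}
  = \Big[\tfrac{1}{N_\mathrm{nat}}\sum_{(i,j)}(r_{ij}-r_{ij,0})^2\Big]^{1/2},$$
is zero in the native complex and remains well defined after every
contact is broken, which is what makes it usable as an umbrella bias all
the way to dissociation. The native pair list is built from the native
structure: intermolecular heavy-atom pairs within a build cutoff and a
residue range. The build cutoff is a deliberate knob (default 0.6 nm,
`build_native_set()`), chosen larger than the 0.45 nm contact cutoff so
the list is not degenerate; no single value is canonical, so it is an
argument, not a constant.

Helix pairs can reach near-native $D_\mathrm{RMS}$ with the wrong
handedness, so a second coordinate, the signed crossing pseudo-dihedral
$\theta$ between the helix end anchors, is mixed in:
$X = D_\mathrm{RMS}/\mathrm{nm} + \mu\,\theta/\mathrm{rad}$. The
coefficient $\mu$ is picked by `scan_mu()` to maximize the
bound-to-unbound barrier of the projected profile; 0.1 is the default.
The dihedral uses the standard right-handed (IUPAC) convention — a
right-handed native crossing gives a negative angle — and contact maps
count a residue pair as touching when any heavy-atom pair is strictly
within 0.45 nm. Strict inequalities are used at every cutoff so tests are
bit-reproducible; the choice is measure-zero.

# Free-energy surfaces

`wham()` solves the weighted-histogram equations by direct iteration on a
binned grid, to a tolerance of $10^{-7}$ on the window free energies, and
then computes unbinned per-frame weights from the converged offsets.
Projections onto arbitrary coordinates (`project_pmf()`) are weighted
histograms with those weights; each bin also records an effective sample
count $n_\mathrm{eff} = (\sum w)^2/\sum w^2$. Two practical rules follow
from the estimator's behaviour and are applied throughout:

- a PMF is only interpreted over the window-covered domain. Frames beyond
  the umbrella ladder receive enormous, essentially arbitrary weights
  (their bias energy is large in every window), and a single such frame
  can masquerade as a deep minimum;
- `locate_barriers()` smooths with a short moving average (default 3
  bins) before the extremum search, reports positions on the unsmoothed
  grid, and can ignore bins below a minimum $n_\mathrm{eff}$. Barrier
  heights are measured from the lower (deeper) adjacent minimum.

The probability density at the dividing surface, needed by the rate
estimator, is read with a 3-bin local average (`p_eq_at()`); a single bin
at a barrier top is noise-limited. Statistical errors come from a block
bootstrap with contiguous blocks within each window (default 10), because
umbrella samples are strongly autocorrelated. Pooling of independent
window sets (e.g. runs started from the bound and from the dissociated
configuration) is plain concatenation: WHAM assigns each window its own
offset. Default bin width is 0.02 on $X$, matching the scale of the
0.005 frame-selection tolerance.

# Shooting and rates

Frames within 0.005 of the dividing surface are selected uniformly at
random without replacement (`select_frames()`, stratified across
independent sources if requested). From each frame two segments are
launched and run until the coordinate enters basin A or basin B —
intervals on $X$, with entry tested against the inner edges and the
crossing time interpolated between steps — or until a time cap. Pairs
ending in different basins are transition paths; a timed-out segment
makes the attempt *incomplete*, which is logged but excluded from the
rate average, whose defining ensemble is classified attempts.

For inertial dynamics the scheme launches the two segments with
sign-reversed Maxwell–Boltzmann velocities. The synthetic models here are
overdamped and carry no momenta; the pair is realized as two independent
noise streams from the same frame. Both constructions make the
concatenated pair a valid equilibrium path through the launch point,
which is the property the estimator needs.

The binding and unbinding rates follow from
$$2\,(k_b^{-1}+k_u^{-1})^{-1}
  = p_\mathrm{eq}(X^\ddagger)\,
    \big\langle \theta_\mathrm{TP}\,(\textstyle\sum_i |v_i|^{-1})^{-1}
    \big\rangle,$$
the average running over classified attempts with
$\theta_\mathrm{TP}=1$ for transition paths. The identity behind it:
selecting a frame near the surface from equilibrium picks a
basin-to-basin path segment with probability proportional to the time it
spends at the surface, i.e. its $\sum_i 1/|v_i|$; the weighted average of
$\theta_\mathrm{TP}(\sum_i 1/|v_i|)^{-1}$ then telescopes to (number of
transitions)/(total time $\times\ p_\mathrm{eq}(X^\ddagger)$), which is
twice the one-way flux. The flux is split into $k_b$ and $k_u$ with the
equilibrium constant from integrating $F(X)$, so $k_b/k_u = K_\mathrm{eq}$
holds by construction. Two implementation points matter and were fixed by
measurement against brute-force transition counting (the package tests
rerun both):

- crossings are recorded at the *fixed* surface $X^\ddagger$ common to
  all attempts, not at each attempt's own launch value. Pinning the level
  to the path's own point destroys the size-biasing that the derivation
  above relies on (measured error: a factor of about 3);
- for diffusive dynamics the single-step finite-difference "speed" of a
  crossing is noise, not velocity, and the reciprocal of the summed
  reciprocal single-step speeds carries a scale-free bias (measured:
  1.3–1.5x, independent of the time step). The package therefore measures
  $\sum_i 1/|v_i|$ on a band of half-width `band_h` around the surface:
  each band transit at speed $v$ spends $2\,\mathrm{band}_h/|v|$ inside,
  so the sum equals the band occupation time divided by the band width —
  the same quantity, evaluated at a scale where speeds are meaningful.
  The default half-width is four single-step standard deviations; with
  it, shooting rates agree with brute-force counting to ~10% on
  analytic benchmarks (the residual reflects the density variation across
  the band). Single-step crossing records are still kept for parity
  diagnostics: a transition path crosses its surface an odd number of
  times.

Path weights $w_i \propto (\sum_i |v_i|^{-1})^{-1}$ (same band
measurement) correct averages over the harvested paths for the selection
bias toward frequently recrossing trajectories; with them, the shooting
ensemble reproduces the spontaneous transition-path duration distribution
of long unbiased runs (a weighted KS check in the tests).

Unimolecular association rates convert to bimolecular ones by dividing by
the 2D partner concentration, $(N_\mathrm{pep}-1)$ per bilayer area at
0.76 nm$^2$ per POPC lipid; both conventions (partner count, per-leaflet
lipid count) are arguments. When simulated and experimental binding
stabilities differ and the difference is attributed to unbinding,
`corrected_off_rate()` rescales the off rate by
$e^{-\Delta\Delta G/k_BT}$.

# Mechanism statistics

`p_q_given_tp()` averages per-path contact populations with the path
weights. Two weightings are offered: the path-ensemble average (each
transition path counts once; the convention used for reporting contact
maps) and a frame-weighted variant in which paths additionally count in
proportion to their duration. The distinction matters for the Bayes
inversion
$$p(\mathrm{TP}\,|\,q_{ij})_\mathrm{nn}
  = \frac{p(q_{ij}\,|\,\mathrm{TP})\; p(\mathrm{TP})_\mathrm{nn}}
         {p(q_{ij})_\mathrm{nn}},$$
because $p(\mathrm{TP})_\mathrm{nn}$ and $p(q)_\mathrm{nn}$ are snapshot
fractions: consistency requires the frame-weighted $p(q|\mathrm{TP})$
whenever contact formation correlates with path duration (it does,
strongly, in the toy model — short paths are the ones that barely detach
from the native interface). The acceptance test validates the inversion
in the frame-weighted form against direct conditional counting.

$p(\mathrm{TP})_\mathrm{nn} = 2\tau_\mathrm{TP}/(2\tau_\mathrm{TP} +
k_\mathrm{bind}^{-1})$ is the steady-state transit identity: each
association event contributes one waiting period and two transits (one
binding, one unbinding) to the time spent outside the bound state. Using
the standard transition-count rate for $k_\mathrm{bind}$ folds
basin-excursion time into the waiting time, so the identity holds to a
few percent rather than exactly; the acceptance tolerance (10%) reflects
that, not a fit.

All `_nn` quantities are restricted to the two states flanking the
barrier under study: frames in the bound basin and frames in the third
state are excluded (`nn_frames()`). Cells whose conditioning set has
fewer than 10 effective samples are reported as undefined rather than 0 —
a ratio of two tiny numbers is not evidence. Tail curves
(`tail_distribution()`) count, per threshold, the native and non-native
contacts whose $p(\mathrm{TP}|q)_\mathrm{nn}$ strictly exceeds it.

# The synthetic world

**1D models.** `multi_well_potential()` builds piecewise-cubic potentials
whose stated wells and barriers are exact stationary points, with
harmonic confinement outside; the overdamped Euler–Maruyama propagator
refuses time steps whose single-step displacement exceeds a tenth of the
narrowest well width. Long trajectories reproduce the Boltzmann density
(KL < 0.01 at $10^6$ steps in the tests) and free diffusion has
MSD = $2Dt$ to 5%. `brute_force_rates()` is the kinetics oracle:
transition counting with block-bootstrap errors.

**Toy dimer.** Two rigid rods of 10 beads (diameter 0.5 nm, one bead per
residue) move in a periodic membrane patch (6 nm box) with in-plane
translation and rotation and a harmonically restrained tilt, so distance
RMSD, crossing angle and contacts are all nontrivial. Beads of different
rods repel below a core distance and attract through Gaussian wells at
the 0.38 nm contact distance. The nonspecific amplitude of pair $(i,j)$
is $\varepsilon_\mathrm{ns} g_i g_j$ with $g_k = (k/10)^6$ rising sharply
toward the C-terminus; the designated native pairs — the *shifted*
registry $(i,i{+}1)$, $i = 3..8$ — get an extra well of depth
$\varepsilon_\mathrm{nat}$.

That registry inversion is the load-bearing design choice. A diagonal sum
of per-bead weights always beats a shifted one, so the in-register
alignment $(i,i)$ is the nonspecific optimum: rods dock there first,
through C-terminally weighted nonspecific contacts — the encounter
complex I — and must slide by one bead spacing, breaking those contacts
while forming the native ones, to reach B. Native contacts therefore gate
the I$\to$B transition *by construction*, giving the mechanism statistics
a known ground truth. Overlapping steps are rejected and retried with
fresh noise (at most 100 times) rather than softened; at the default time
step rejections are rare.

The reference parameter set (`toy_dimer_reference()`:
$\varepsilon_\mathrm{nat} = 0.8$, $\varepsilon_\mathrm{ns} = 4.2$, well
widths 0.05 nm, $D_t = 0.5$, $D_r = 0.3$, $\Delta t = 5\times10^{-5}$)
was chosen once, by inspecting equilibrium profiles, to put the three
states at comparable (within a few $k_BT$) free energies with the
projected density on $X$ showing exactly two substantial maxima — near
$X = 0.33$ (native docking) and $X = 0.80$ (association) — and frequent
spontaneous exchange, so that direct counting has statistics. Earlier
candidates with a gentler C-terminal exponent left a third, metastable
registry-shifted dock visible as an extra maximum; the sharper weighting
suppresses it. The barrier positions land near the numeric values of the
real system's dividing surfaces, which keeps those constants exercised at
realistic magnitudes, but no quantitative correspondence with the real
dimer is implied.

What a green test on this world does establish: the estimators
(WHAM, shooting rates, transit identity, Bayes inversion) are correct,
because they agree with independent brute-force truth on a system sharing
the real problem's structure — three states, two barriers, diffusive
dynamics, native-gated docking. What it does not establish: anything
about force fields, lipid specificity, helix flexibility (the rods are
rigid), three-dimensional escape, or the actual magnitudes of
glycophorin's rates and barriers, which require the all-atom inputs this
package consumes but does not generate.

# Numerical choices and degenerate inputs

- Basin entry is tested on interpolated coordinates between steps, so
  classification does not depend on the storage stride.
- Attempts whose surface-band occupation is exactly zero (an infinite
  apparent crossing speed) are flagged and excluded from weights.
- `scan_mu()` records a barrier height of 0, flagged, when a candidate
  $\mu$ produces no interior barrier.
- `equilibrium_constant()` splits the dividing bin's mass linearly and
  refuses dividing points outside the domain or with an empty side.
- The pipeline (`run_pipeline()`) spawns per-stage seeds deterministically
  from the master seed, caches each stage, and is bit-reproducible from
  scratch; attempt results are independent of execution order because
  every attempt has its own derived seed.

# Known limitations

- Real-MD ingestion is limited to PDB text for single structures plus
  in-memory conformations; XTC/DCD/GRO readers are not available in R
  without external dependencies, so trajectory CV series must be computed
  upstream and imported as tables.
- The crossing-speed band measurement is exact for diffusive dynamics but
  introduces a band-averaging approximation of order the density
  variation across the band (~10% on the steepest benchmark); inertial
  dynamics, where single-frame finite differences are meaningful, would
  not need it.
- The rate split assumes a two-state reduction around each barrier; the
  third state is excluded by interval, not by committor.
- Rigid rods cannot report on internal helix deformation during docking.
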