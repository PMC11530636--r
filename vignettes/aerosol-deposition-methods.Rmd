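---
title: "Models and methods behind aerodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aerodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerodose)
```

# Scope and overall model

`aerodose` is a desk-scale toolkit for studying how inhaled radioactive
aerosols deposit in human airways and for converting deposition patterns
into Monte-Carlo point-source terms for internal dosimetry. It replaces the
two expensive stages of a full computational fluid and particle dynamics
(CFPD) study — CT-based airway reconstruction and a 3-D RANS airflow
solution — with analytic stand-ins, while keeping the particle physics, the
deposition metrics, the cohort statistics and the dosimetry export at full
fidelity:

* **Geometry.** Airways are parametrized bifurcating trees of straight
  circular tubes (mm units), generated from two clinically anchoring
  parameters — volume-averaged trachea diameter `t_d` and carina angle
  `b_a` — plus Weibel-like per-generation scaling conventions. The analytic
  representation permits exact inside/outside tests for wall contact, which
  is what the stick-on-contact deposition model needs.
* **Airflow.** The carrier flow is a reduced-order model: a breathing
  waveform Q(t) = Qmax sin(2 pi t / T) scales a quasi-steady per-segment
  flow distribution obtained by splitting flow at each junction in
  proportion to the Poiseuille conductance (d^4/L, series-parallel
  composition) of the downstream subtrees. Within a segment the profile is
  parabolic (or plug). The particle tracker only consumes a local-velocity
  provider, so a CFD-sampled field could be substituted without touching
  the transport code.
* **Particles.** One particle per parcel, integrated in a Lagrangian frame
  under Schiller-Naumann drag, gravity with a (1 - alpha_p) buoyancy
  factor, and Brownian force; lift and virtual mass are implemented but off
  by default. Walls stick on contact; crossing a terminal outlet face is an
  escape toward the unmodeled bronchiolar/alveolar generations; crossing
  the inlet face is exhalation.
* **Metrics.** Number and mass deposition fractions with an explicit ICRP
  escape credit, left/right lobar splits, impaction-parameter curves with
  the d_p^2 Q < 0.1 exclusion filter, and normalized 19-bin size
  histograms on 0-10 um.
* **Dosimetry export.** Deposited particles become point sources with
  mass-proportional iodine-131 activity, optionally transformed into a
  phantom frame, duplicated per decay mode (beta and gamma), and batched
  under a 500-sources-per-deck cap.

# The airway-tree generator

`generate_airway_tree()` builds: a trachea of constant diameter `t_d`
(so the measured volume-averaged diameter is exact by construction), two
main bronchi separated by exactly `b_a` degrees (half-angle each side, with
any left/right asymmetry applied as a skew that preserves the inter-branch
angle), and deeper generations with a default daughter/parent diameter
ratio of 0.78 and a length of 3 diameters — standard morphometric
conventions for human airways, both overridable. Branching planes rotate
90 degrees per generation, which is what gives real bronchial trees their
three-dimensional spread. A log-normal `jitter` (default 3% relative sd)
perturbs diameters and angles below generation 1 so that synthetic cohorts
are not perfectly self-similar; the trachea and carina are never jittered,
so `t_d` and `b_a` are recovered exactly and the nine phenotype fixtures
stay inside their documented min-max ranges.

`measure_tree()` computes the four morphometric parameters used for
phenotyping. The volume-averaged trachea diameter is the length-weighted
mean over generation-0 segments: with tube segments, length weighting and
slice-volume weighting coincide up to the (constant) cross-section, and
the length-weighted form remains well defined for tapering
multi-segment tracheas. This weighting choice is an assumption the package
makes explicit rather than hides.

Mirror symmetry (`asymmetry = 0`, `jitter = 0`) gives exactly equal
left/right lobe volumes — a machine-precision invariant the tests rely on.

For geometry exchange the package writes a versioned JSON schema
(`airway-tree/1`) and watertight triangulated tube surfaces (binary and
ASCII STL). Surface import is skeletonized by geodesic level sets: mesh
vertices are binned by graph-geodesic distance from the inlet, connected
components per bin form cross-section rings, ring centroids give
centerline nodes, and component adjacency gives the branch topology. The
default bin width is about one tube radius; much finer bins fragment
cross-sections into arcs (classic Reeb-graph noise), much coarser bins
blur short branches. This method is intended for tube-like surfaces, not
as a general medial-axis extractor; junction blending limits the accuracy
of angles recovered from surfaces to a few degrees, which the tests state
explicitly.

# Cohort statistics

`rank_feature_importance()` regresses age or weight on the four
morphometric parameters with a random forest and reports node-purity
importances normalized to sum to one, plus a 25%-held-out RMSE. The
synthetic cohort generator plants a known dependence (standardized
coefficients, trachea diameter dominant and carina angle a close second)
so the expected ranking is ground truth, not folklore.

`fit_kernel_kmeans()` is the package's own kernel k-means: z-scored
inputs, an RBF kernel whose bandwidth defaults to the median pairwise
distance heuristic (no value is documented for this step in the source
problem, and the heuristic is scale-free), kernel-space k-means++ seeding,
and Lloyd iterations on kernel-matrix distances with 10 restarts keeping
the lowest objective. The objective is non-increasing within a run and the
partition is invariant to row permutation. An independent implementation
(`kernlab::kkmeans`) serves as a cross-check in the test suite; it is not
used in the package itself.

Cluster labeling places the 9 centroids on a small/mean/big 3x3 grid by
tertiles of the centroid coordinates (diameter letter first), with ties
broken by ascending cluster index. Representatives are the members nearest
their centroid in kernel feature space. Clusters whose representative
distance exceeds a threshold (default 0.75 on the normalized kernel
scale) are *flagged* rather than silently dropped — the analyst decides
whether a cluster lacks a usable representative, as happens when a cluster
sits between two neighbors (the reason the `ss` phenotype is excluded from
the default pipeline sweep).

# Reduced-order airflow

Defaults describe heavy-exercise breathing: Qmax = 90 L/min and
T = 2 s. The peak value is stated for the steady mesh-study condition of
the source problem rather than for the transient runs, so adopting it for
the waveform is an assumption, recorded here. The turbulence
boundary-condition calculators implement the transitional k-omega SST
inlet formulas — k = 3/2 (I |u_ref|)^2 with I = 0.04, omega =
sqrt(k)/(C_mu^0.25 L) with C_mu = 0.09 (we read the constant as C_mu
itself, the standard SST value, so C_mu^0.25 is about 0.548), Tu =
100 sqrt(2k/3)/|u_ref|, gamma = 1, and the piecewise transition
Re_theta correlation (left branch at the Tu = 1.3 boundary). These values
are reported for solver parity; the reduced-order flow model does not
consume them, and turbulent particle dispersion is off by default — a
stated fidelity gap relative to a RANS-coupled tracker.

# Particle transport

The momentum balance per particle is

m_p dv_p/dt = 1/2 C_d rho A_p |v_s| v_s + m_p g (1 - alpha_p) +
f_Brownian (+ f_lift + f_virtual_mass),

with v_s = u - v_p the slip velocity, A_p the projected area, and C_d
from Schiller-Naumann (24/Re (1 + 0.15 Re^0.687) up to Re = 1000, then
0.44). The tracker never divides by Re: drag enters through the bounded
factor C_d Re / 24, so the Stokes limit is exact.

**Integrator.** Each sub-step freezes the drag rate beta =
18 eta / (rho_p d_p^2) x (C_d Re/24) at the start-of-step slip and solves
the resulting linear ODE exactly (exponential / point-implicit form).
Constant accelerations — gravity and the Brownian force — fold into an
effective fluid velocity u* = u + a/beta. This scheme is unconditionally
stable, reproduces Stokes settling and velocity relaxation exactly in the
linear-drag limit, reduces to Euler-Maruyama for the Brownian term as
beta dt -> 0, and gives the overdamped diffusion limit MSD = 2 D dt as
beta dt -> infinity. That matters because the flow step (0.02 s by
default, within the 0.015-0.025 s band typical of such runs) is orders of
magnitude larger than the relaxation time of micron particles
(about 3e-7 s for the 0.42 um count-median default).

**Brownian force.** The printed literature form of the Brownian force
places the particle mobility alpha = D/(k_b T) inside the square root,
which is dimensionally inconsistent with the fluctuation-dissipation
theorem. The package's default uses the friction coefficient
gamma_f = 3 pi eta d = 1/alpha, giving amplitude
sqrt(2 k_b T gamma_f / dt) per axis and hence MSD = 2 D t with
D = k_b T/(3 pi eta d) (Einstein relation) — verified against free
diffusion in the tests. The printed variant stays available behind
`brownian_printed_form = TRUE` for comparison. The Cunningham slip
correction is off by default (the continuum drag model is used as given);
a flag enables it.

**Sub-stepping.** Within each flow step every particle advances with its
own sub-step: the smaller of the remaining budget, a fixed fraction
(default 1/20) of its segment transit time at max(own speed, local fluid
speed), and — when Brownian motion is on — a cap that keeps one diffusive
step at less than 0.3 of the current wall distance. A Brownian-bridge
first-passage correction (absorption probability exp(-d0 d1/(D dt)) for
start/end wall distances d0, d1) catches wall contacts inside a step;
without it diffusional deposition is systematically underestimated.
Asynchronous sub-steps keep a particle in a fast narrow segment (such as
a glottal constriction) from throttling the whole population.

**Junction geometry.** Straight tube segments meet at junctions blended
by a sphere of the largest adjoining radius. A particle beyond its
segment's distal end that is not inside any child tube keeps moving
inside the blending ball with the plug velocity of the nearest child;
leaving the ball without entering a child is a wall contact (the outer
corner of the bend — the impaction site). Anywhere else, radial distance
beyond the tube radius is a wall contact immediately. This analytic
treatment gives physically sensible inertial impaction at bends while
letting small, flow-following particles turn the corner; it is the main
geometric simplification relative to a smooth CT surface.

**Injection.** Particles enter on the inlet disk with flux-weighted radial
positions (density proportional to the local axial velocity), at the local
fluid velocity, uniformly in time over the injection window — by default
the inhalation of the second simulated cycle, i.e. seconds 2-3 of a 4 s
run whose first 2 s are flow-only. For steady validation runs a zero-width
window injects everything at the start.

# Validation strategy of the transport model

Every deposition mechanism is checked against an independent closed form
(all shipped in the package as analytic benchmarks):

* Sedimentation: terminal velocity within 1% of rho_p d^2 g/(18 eta);
  tube deposition within 10% of the laminar-flow horizontal-tube
  efficiency (2/pi)(2 kappa sqrt(1-kappa^(2/3)) - kappa^(1/3)
  sqrt(1-kappa^(2/3)) + asin(kappa^(1/3))), kappa = 3 L v_ts/(8 R u_mean).
  During development this formula was itself verified against a
  deterministic flux-weighted streamline integration before being frozen
  as the oracle.
* Diffusion: free-particle MSD within 5% of 2 D t at 1e4 particles; tube
  deposition within 10% of the Gormley-Kennedy penetration series over
  deposition parameters 1e-3 to 1e-1.
* Impaction: monotone capture with d_p^2 Q on a 90-degree bend fixture,
  and the upper-airway surrogate check below.
* Book-keeping: exact particle and mass conservation across fates at all
  times; bit-identical reruns for a fixed seed; total deposition changes
  by less than 1% when the sub-step is halved.

The upper-airway surrogate `UA-1` is a serial-tube mouth-throat stand-in:
an oral tube (20 mm), a downward bend into a pharynx (14 mm), a bend into
a 6 mm glottal constriction, and a bend into a trachea-like outlet. At
90 L/min the constriction velocity is about 53 m/s, so 10 um unit-density
particles carry a Stokes number well above one and deposit almost entirely
by impaction — the tests require more than 90% capture, the filtering
behavior expected of the extrathoracic airway for such particles.

What passing these tests does *not* show: agreement with CT-specific
deposition patterns. The reduced-order flow has no laryngeal jet,
secondary (Dean) vortices, turbulent dispersion, or two-way momentum
coupling, and the analytic geometry has no surface irregularity. Per-tree
deposition fractions from this package are therefore indicative, not
subject-specific predictions; the package's value is the workflow, the
metrics, and the physics building blocks, each individually validated.

# Deposition metrics

nDF = (n_stick + n_scape x ICRP_correction)/n_total credits a fraction of
the particles escaping through the distal outlets as deposited in the
unmodeled bronchiolar/alveolar generations. The correction has no
defensible universal value, so `metrics_config()` requires it explicitly —
there is no silent default.

The printed mass fraction mDF = (m_stick + m_scape)/m_total would equal
one whenever nothing is exhaled if "escape" included the inlet; the
package therefore tallies exhaled mass separately and excludes it from the
numerator (the only reading consistent with sub-unity reported mass
fractions), and offers an ICRP-corrected numerator symmetric with nDF as
an alternative convention. Regional fractions are lobar splits of the
deposited (stuck) particles and always sum to one.

The impaction parameter d_p^2 Q uses um^2 L/min; when a breathing
waveform is supplied, Q is the mean inspiratory flow (2/pi) Qmax. Points
with d_p^2 Q < 0.1 are excluded from reported curves (no comparison data
exist below the threshold); the threshold itself is retained. Size
histograms use 19 equal bins on 0-10 um, normalized to integrate to one,
and concatenate across runs rather than averaging, so multi-run histograms
are count-weighted merges.

A packaged deposition summary table for the eight phenotype geometries
ships as plain CSV; the reader enforces that each row's lobar pairs sum to
100% within printed rounding (0.6 percentage points).

# Grid convergence toolkit

The toolkit is generic — any scalar functional versus element base size.
For exactly three grids at a common refinement ratio the observed order is
the closed form p = ln((f3-f2)/(f2-f1))/ln r; otherwise (f_exact, C, p)
are fitted jointly by least squares on f(h) = f_exact + C h^p, the linear
sub-problem solved exactly for each trial p. Oscillatory (sign-changing)
differences refuse an order rather than reporting a meaningless one.
GCI = Fs |(f_coarse - f_fine)/f_fine|/(r^p - 1) x 100 with safety factor
1.25; refinement ratios outside the recommended 1.25-2 band warn. The
asymptotic-range ratio GCI_23/(r^p GCI_12) is near one when the grids sit
in the asymptotic range; because each GCI is normalized by its own fine
value, the exact-identity check in the tests multiplies the normalization
back out. Since no CFD runs inside this package, the toolkit is exercised
on manufactured data and on the tracker's own deposition-fraction
convergence in the sub-step.

# Dosimetry export

Effective specific activity is mass_fraction x pure specific activity:
0.21% of 4.6e15 Bq/kg gives 9.66e12, reported to one significant figure
as 1e13 Bq/kg. Particle activity is mass-proportional,
A = (pi/6) d_p^3 rho_p SA — how activity should be distributed across
polydisperse particles is not otherwise specified, and mass
proportionality is the physically natural choice for a homogeneous
mass fraction. Each deposited particle yields one point source per decay
mode (beta and gamma for iodine-131, whose data — half-life 8.02 d, beta
endpoints 0.606/0.334/0.807 MeV at 89.6/7.34/0.39%, gamma 0.364 MeV at
81.5% — ship in `nuclide_i131()`). Batches respect a 500-source cap with
a particle's modes kept together. The deck dialect is a documented
plain-text format (position, activity, spectrum lines, JSON manifest)
inspired by multi-source Monte-Carlo input conventions; byte-level
compatibility with any particular transport code is not claimed, and beta
spectra are carried as endpoint/intensity triplets — spectral shaping is
the transport code's job. The phantom-frame transform is
rotation + isotropic scale + translation in cm, with an exact inverse.

# Numerical and design choices, summarized

* Units: geometry files in mm, physics in SI, deck positions in cm,
  diameters in particle records in um (the natural unit of each domain);
  converters are internal and tested.
* Configs are YAML; unknown keys are errors. All stage RNG streams derive
  from one global seed by fixed offsets (kept below 2^31).
* Degenerate inputs fail loudly: zero-diameter segments, empty snapshots,
  missing ICRP correction, singular transforms, oscillatory convergence,
  k larger than the number of points.
* Tie-breaks: tertile labeling ties go to the ascending cluster index;
  membership ties at junctions go to the smaller relative radial offset.
* Problem sizes used by the shipped tests and the acceptance script:
  25 random trees for round-trip recovery, 1e6 draws for the sampler
  check, 5e4 particles for the upper-airway surrogate, 2.5-3e3 particles
  per analytic-benchmark point, 270 points for the clustering fixture.
  These sizes were chosen so each check's Monte-Carlo error is several
  times smaller than its tolerance.

# Known limitations

* The reduced-order flow omits all secondary-flow phenomena; deposition
  hot spots caused by the laryngeal jet or Dean vortices are outside the
  model.
* No two-way momentum coupling: particles do not feed back on the flow,
  although the source problem class reports this matters for dense plumes.
* No hygroscopic growth, evaporation, particle-particle collisions,
  electrostatics, or resuspension.
* The skeletonizer targets tube-like surfaces; it is not a general
  medial-axis tool and blunts branch angles near junctions.
* Whether the 0.42 um parameter of the aerosol source is a count-median
  or an arithmetic mean is ambiguous in the source material; the package
  adopts the count-median reading (`cmd_um`), under which the sample
  geometric mean reproduces 0.42 um.
* The ICRP escape credit is a global scalar; a size-resolved credit would
  need an external lookup the user can apply per size class before
  tallying.
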