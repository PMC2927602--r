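---
title: "Comparing bound and unbound interface mobility with an elastic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing bound and unbound interface mobility with an elastic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerdyn)
library(dplyr)
library(ggplot2)
```

## The question the package answers

Residues at a protein-protein interface are, on average, less mobile than
other surface residues. Two distinct mechanisms can produce that: the
monomer's own architecture may hold the future interface rigid even when
the partner is absent, or the partner itself may act as the restraint.
`dimerdyn` separates the two by computing, for every residue of one subunit
of a dimer, its root mean square fluctuation (RMSF) in the *bound* form --
partner present, treated exactly through Gaussian marginalization -- and in
the *unbound* form -- the structurally-quenched monomer obtained by
splitting the complex in silico, with its network rebuilt from its own
coordinates. Comparing the two per residue distinguishes three scenarios:
fluctuations small in both forms (A: the architecture dominates), small
bound but large unbound (B: the partner restrains), or large in both (C:
neither does). Since a harmonic partner can only remove conformational
freedom, a fourth case -- more mobile bound than unbound -- cannot occur,
and the package treats any numerical violation of it as an error.

The unbound form is a proxy for the free monomer only for non-obligate
complexes; for obligate ones (monomers unstable alone) it is still well
defined, because the elastic free energy has its minimum at the input
structure by construction. That is precisely why an elastic network, rather
than a transferable force field, is the right tool for this comparison.

## The elastic network

The model is a two-centroid (beta-Gaussian) network over the C-alpha trace.
Each non-terminal, non-glycine residue gets a pseudo side-chain centroid at
distance $l$ from its C-alpha along the normalized local outward direction
$w_i = 2 r_i - r_{i-1} - r_{i+1}$. All centroid pairs from different
residues within a cutoff $R_c$ are coupled by a quadratic penalty on the
component of their relative displacement along the inter-centroid axis (the
linearized distance change); consecutive C-alphas of a chain are always
coupled, with a strengthened constant. Side-chain centroids carry no free
degrees of freedom: their displacement is the exact Jacobian of the
construction,

$$\delta\beta_i \;=\; \delta a_i + \frac{l}{\lVert w_i\rVert}
  \left(I - \hat n_i \hat n_i^{\mathsf T}\right)
  \left(2\,\delta a_i - \delta a_{i-1} - \delta a_{i+1}\right),
  \qquad \hat n_i = w_i / \lVert w_i \rVert,$$

substituted into every coupling. Because this map sends rigid-body motions
of the C-alphas to the corresponding rigid motion of the centroid, the
resulting $3N \times 3N$ stiffness matrix $M$ annihilates all six
rigid-body displacements *exactly*, not merely to rounding -- the property
the zero-mode bookkeeping below relies on. Predicted fluctuations refer to
backbone motion only.

Parameters, with defaults and rationale (`enm_params()`):

* `cutoff` ($R_c$, Angstrom, default 7.5): interaction range between
  centroids. The standard coarse-grained choice; large enough that a
  compact fold is connected, small enough that couplings stay local.
* `k`, `kBT` (model units, both fixed at 1): only mobility *changes* are of
  interest, so fluctuations are expressed on a common adimensional scale;
  RMSF scales as $1/\sqrt{k}$ and calibrating $k$ against B-factors is out
  of scope.
* `cbeta_offset` ($l$, default 3.0 A): distance of the side-chain centroid
  from the C-alpha, a typical C-alpha-to-side-chain-center distance. The
  exact constants of the two-centroid construction vary between
  formulations, so both $l$ and the backbone factor are exposed rather than
  hard-coded.
* `backbone_strengthening` (default 2): multiplier for consecutive-C-alpha
  couplings, expressing that chain connectivity is stiffer than a generic
  non-bonded contact. The published formulation leaves this constant
  unstated; results at the dataset level may shift modestly with it, which
  is why it is a parameter.
* `zero_mode_tol` (default $10^{-9}$, relative): an eigenvalue below
  `zero_mode_tol * max(eigenvalue)` counts as zero. In double precision the
  rigid modes of structures up to ~900 residues sit many orders below the
  softest internal mode, so this separates them cleanly.

Degenerate geometry: if the three supporting C-alphas are collinear the
outward direction is undefined and the side-chain centroid is omitted for
that residue with a warning; coincident interaction centroids are an error.

### Zero modes as a validity filter

A connected elastic body has exactly six zero modes. Extra (near-)zero
modes mean some group of residues moves diffusively -- disconnected chains,
long exposed loops or termini -- which a harmonic model cannot describe, so
`validate_for_enm()` computes the zero-mode count of the complex and of
each monomer alone and declares the dimer suitable only if all three equal
six. The pipeline excludes unsuitable entries with a recorded reason rather
than failing the run, mirroring how such entries are excluded from a
curated dataset.

## Marginalizing the partner, and the subunit frame

With the complex matrix partitioned as
$M = \begin{pmatrix} M_A & G \\ G^{\mathsf T} & M_B \end{pmatrix}$,
canonically integrating monomer B's coordinates leaves a quadratic
effective free energy for A with stiffness the Schur complement
$\tilde M_A = M_A - G M_B^{-1} G^{\mathsf T}$. Two facts make this the
natural object:

* $M_B$ is positive definite exactly when B is internally connected *and*
  coupled to A (the cross-couplings pin B's rigid motions). If the chains
  are not in contact, $M_B$ is singular, the marginalization is physically
  undefined, and `marginalize_partner()` refuses with "partner not coupled"
  instead of regularizing silently.
* The null space of $\tilde M_A$ is exactly the six rigid motions of
  monomer A alone. Removing those modes from the RMSF sum therefore
  measures fluctuations in the *subunit reference frame* -- rigid-body
  motion removed with respect to A's C-alpha trace, not the whole complex.
  This is the default frame, because relative inter-monomer motion would
  otherwise contaminate the per-residue comparison; the conventional
  whole-complex frame is available via `frame = "complex"` for
  complex-level pictures.

The unbound network is *rebuilt* from monomer A's coordinates (side-chain
centroids re-derived, contacts re-enumerated within A only), not obtained
by deleting rows of the complex matrix -- deletion would retain the
partner's contributions to A's diagonal blocks and understate the unbound
mobility. Since the complex energy decomposes as A-internal + B-internal +
cross terms, minimizing over B's coordinates can never fall below the
A-internal energy: $\tilde M_A \succeq M_A^{\mathrm{unbound}}$, and with
identical null spaces the pseudo-inverses order the opposite way, giving
the per-residue guarantee bound RMSF $\le$ unbound RMSF. The test suite
asserts this on every fixture, and cross-checks the whole construction
against two independent routes: exact Gaussian marginalization by full
inversion of random SPD matrices, and a complex-matrix inversion route in
which A's rigid modes are pinned by an explicit projector penalty.

## Accessibility, surface and interface definitions

Solvent-accessible surface areas use numerical sphere-point sampling: each
atom's solvent sphere (van der Waals radius + 1.4 A probe) is sampled on a
deterministic spiral point set (default 960 points/atom) and a point is
accessible if it lies inside no neighboring solvent sphere. The spiral set
was chosen over random sampling so that every result is exactly
reproducible. Radii follow the NACCESS/Chothia convention (C 1.87,
carbonyl C 1.76, N 1.65, O 1.40, S 1.85 A), because the published interface
areas this package is compared against were produced with those radii;
relative accessibility (RASA) divides by extended Ala-X-Ala reference areas
per residue type. Unknown elements fall back to 1.80 A with a warning.

Definitions, with their thresholds:

* **Surface residue**: unbound-form RASA > `rasa_threshold` (default 5%).
* **Semi-interface residue**: ASA loss from isolated monomer to complex
  greater than `delta_asa_min` (default 0.1 A^2). The underlying criterion
  is "any decrease"; the small positive floor only suppresses sampling
  noise. Interface *sizes* are sensitive to this choice, interface *areas*
  are not, so the value is carried in the output attributes of every
  annotation.
* **Interface area**: ASA(A) + ASA(B) - ASA(AB), which equals the summed
  per-residue ASA loss over both chains by construction.

Numerical behavior of the estimator: total areas are stable to well under
1% when the point density doubles. Per-residue areas of solvent-exposed
residues converge to better than 2%; residues that are nearly buried have
areas of only a few sample-point weights, where the relative error is
dominated by discreteness (for the coarse synthetic spheres below, the 2%
figure holds for residues with ASA above ~25 A^2 from about 2000
points/atom). The exactly-coincident-spheres corner case is resolved by an
index tie-break so the degenerate union has the area of a single sphere.

## Secondary structure

DSSP output is consumed, not recomputed: `read_dssp()` parses the classic
fixed-column format (chain breaks skipped, alignment preserved) and
`collapse_ss()` maps the seven states to three -- helix (H, G, I), strand
(B, E), coil (T, S, blank) -- rejecting anything else. For synthetic
fixtures, which have no hydrogen-bond pattern, ideal helices are labeled H
by construction (`synthetic_ss()`), so secondary-structure-grouped figures
remain testable offline.

## Comparative statistics

`summarize_distribution()` reports mean, population standard deviation
(divide by $n$; with hundreds of pooled residues the sample/population
distinction is immaterial, but the convention is fixed and documented),
the fraction of residues below a mobility threshold (default 1.0, an
intermediate mobility on the model scale), and the normalized cumulative
distribution. `scatter_and_fit()` fits the interpolating line of bound (y)
on unbound (x) RMSF per group. The line is constrained through the origin
(slope $\sum x_i y_i / \sum x_i^2$) because slopes are read against the
reference lines $y = x$ (partner leaves intrinsic mobility unchanged) and
$y = x/2$, both of which pass through the origin; a free-intercept fit is
available behind `intercept = TRUE`. `classify_scenario()` assigns A/B/C by
comparing the median (configurable to the mean) of each coordinate with the
threshold; since "small" and "large" are not sharply defined, the statistic
and threshold used are always part of the output.

The analysis population is the first chain of each dimer: for interface
classes where only one semi-interface is shared between cluster members the
first-listed chain is the conserved side, so the subunit frame and all
dataset statistics are defined on first chains throughout.

## What the synthetic generator does and does not emulate

`make_dimer()` produces two connected monomers -- ideal helices, or
self-avoiding 3.8 A-step walks confined to a sphere sized at ~120 A^3 per
residue with a 3.4 A excluded-volume distance -- placed so that the number
of inter-chain C-alpha contacts lands within 20% of a target, with no
cross-chain pair closer than 3.0 A. The generator retries deterministically
(seeded) until the non-bonded contact graph is connected, so every fixture
has the exact rigid-body null-space structure of a compact globular dimer.
For accessibility, each residue is rendered as a single 3.0 A effective
sphere at its C-alpha, which lets the whole accessibility stage run
unmodified on synthetic complexes.

This reproduces the *topological and statistical* structure real dimers
feed into the pipeline: connected monomers sharing a localized contact
patch, six/twelve zero modes, interface size growing with contact count,
bound-unbound softening concentrated at the patch. It does not reproduce
protein realism -- no side chains, no sequence, no secondary-structure
packing, no atomic-scale surface texture. Passing tests therefore certify
the machinery (matrix construction, marginalization identities, ordering
constraints, classification logic), not agreement with any particular real
complex; dataset-level numbers on real structures additionally depend on
the full-atom coordinates and on the elastic constants discussed above.
Default problem sizes in the tests and the acceptance script (monomers of
16-36 residues, six-entry manifests, 240-960 sample points) were chosen as
the smallest sizes at which every property being asserted is
well-separated from its failure mode.

```{r example, fig.width = 6, fig.height = 4, eval = FALSE}
d <- make_dimer(synthetic_dimer_spec(n_first = 30, n_second = 30,
                                     target_interchain_contacts = 15,
                                     seed = 7))
pp <- bound_unbound_profiles(d)
autoplot(pp)

run <- run_pipeline(synthetic_manifest(6, seed = 1), n_points = 480)
autoplot(run$slopes_by_type)
```

## Known limitations

* The elastic constants of the two-centroid construction (side-chain
  offset, backbone factor) follow a standard prescription but are not
  uniquely fixed by the published formulation; dataset-level mobility
  statistics on real structures can shift within a few percent under
  reasonable alternatives. They are parameters, echoed into every output.
* The harmonic model says nothing about anharmonic rearrangements, and the
  unbound form of an obligate monomer is a quenched construct, not a
  prediction of its free-state ensemble.
* Free-energy or entropy differences are deliberately not computed; the
  package stops at mobility comparisons.
* The accessibility stage reads full-atom coordinates as given; it does not
  build missing side chains or hydrogens (hydrogens are ignored).
* PDB input is limited to ATOM records of the two analysis chains, first
  model, highest-occupancy conformers; mmCIF and symmetry-generated
  assemblies are out of scope.
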