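---
title: "A coarse-grained model of direct radiation damage to DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of direct radiation damage to DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgdamage)
```

## Scientific problem

Ionising radiation breaks DNA strands. Isolated single-strand breaks
(SSBs) are repaired efficiently; double-strand breaks (DSBs) — two
breaks on opposite strands within a short stretch, conventionally 10
base pairs — are the biologically critical lesion. Experimentally,
break yields are measured by irradiating supercoiled plasmids and
quantifying the supercoiled (SC), open-circular (OC) and linear (L)
topological forms on an agarose gel: one SSB relaxes a plasmid to OC,
one DSB linearises it.

`cgdamage` implements a coarse-grained (CG) model of *direct* damage:
each nucleotide is reduced to three spherical beads — phosphate,
deoxyribose and base — and a strand break is declared whenever the
energy deposited inside a backbone bead's scoring sphere exceeds a
threshold derived from the bead's internal pair-potential energy. The
package covers the full chain: atomic DNA fixtures, bead construction,
a spherical water phantom, synthetic energy-deposition events, deposit
scoring, break clustering and classification, yield computation, and
the closed-form dose response used to extract yields from gel data.

## Pair potentials and break thresholds

Covalent bonds are modelled with the Morse potential in its standard
well form,

$$U_M(r) = D_e\left[e^{-2\alpha(r-r_e)} - 2\,e^{-\alpha(r-r_e)}\right],$$

which has its minimum $-D_e$ at the equilibrium distance $r_e$ and
dissociates to zero. (An often-quoted variant with a positive sign on
the second exponential does not have these properties; the well form is
the one consistent with the calibrated energies below.) The width is
not a free parameter: it follows from the harmonic force constant,
$\alpha = \sqrt{k_e / 2 D_e}$, with $k_e$ fixed by bond order
($5\times10^5$, $10\times10^5$, $15\times10^5$ dyn/cm for single,
double, triple bonds) and converted to SI before the square root.

Non-bonded contacts inside a cluster use the 12-6 Lennard-Jones form

$$U_{LJ}(r) = 4 D_e\left[(\sigma/r)^{12} - (\sigma/r)^{6}\right],
\qquad \sigma = r_e/2^{1/6},$$

reusing the $(r_e, D_e)$ of the covalent row for the same element pair.

The parameter table (`bond_params()`) holds five rows — C–C, C–O, O–O,
P–O and P=O — with $r_e$ in Å and $D_e$ in eV. The threshold energy of
a bead is the magnitude of the summed pair energies of its atom
cluster at the template geometry:

```{r thresholds}
bond_params()
backbone_thresholds()
```

Two geometry conventions matter here:

* **Phosphate cluster.** The four atoms P, OP1, OP2 and O5' are
  embedded exactly from six calibrated pairwise distances (P–OP1
  1.480, P=OP2 1.482, P–O5' 1.598, OP1–OP2 2.520, OP1–O5' 2.506,
  OP2–O5' 2.463 Å), so the three bonded Morse terms and three
  non-bonded LJ terms reproduce the reference decomposition; the total
  is $-12.3562$ eV, i.e. a 12.4 eV break threshold. Note that the
  widely quoted per-bond value $-3.4339$ eV for P–O5' is inconsistent
  with that total; direct evaluation of the Morse form at 1.598 Å
  gives $-3.4399$ eV, which does reproduce it, so the total is treated
  as authoritative.
* **Deoxyribose cluster.** The seven sugar atoms (C1'–C5', O4', O3')
  are summed together with the two boundary ester bonds that anchor
  the sugar in the backbone: C3'–O3' (internal, since O3' is assigned
  to the sugar) and C5'–O5' (O5' enters only as a boundary atom — it
  contributes its bond, not LJ contacts). With the template sugar ring
  at the equilibrium bond lengths this yields ≈ 32.3 eV, close to the
  ≈ 30.5 eV reference value; the residual difference reflects the
  idealised ring geometry and the exact bond inventory, both of which
  are assumptions rather than calibrated quantities.

Base beads carry **no** threshold: they are not break sites, but they
do compete for deposits in scoring, shielding the backbone.

## From atoms to beads

`build_bdna()` generates idealised B-DNA (rise 3.38 Å, twist 36°/bp,
antiparallel strands) as a straight helix, a closed circle, or a
closed figure-eight with one axis crossing — the latter emulating the
flattened shape of dried supercoiled plasmids. `read_pdb()` /
`write_pdb()` exchange models with standard PDB files via bio3d.

`build_cg_model()` centres each bead on the unweighted centroid of its
cluster and derives its radius from the van der Waals union volume $V$
of the cluster (Monte-Carlo or grid integration over Bondi spheres),
$r = (3V/4\pi)^{1/3}$. The published volumes 0.050, 0.084 and
0.104 nm³ give radii 2.3, 2.7 and 2.9 Å; the template reproduces these
volumes within a few percent, and they can be pinned exactly via the
`volumes` argument. Scoring radii are, by default, the 3.4 Å first
hydration-shell radius for the two backbone moieties (indirect-like
proximity is folded into the direct-damage geometry) and the bead's
own radius for bases; `scoring = "vdwr"` uses bead radii throughout.

## Phantom and tracks

`place_segments()` fills a spherical water phantom with rigid copies
of one or more CG segment models: positions uniform in the sphere,
orientations uniform over rotations, with rejection of any placement
whose cuboid mother volume leaves the sphere or intersects another
(separating-axis test). Form counts are exact, e.g. 90% supercoiled /
10% relaxed. The full-scale configuration — 5400 copies of a 436-bp
plasmid model in a 3 µm sphere — matches a plasmid-irradiation assay's
DNA density; desk-scale runs shrink both numbers.

`generate_events()` is a **parametric surrogate** for a Monte Carlo
track-structure (MCTS) code, not transport physics. Each primary
enters at a uniform point on the sphere with a cosine-law inward
direction (mean chord $4r/3$), deposits points along its chord as a
Poisson process with linear density LET divided by the mean energy per
deposit (default 40 eV), exponential point energies, and a Gaussian
lateral spread (default 2 nm). What it reproduces is the *clustering*
degree of freedom: more energy per unit path means denser deposits and
more correlated opposite-strand hits. What it does **not** reproduce
is the nanometre-scale spur/blob structure of real tracks, in which
deposits arrive in tight clusters even at low LET. Consequently the
absolute LET scale is not comparable to experiment — plausible DSB
counts require higher *nominal* linear densities than physical LET
values — and the package treats the generator's density parameter as a
deposit-clustering ladder on which qualitative trends (SSB/DSB ratio
falling as clustering rises) are asserted. Users with real MCTS output
can inject it through `read_events()` and bypass the surrogate
entirely.

## Scoring, breaks and classification

`score_events()` assigns every deposit to the nearest bead centre
among the beads whose scoring sphere contains it (ties to the lowest
bead id); unassigned deposits still count toward absorbed dose. Energy
accumulates per bead within one event and resets across events —
primaries are independent. A nucleotide breaks when its phosphate *or*
its deoxyribose bead accumulates strictly more than its threshold.

`classify_breaks()` groups the breaks of one event and segment by
single-linkage with a 10-bp window (modular distance on circular
segments) and reports each cluster once, at its most complex class:

| class | meaning |
|-------|---------|
| SSB   | isolated single-strand break |
| SSB⁺  | ≥ 2 same-strand breaks within the window |
| 2SSB  | opposite-strand single-strand lesions farther apart than the window |
| DSB   | one opposite-strand pair within the window |
| DSB⁺  | a DSB plus ≥ 1 extra break in its cluster |
| DSB⁺⁺ | ≥ 2 opposite-strand pairs in one cluster |

Opposite-strand pairs are matched greedily, closest pair first, with a
deterministic tie rule (lower strand-0 position, then lower strand-1
position), each break used at most once. `yields()` converts tallies
to Gy⁻¹ Gbp⁻¹, counting a 2SSB as two single-strand lesions and a
DSB⁺⁺ as two double-strand lesions by default (both multiplicities are
arguments).

## Gel dose response

For a plasmid population with unirradiated fractions $S_0$ (SC) and
$C_0$ (OC), per-plasmid per-Gy yields $\mu$ (SSB) and $\phi$ (DSB),
and pairing probability $\rho$ that two independent SSBs on opposite
strands fall within the DSB window:

$$\mathrm{SC}(D) = S_0\,e^{-(\mu+\phi)D}$$
$$\mathrm{OC}(D) = e^{-\phi D}\left[e^{-\tfrac12\mu^2\rho D^2}(S_0+C_0)
  - S_0 e^{-\mu D}\right]$$
$$\mathrm{L}(D) = 1 - (S_0+C_0)\,
  e^{-(\phi D + \tfrac12\mu^2\rho D^2)}$$

The three fractions sum to one identically. The default
$\rho = 2(2w+1)/n_{bp}$ (window $w = 10$) counts, for a given SSB, the
$2w+1$ opposite-strand positions within the window on either side,
doubled for the two strand assignments, over the $n_{bp}$ positions of
the plasmid — 0.0096 for pBR322 (4361 bp).

`fit_oc()` extracts $(\mu, \phi)$ by nonlinear least squares on the OC
channel alone (the channel sensitive to both parameters), with $S_0$,
$C_0$ read from the zero-dose lane, $\rho$ held fixed, and a
multi-start grid guarding against local minima. `generate_gel_data()`
produces synthetic gels; its noise model is **proportional** by
default — each band intensity is multiplied by $1 + N(0,
\sigma)$ — because densitometry noise scales with band intensity, and
because an additive-noise model induces a small but systematic bias in
$(\hat\mu, \hat\phi)$ through the truncation and renormalisation of
near-zero bands. `per_plasmid_to_per_gbp()` converts fitted yields to
the Gy⁻¹ Gbp⁻¹ unit used by the simulation side.

## Worked example

```{r example}
bt <- backbone_thresholds()
round(bt, 4)

summary_df <- run_pipeline(list(
  n_bp = 40L, n_segments = 4L, phantom_radius_nm = 60,
  form_fractions = c(supercoiled = 0.75, relaxed = 0.25),
  volumes = c(phosphate = 0.050, deoxyribose = 0.084, base = 0.104),
  let_values = c(60, 100), events = 100L, seed = 3L))
summary_df[, c("nominal_LET", "ssb_yield", "dsb_yield", "dose")]
```

## Limitations

* Direct damage only: no radical chemistry, no indirect-damage
  diffusion model (the hydration-shell scoring radius is a geometric
  stand-in), no repair.
* The synthetic track generator has no spur structure; its density
  parameter orders clustering but is not a physical LET axis.
* The nucleotide template is idealised (equilibrium bond lengths,
  generic purine-like base); thresholds inherit that idealisation.
* Problem sizes in examples and defaults (segment counts, event
  counts, sphere radii) are package choices scaled for a desktop; the
  full-scale configuration is available by overriding them.
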