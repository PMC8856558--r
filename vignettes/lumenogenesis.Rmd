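---
title: "Cell-resolved mechanics of bile-duct lumen initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-resolved mechanics of bile-duct lumen initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

lumensim simulates the first day of bile-duct lumen formation around an
embryonic portal vein with a hybrid agent-based model: a deformable cell
model (DCM) resolves the shapes of the cells that line the forming lumen,
and a center-based model (CBM) carries the surrounding endothelium and
far-field hepatoblasts at sphere resolution. This vignette is the
package's own account of the model: the equations, the tunable
parameters, what the synthetic scenarios emulate, the numerical choices,
and the known limitations.

## The deformable cell model

Each deformable cell is a closed, counter-clockwise ring of cortex nodes
joined by viscoelastic elements; the ring is the in-plane cross-section
of a cell in a tissue slab of depth `h_z = 10` um (one cell diameter),
and all areal quantities (adhesion energy, friction, pressures, cortex
modulus) are converted to per-unit-contact-length coefficients with that
depth. Every node obeys an overdamped force balance: node drag times
velocity equals the sum of in-plane elastic, bending, volume, contact
(adhesion and repulsion), migration and osmotic forces. Motion is
restricted to the plane by construction.

The conservative terms are defined through potentials, and the forces
are their exact negative gradients (the test suite verifies this to
1e-6 by central finite differences):

* **In-plane elasticity.** Each element is a linear spring with
  stiffness `E_cor * h_cor * h_z / rest`, i.e. the cortex acts as an
  elastic sheet of modulus `E_cor` (1000 Pa) and thickness `h_cor`
  (500 nm). The elements are *viscoelastic*: the rest length remodels
  toward the current length with the cortical turnover time `tau_ve`
  (600 s), so elastic tension relaxes on the minutes scale while the
  instantaneous response stays elastic. Without this relaxation the
  strong adhesion (`W` = 9e-4 J/m^2) builds up persistent membrane
  tensions of a few nN whose Laplace pressure (on the order of 100 Pa
  across a few-micrometre cavity) would spuriously crush every nascent
  lumen at the physiological pressure scale.
* **Bending.** A turning-angle penalty per node with the regular
  polygon's spontaneous angle; the stiffness derives from the plate
  bending modulus `E_cor h_cor^3/12` over the slab depth. It is small
  compared with the in-plane term, as expected for a thin cortex.
* **Volume control.** The enclosed polygon area `A` is driven toward
  the reference `A_ref` by a pressure `p = K_V (1 - A/A_ref)` applied
  through the exact shoelace area gradient; `K_V` defaults to 1500 Pa,
  the middle of the plausible 750-2500 Pa range.
* **Contact.** Each node interacts with the nearest boundary point of
  every foreign cell (interior projection of the segment distance, or
  the clamped endpoint with the sign resolved by ring containment, so
  the distance field and the cohesive energy are continuous). The
  traction is a smoothed Dugdale cohesive zone over the interaction
  range `h_int = 0.4` um with linear repulsion below contact; each side
  carries half the traction, and the plateau is scaled so that the work
  of separation per unit contact length from the nominal contact plane
  equals the pairwise adhesion energy times the slab depth.
* **Migration.** One zero-mean Brownian force per cell and substep,
  spread equally over the nodes and scaled by the total cell drag so a
  free cell's centroid diffuses with the configured motility
  (`D = 1e-16` m^2/s).
* **Osmosis.** Surface elements marked as bordering the ion-rich
  luminal space carry a constant inward pressure `P_L` (the paper-style
  simplification that the osmotic pressure difference is constant).

Friction is diagonal per node: surfaces within the interaction range of
another cell use the cell-cell coefficient (5e10 Ns/m^3); all other
surfaces use the cell-ECM coefficient (1e8 Ns/m^3). The printed
cell-liquid drag (500 Ns/m^3) is five orders of magnitude below the ECM
value and would only set an irrelevantly fast free-surface relaxation
scale while forcing a microsecond timestep, so the free-surface drag is
`max(gamma_ECM, gamma_liq)`; this also answers how the two coefficients
are switched per element (ECM drag wherever there is no cell-cell
contact).

### Region-dependent adhesion

A polarized cell carries an apical-basal unit vector (ABP) and a planar
polarity unit vector (PCP, perpendicular to ABP). Surface regions are
angular cones around the ABP axis: apical within the half-angle `alpha`,
tight junction within `[alpha, alpha + gamma_tj]`, basal within `alpha`
of the anti-apical direction, lateral elsewhere. `alpha` defaults to
pi/4 so that the apical cone covers the full apical contact face of a
cuboidal packed cell, placing the tight-junction belt exactly
apico-laterally; `gamma_tj` defaults to pi/12.

Per-side adhesion energies are `W_ap` (1e-6 J/m^2) on apical elements,
`W_tj_factor * W` (10x, the "much higher" junctional adhesion) on the
belt, and `W` (9e-4 J/m^2) elsewhere. Because cadherin binding is
homophilic, the pairwise work of separation is the *minimum* of the two
sides: a nearly cadherin-free apical surface cannot be strongly bonded
regardless of its partner. This choice is what lets a lumen lined partly
by cholangiocytes (apical side) and partly by not-yet-differentiated
hepatoblasts open at 10-100 Pa: with a symmetric three-way rule
(apical-apical weak, everything else `W`) the peel threshold of a mixed
interface would be W/P_L = 18 um of opening - unreachable - and no lumen
could ever form next to a hepatoblast.

### Apical constriction

Constriction reduces the equilibrium element lengths: the tight-junction
belt by the circumferential factor (0.6) and the apical domain by the
medioapical factor (0.8); the basal side is untouched. Two
implementation details matter. First, the constricted element set is
material: it is fixed when constriction starts and only re-derived if
the ABP axis rotates by more than 60 degrees, because re-labelling the
patch every step would let cortex material treadmill through the cone
and no net contraction would accumulate. Second, contraction stiffens
the springs (stiffness = sheet modulus / rest length) and, through the
viscoelastic remodeling, is maintained as a persistent strain offset
(rest length tracks current length times the factor). A free ring
cannot hold a wedge shape - tension equilibrates tangentially and the
equilibrium is a circle - so wedging is a tissue effect that appears
when constricted cells are embedded among neighbours; the basal/apical
arc-length ratio above 1 is therefore measured in the bilayer and duct
scenarios, not on isolated cells.

### Tracer particles and osmosis

Secreting cholangiocytes create tracer particles (discrete ion-cloud
markers) at their centroid at a Poisson rate; the particles random-walk
without interacting, may leave their cell only outward through an
apical element that faces open extracellular space, and never cross any
other surface (tight junctions and ordinary contacts block them).
Extracellular particles mark unsealed surface elements within the
capture radius; all unsealed elements within reach of the luminal
particle cloud are refreshed as marked once per event step, and a mark
is cleared when its element is pressed back into sustained contact
(momentary sub-resolution touches do not erase it). Marked elements
carry the constant lumen pressure `P_L`. A particle overrun by a moving
surface is pushed back out if the overlap is shallow and absorbed by
the cell otherwise; particles beyond the domain radius are retired.
The particle kinetics (rate 300/h, D = 1e-11 m^2/s, capture radius
1.2 um, 80 live particles per cell) only control how quickly and
completely cavity walls are recognized as luminal - the pressure
magnitude is always exactly `P_L` - and were chosen so that re-marking
outpaces the surface fluctuation scale of the integrator.

### Growth, division, fate

Cycling cells grow their reference volume linearly from the birth
volume to twice the birth volume over the cycle time `tau` (24 h, cell
variability 10%); quiescent cells do not grow. Division proceeds in
five stages: mitotic round-up (adhesion released, constriction relaxed,
brief in-place relaxation), choice of the division axis (along PCP or
uniform random), two small daughter rings seeded inside the frozen
mother envelope, confined fast growth (200x nominal, substep a third of
the stable step) until the daughters together carry the mother volume,
and envelope removal. Daughters inherit type, polarity, secretion and
constriction competence; cycle times are resampled.

A hepatoblast differentiates after its signalling timer (`T_sig`, 2 h)
runs down; the timer only counts while the cell touches a cholangiocyte
and borders the (possibly very small) lumen - an open surface arc or
direct adjacency to the extracellular particle cloud. Conversion scales
the birth and reference volumes by 0.75 and concentrates the loss at
the apical pole: the apical arc retracts instantly (apical water
efflux through the aquaporin-rich membrane), the cortex is rebased to
the retracted geometry, the nascent pole is osmotically marked (the
exocytosed vesicle content is the initial ion source), secretion and
constriction competence switch on, and the apical vector points to the
free space. This retraction is the microlumen nucleus; without it the
50 Pa osmotic pressure has no cavity to act on, because any unpressurized
void is erased by the tissue within minutes.

The proliferation-rate controller enforces the measured cycling
fractions (26.0% of cholangiocytes, 10.7% of hepatoblasts) every half
hour: the cycling count of each type is driven to floor(f N) plus a
Bernoulli draw on the fractional part. This expectation-preserving
rounding keeps the time-averaged realized fraction at the set-point for
any population size; deterministic rounding would permanently quiesce a
lone founder cholangiocyte (round(0.26) = 0) and overshoot the fraction
whenever N is small. Excess cyclers are quiesced at random; if the
count falls below the set-point, quiescent cells are re-activated
(the set-point is held from both sides).

## The center-based model

Endothelial cells and far-field hepatoblasts are discs obeying a
Langevin equation with cell-ECM drag, pairwise cell-cell drag on the
contact chords, Brownian motility, and Johnson-Kendall-Roberts contact
forces (E = 450 Pa, nu = 0.47). The drag-coupled linear system is
solved per step by Jacobi iteration to a relative tolerance of 1e-4
(absolute 1e-8), with the diagonal solve as the fallback. The classical
JKR law underestimates contact forces at high packing, so a
density-correction multiplier on the elastic part (active above 5%
relative overlap) is calibrated against a deformable-cell pair:
stepwise body forces compress the pair, each step relaxing for 240 s -
short against the cortical turnover time, so the elastic response is
probed - and the measured force-overlap curve fixes the multiplier
table. The calibration makes the force-free CBM pair spacing match the
DCM pair and the compression response agree within the tested range; on
longer timescales the viscoelastic cortex flows and the sphere
approximation only holds statistically. DCM cells see CBM cells as
rigid discs through the same cohesive-zone law, with the reaction
accumulated on the center (exact action-reaction).

## Scenarios

**Idealized bilayer.** Two rows of ten 10-um cells adhering in a free
medium. The central four cells of the upper row are polarized with the
apical vector toward the lower row, and a 0.35-um cleft under them
seeds the pre-existing microlumen (nucleation space from vesicle
exocytosis); its ends are sealed by the adhering flanking interfaces.
Mechanism I (division) keeps the polarized cells quiescent and lets the
four facing cells of the opposite row proliferate without restriction -
the differential-proliferation reading - dividing in the layer plane or
at random angles in the control. Mechanism II switches on apical
constriction in the four polarized cells. Mechanism III makes them
secreting cholangiocytes with the osmotic pressure acting in the
cavity. Construction-defined polarity co-rotates with the cell bodies
instead of chasing free space.

**Portal-vein duct system.** A fixed CBM endothelial ring at
`R_pv = 50` um; a mesenchyme ring around it (10 um cells); two
hepatoblast rows (15 um cells) and two far-field rows beyond; the
120-degree segment around the future lumen is deformable, everything
else center-based, so the segment is laterally confined by
mechanically consistent CBM tissue rather than artificial walls. Rings
are packed tangentially by sampled size with 2% slack, cells are placed
at their age-grown size (so the initial state is near mechanical
reference; placing birth-size geometry under grown references would
start the tissue ~25% over-compressed and swallow any freed volume),
and the system settles for 300 s under the background pressure before
the founder appears. The mid-segment hepatoblast of the inner row is
pre-designated as the founder and is late in its cycle (age 0.9 tau),
matching the observation that the initiating cell divides into the
first cholangiocyte pair soon after differentiation. A constant
background pressure `P_b = 50` Pa loads the outermost decile of
hepatoblasts radially inward. Simulations run for the configured hours
after the founder appears, with events (polarity, regions, growth,
division, differentiation, secretion, marking) every simulated minute,
the controller every half hour and measurements every quarter hour.

Model variants 0-3 toggle division orientation, apical constriction and
osmosis exactly as the feature table prescribes.

## Measurement

The lumen is the largest enclosed extracellular cavity adjacent to at
least one apical element. Its boundary is traced by walking free
surface elements along each ring and jumping across cell-cell contacts
to the partner surface; the walk closes on a cycle, hull-like loops
(containing cell centroids, or counter-clockwise) are rejected, and the
shoelace formula gives the area. Cavities below 1 um^2 are numerical
slack and ignored. If no enclosed cavity is found at the physical
interaction range, passages narrower than 0.8 and then 1.2 um are
treated as closed, so a lumen that transiently leaks through a
sub-cell-scale neck keeps a well-defined boundary. A pixel-rasterization
oracle at 0.1 um resolution checks the traced areas in the test suite.
Apical and basal arc lengths are the summed current element lengths of
the corresponding regions. Ensembles are summarized by the pointwise
mean, a +-2 SD band clipped at zero for areas, and the min/max
envelope (n-1 denominator).

## Numerical choices

Explicit Euler with a per-state stable step: 30% of the smaller of the
free-surface drag/in-plane-stiffness bound and the contact-zone bound,
capped at 0.5 s (typically 0.03-0.09 s). Per-substep displacements are
clamped at 0.1 um (a quarter of the interaction range) so nodes cannot
tunnel through the cohesive zone; neighbour lists use a 2-um skin and
rebuild on half-skin drift. The CBM advances every tenth substep with a
correspondingly larger step (its stability bound is two orders of
magnitude above the DCM's). Tracer moves run every 15th substep with
exact segment-crossing tests, so large steps cannot jump through
membranes. Mechanics substeps run in compiled code; the event layer
(polarity, constriction, growth, division, fate, control, marking)
runs in R every simulated minute. A surface is "open" above a 0.15-um
gap and "sealed" below 0.08 um (with sustained closure required to
clear osmotic marks); these two scales discretize the distinction
between a genuine extracellular cleft and adhesive contact.

Reduced problem sizes used by the test suite and the acceptance script
(36 ring nodes per 10-um cell, a 90-degree deformable duct segment for
the long duct checks, horizons of 2-6 simulated hours, single seeds for
the long runs and 5-seed ensembles for the statistical quantities) are
the package's choices for desk-scale verification; the scenario builders
accept the full-size settings unchanged.

## What the scenarios do and do not show

The synthetic systems emulate the geometry, pressures, adhesion
contrasts, proliferation statistics and differentiation logic of the
early duct; they do not model 3D duct branching or merging, bile flow,
explicit ECM material, hematopoietic cells, or molecular signaling
beyond the single timer. Conclusions about real tissue therefore
concern the mechanical feasibility and interplay of the three
mechanisms, not their molecular control. Two further caveats: first,
an isolated free ring cannot exhibit a stable wedge shape, so
single-cell constriction claims are only meaningful in tissue context;
second, with the osmotic pressure equal to the background pressure the
cavity is near neutral stability, and in this implementation the
balance resolves toward closure in the duct system: the nascent
single-cell pocket is pressurized one-sidedly until its opposing walls
are recognized as luminal, a strongly pressurized wall can invaginate
into its own cell (single-ring self-contact is not modeled), and the
tissue's growth pressure adds to the background load. Within the
simulated horizons the portal-vein lumen therefore does not establish
at 25-100 Pa, and the duct experiments chiefly demonstrate the
differentiation cascade, the proliferation control and the perturbation
logic; the bilayer realizes the constriction-driven (small) and
osmosis-driven (cell-scale, sustained) cavities. A volumetric
(incompressible) luminal content and single-ring self-contact would be
the natural extensions to move the duct's effective pressure threshold
back to the nominal scale.

## Known limitations

* The cross-section is 2D; out-of-plane transport and 3D neck geometry
  are absent, which makes luminal sealing harder than in 3D.
* Tracer particles are volumeless markers: a closing cavity does not
  feel an incompressibility backstop from its content, only the marked
  pressure, so the effective pressure threshold for stable lumen growth
  sits somewhat above the nominal scale.
* The proliferation controller regulates fractions, not spatial
  patterns of cycling cells.
* Self-contact of a single ring is not detected; strongly folded single
  cells are outside the validated regime.
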