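---
title: "Methods: fire-front simulation and fire-safe evacuation routing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fire-front simulation and fire-safe evacuation routing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firevac)
```

## Overview

`firevac` couples two models that are usually run separately in wildfire
emergency planning: a discrete-time simulation of the spreading fire
perimeter over a raster landscape, and a time-dependent router that finds
the evacuation route whose every road junction is still untouched by the
fire at the moment the evacuating vehicle reaches it. The motivating use
case is the evacuation of farm animals (the package's running example is
apiaries in a volcanic red zone), where the planning output of interest is
the *OPERA value* — the number of junctions on the optimal evacuation
route — together with the route itself and the set of junctions the fire
ruled out.

## The fire-spread model

### Effective rate of spread

The front advances locally at

$$\mathrm{ROS}_{\mathrm{eff}} \;=\; \mathrm{ROS}_{\max}\cdot W \cdot S,$$

where $\mathrm{ROS}_{\max}$ (m/h) is the fuel- and humidity-determined
ceiling and $W, S \in [0,1]$ are *limiting* factors for wind and slope:
whatever their form, the effective rate can never exceed the ceiling.

$\mathrm{ROS}_{\max}$ is a per-fuel-class table (Anderson classes 1–13)
modulated by vegetation humidity $h \in [0,1]$:

$$\mathrm{ROS}_{\max}(f, h) = T[f]\,e^{-k h}.$$

The exponential damping is a design choice: it is monotone, bounded, and
controlled by the single coefficient $k$ (`humidity_damping`, default 3,
so $h = 0.23$ roughly halves the rate). The table $T$ ships as data
(`inst/extdata/ros_defaults.json`) with order-of-magnitude defaults —
grass classes fastest (1000–2000 m/h), timber-litter classes slowest
(150–300 m/h) — because the model family this implements prescribes *that*
a fuel table exists, not its values; operational use should substitute
locally calibrated rates.

### Wind and slope factors

The underlying simulation tool family names wind and slope limiting
factors but the published material does not define their functional forms
(they live in unpublished technical references). The shipped forms are
therefore documented stand-ins, swappable via the `wind_effect_fn` /
`slope_effect_fn` strategy slots of `ros_params()`:

* **Wind.** With $\theta$ the angle between the vertex's outward normal
  and the downwind direction, $u = \min(U, U_{\mathrm{sat}})/U_{\mathrm{sat}}$,

  $$W(\theta, U) = 1 - u\,\frac{1 - \cos\theta}{2}.$$

  This is 1 under calm and straight downwind, $1 - u$ straight upwind
  (0 at saturation), and smooth in between. `wind_saturation_speed`
  defaults to 30 000 m/h (30 km/h), a moderate-gale figure beyond which
  additional wind is assumed not to change the *directional shape* further.

* **Slope.** With $g$ the terrain gradient (rise/run, from central
  differences on the DEM) and $d = \max(0, -\,g \cdot \hat n)$ the downhill
  component along the spread direction,

  $$S(g) = 1 - \frac{s\,d}{1 + s\,d},$$

  i.e. uphill spread is unpenalized and downhill spread is damped toward 0
  on ever steeper descents ($s$ = `slope_coefficient`, default 2: a 45°
  descent gives $S = 1/3$). Keeping $S \le 1$ deliberately preserves the
  limiting-factor contract; models in which uphill spread *accelerates*
  beyond $\mathrm{ROS}_{\max}$ would fold that acceleration into the table
  instead.

### Huygens front expansion and polygon maintenance

The burning area is a set of closed vertex rings. Each step of length
`dt` minutes displaces every vertex along its outward normal (the
bisector of the adjacent edge normals, oriented by counter-clockwise
winding) by $\mathrm{ROS}_{\mathrm{eff}} \cdot dt/60$ metres, evaluating
fuel, humidity, wind and slope at the vertex. After displacement the rings
are repaired:

1. all pairwise segment intersections (within and across rings) are
   computed and segments split there;
2. a sub-segment is kept iff it lies on the boundary of the region with
   nonzero winding number (burned on the left, unburned on the right);
3. kept pieces are stitched into closed rings, taking the sharpest left
   turn at ambiguous junctions; clockwise output rings are interior holes
   and are discarded — an enclosed unburned pocket is counted as burned,
   which keeps the burned area monotone;
4. rings are refined to roughly one-cell vertex spacing by splitting long
   edges; existing vertices are never moved, so pure radial growth stays
   exact (this is why the circular-growth check holds to well under 2%
   over 60 one-minute steps).

Two numerical choices deserve note. First, when two fronts touch
*tangentially* there is an instant with no transverse crossing at all; a
ring is then considered contained in another only if *every* vertex lies
inside, because a point-on-boundary winding test is unreliable. The rings
stay separate for that one step and merge cleanly at the next, transverse,
contact. Second, side-of-boundary tests offset the segment midpoint by
$10^{-7}$ of the coordinate scale, far below a cell but far above double
rounding error.

The ignition seed is a regular 16-gon of radius one cell: a point has no
normals, and this is the smallest well-conditioned front. Vertices that
would leave the raster are clipped to the extent with a warning.

### Arrival times

The arrival-time field records, per grid cell, the first step time at
which the cell centre lies inside the burning polygon; never-covered
cells stay nodata. Its resolution is therefore `dt`. This field is the
entire interface between the simulator and the router: the router never
sees perimeter geometry, only "when does this place burn".

## The road network and traffic statistics

The road network is an oriented graph; each directed edge carries length,
free-flow speed and a normalized traffic intensity $\varphi \in [0,1]$.
The published model requires that $\varphi$ determine the likely speed on
the edge but does not give the mapping; the package uses a
Greenshields-style linear degradation $v = v_{\mathrm{free}}\max(1 -
\varphi, 0.05)$, the 0.05 floor keeping saturated edges slow but
traversable rather than infinitely costly.

The classical speed summaries are provided for characterizing speed
samples: the time-mean speed (arithmetic mean over vehicles), the
space-mean speed (harmonic mean — the printed form of its defining
equation is typeset ambiguously in the source material, and is resolved
here as $\Delta t_i = L/S_i$, which makes it algebraically the harmonic
mean; the choice is observable through the AM–HM inequality the tests
enforce), the 85th-percentile speed $S_{85}$ (nearest-rank, so "at most
15% strictly above" holds exactly), and the modal speed $V_{\mathrm{mod}}$
(midpoint of the densest histogram bin, ties toward the lower bin). The
summaries are exposed as descriptive statistics; the router consumes only
$\varphi$ and $v_{\mathrm{free}}$.

## The evacuation router

### Objective

The availability function $\rho(n, t) \in \{0, 1\}$ marks junction $n$
burned at time $t$ when the fire arrival time at (or within
`safety_margin` of) the junction is $\le t$. A route
$n_1, \dots, n_K$ departing at $t_1$ with $t_{k+1} = t_k +$ edge travel
time is *feasible* when $\rho(n_k, t_k) = 1$ and $t_k \le t^\*$ (the
simulation horizon) for every $k$. The objective printed by the source
model sums an indicator over visited junctions, which is ill-typed as
printed (burned junctions cannot be visited at all); it is resolved here,
consistently with the model's worked example ("a route comprising 16
junctions"), as: **minimize the count of visited junctions over feasible
routes**, with ties broken by smaller total travel time, then by smaller
summed $\varphi$. The published "exactly one successor of least traffic
intensity" rule is thus honored as the final tie-break inside a globally
optimal search rather than as a greedy walk, which could miss the global
minimum; the published material itself points to label-setting algorithms
as the solution device.

### Algorithm

`find_opera()` is a label-setting search over labels
(junction, arrival time, node count, $\varphi$ sum), expanded in
lexicographic (count, time, $\varphi$) order. Both count and time strictly
increase along any expansion, so the first label settled at the sink is
the lexicographic optimum. A label is discarded when another label at the
same junction is no worse in all three attributes. Waiting at junctions is
not modelled: $\rho$ only ever degrades, so waiting can never help.
Junctions whose relaxation failed because the fire had arrived are
collected and reported (`plan$rejected`) — the "crossed-out junction"
behaviour of the motivating case study. Infeasibility is a first-class
result (`feasible = FALSE`), never an exception, so batch runs over many
farms complete.

`brute_force_opera()` enumerates all simple paths (guarded to ≤ 12
junctions) under the identical feasibility and tie-break rules and is the
reference semantics; the acceptance suite checks equivalence on 200 random
instances. `validate_plan()` certifies any plan against the graph and
availability function, returning violations as data.

### Properties the tests pin down

* no-fire reduction: with $\rho \equiv 1$ the router returns
  1 + minimum hop count (checked against an independent breadth-first
  oracle from igraph);
* fire-delay monotonicity: scaling all arrival times by $\lambda \ge 1$
  (or removing fire) never increases the OPERA value and never breaks
  feasibility — the feasible set only grows;
* safety: every returned feasible plan passes `validate_plan()` with zero
  violations.

## Exposure analysis

`classify_farms()` classifies farm points against fire footprints
(simulated perimeters or historical burn polygons) by Euclidean
point-to-polygon distance (0 inside): `direct` within 1 km, `indirect`
within 7 km — the maximum flight range of a bee swarm from its hive, so
apiary production is affected even without direct burning — `outside`
beyond. Distances exactly at a radius fall in the inner class; this
boundary convention is asserted by the acceptance tests. The buffers are
drawn as distance-from-footprint (rather than intersecting fixed-radius
discs around farms), the reading consistent with classifying farms by
their distance from "areas directly involved" in fires. Class totals
always sum to the farm count.

## Synthetic data: what it emulates, what it does not

The real inputs of the motivating study — the volcanic-area GIS layers,
the regional fire registry, the road network — were never deposited, so
every fixture is generated: smooth DEMs (flat / constant-gradient ramp /
Gaussian hill), categorical fuel mosaics (one Anderson class per
10×10-cell block), scalar humidity broadcast over the grid, uniform wind
per step, grid-with-jitter road graphs with uniform-random $\varphi$, and
uniformly scattered farms. The default grid is 100×100 cells at 20 m —
the lower bound of the 20–40 m DEM resolution the spread model is
designed for. Each generator draws from a labelled sub-stream of one
master seed, so adding a generator never perturbs existing fixtures, and
fixed seeds give byte-identical outputs.

What a green test therefore establishes: the geometry engine, the
ROS model plumbing, the router's optimality and safety logic, and the
end-to-end pipeline are correct *on landscapes with these statistics*.
What it does not establish: realism of spread rates on real fuels, real
road-network topology effects, or the study's site-specific results
(which would require the undeposited registry data). The bundled demo
places the ignition on the central junction of a 5×5 road grid so that
the router provably has to reject at least one junction and detour; it is
a workflow analogue, not a reproduction.

## Numerical choices and limitations

* Arrival times are quantized to `dt`; a junction "burns" at the first
  step its cell centre is covered. Sub-step timing is out of scope.
* $\rho$ is node-based: an edge is traversable iff its head junction is
  safe at arrival there; mid-edge burn-over is not modelled (the
  availability function's domain is junctions × time).
* Holes in the burned region are discarded by design (monotone burned
  area); unburned islands are not tracked.
* The simulator is fully deterministic — all stochasticity lives in the
  fixture generators.
* GeoTIFF input is not supported in this build (no GeoTIFF-capable R
  package in the supported dependency set); ESRI ASCII grids are the
  raster interchange format, and the reader rejects grids that are
  plausibly in geographic degrees, since all model quantities are metric.
* No reprojection: all layers must already share one metric CRS and one
  grid, and this is validated.
* Spotting, crown-fire transitions, fuel-moisture dynamics, suppression,
  vehicle capacities and multi-vehicle scheduling are out of scope.

## A worked run

```{r demo}
res <- run_case_demo(seed = 1)
res$plan
attr(res$exposure, "totals")
```

The plan's junction count is the OPERA value; `rejected` lists junctions
the fire ruled out during the search; `validate_plan()` on the returned
plan is empty by construction and re-checked in the test suite.
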