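# biopsam

Agent-based simulation of tumour-immune biopsies with spatial agreement
scoring.

## What it is for

In early-phase oncology trials, paired tumour biopsies — one at baseline,
one on treatment — are digitised and the positions of cytotoxic CD8+ T cells
are extracted by image analysis. The on-treatment sampling day is usually an
expert best guess. `biopsam` supports making that choice quantitatively: it
turns a baseline CD8 cell map into a lattice initial condition, simulates
tumour-immune dynamics forward with a stochastic agent-based model, and
scores how well simulated tissue reproduces observed on-treatment tissue.
Calibrated against paired samples, the model predicts the full time course
of the CD8 spatial distribution, which helps schedule biopsies and explore
hypothetical combination treatments.

The audience is computational biologists and pharmacometricians working
with digital-pathology point patterns.

## The model and the score

**Model.** Tumour and immune (CD8) cells occupy a periodic 100 × 100 lattice
with single occupancy. Per daily step, each agent (in random order) may die,
divide into a free Moore neighbour (finite proliferation capacity; 20% of
tumour cells are stem cells), and migrate; immune cells additionally attack
adjacent tumour cells — a tumour cell survives `TUintmax` attacks before
dying — and perform a biased random walk toward the nearest tumour cell.
Fresh immune cells flow in stochastically. The thirteen parameters (IMpprol,
IMpkill, IMpdeath, IMrwalk, TUpprol, TUpmig, TUpdeath, TUpmax, TUintmax,
IMpmax, IMpmig, IMinfluxProb, IMinflRate) carry literature defaults; the
four immune ones are calibrated.

**Score.** The CD8 pattern on a tile is summarised by the lattice radial
distribution function g(j): the normalised density of CD8 pairs at Chebyshev
distance j = 1..M (M = 50 on a full tile), flat at 1 under complete spatial
randomness. With observed RDFs `Ro` (rows = on-treatment tiles) and
simulated RDFs `Rs` (rows = baseline tiles × repeats), each distance gets an
acceptance envelope

    u_j = max_i Ro_ij + 0.2 · range_i Ro_ij
    l_j = max(min_i Ro_ij − 0.2 · range_i Ro_ij, 0)

and with A_j the proportion of simulated rows strictly inside [l_j, u_j],

    SAM    = #{ j : A_j ≥ threshSAM } / M
    VarSAM = min( range(Rs|j≤15) / range(Ro|j≤15),
                  range(Ro|j≤15) / range(Rs|j≤15) ).

A comparison is accepted when SAM > 0.7 and VarSAM > 0.3. Rejection
calibration samples candidate parameter sets, gives each a vote per patient
that accepts it, and keeps sets whose votes exceed 22/37 of evaluable
patients. A last-observation-carried-forward benchmark (baseline predicts
on-treatment) sets the bar a mechanistic model must clear.

## Worked example

```r
library(biopsam)

# a synthetic biopsy: clustered CD8 pattern plus detected tumour cells
cm <- generate_cellmap("clustered", n_cd8 = 180, L = 100, seed = 11)
cm
#> cellmap: 680 cells on a 100 x 100 lattice (cell width 5 um)
#>           cd8    cd8_prolif tumour_prolif
#>           147            33           500

# tile it, back-fill tumour to 70% density, draw per-cell properties
tile  <- populate_tumour(extract_tiles(cm)[[1]], seed = 12)
tile
#> tile 100x100 at (1, 1): 6820 tumour, 180 immune, tissue fraction 1.000
props <- assign_properties(tile, seed = 13)

# simulate 20 days and read the daily counts
traj <- simulate_tile(tile, props, model_params(seed = 14), end_day = 20)
data.frame(day = traj$day, n_cd8 = traj$n_cd8, n_tumour = traj$n_tumour)[c(1, 5, 10, 20), ]
#>    day n_cd8 n_tumour
#> 1    1   186     8150
#> 5    5   193     9261
#> 10  10   189     9303
#> 20  20   201     9181

# score simulated repeats against "observed" day-20 tiles
obs <- lapply(1:4, function(i) simulate_tile(tile, props,
              model_params(seed = 20 + i), end_day = 20)$final$grid)
sim <- lapply(1:8, function(i) simulate_tile(tile, props,
              model_params(seed = 40 + i), end_day = 20)$final$grid)
sam_score(rdf_matrix(obs), rdf_matrix(sim))
#> sam_score: SAM 0.960, VarSAM 0.982, accepted = TRUE
```

The counts show a tumour held near carrying capacity with a slowly growing
CD8 compartment; the score says that at 96% of inter-cell distances the
simulated RDFs fall inside the observed envelope, with well-matched
short-range variability — stochastic repeats of the same dynamics are, as
they should be, in spatial agreement.

For calibration, `sample_parameter_sets()` + `calibrate()` +
`select_parameters()` run the rejection loop, `locf_benchmark()` the null
reference and `validate()` the holdout accuracy; `generate_paired_cohort()`
builds ground-truth cohorts for all of them.

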