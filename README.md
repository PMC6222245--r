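# seegplan

Experience-based planning of SEEG electrode trajectories in R.

StereoelectroencephaloGraphy (SEEG) implants many intracerebral electrodes
to localise the epileptogenic zone. Trajectory *optimisers* refine
individual electrodes against safety constraints, but they need an initial
electrode set to start from — and that choice encodes the implanting
centre's experience. `seegplan` mines retrospective plans into a model of
that experience and uses it to initialise plans for new subjects. It is
aimed at researchers in computer-assisted neurosurgery and at centres that
keep a database of past implantations.

## The method

Given plans *p_j* = {tr_1, …, tr_E} of previously implanted patients, an
atlas label volume in a common average space, and per-patient affine
registrations (subject → average):

1. **Descriptors.** Each trajectory gets a descriptor
   *d = [Z_EP^a; Z_TP^b]* — the first admissible entry zone and the deepest
   admissible target zone it traverses, after configurable label merges
   (e.g. hippocampus + para-hippocampus; putamen folded into the insular
   zone) and exclusions (ventricles, brain stem, cerebellum → outliers).
2. **Exploratory patterns & mean trajectories.** Same-descriptor
   trajectories pooled across patients form patterns *pt_{a,b}*. Each
   pattern is compressed by k-means on joint (EP, TP) coordinates, starting
   at *k = U_{a,b}* (the most same-descriptor electrodes any one plan used)
   and decrementing *k* until every cluster holds ≥ 5 % of the pattern.
   Each final cluster is a mean trajectory *mT* with centroid EP/TP and RMS
   dispersions σ_ep, σ_tp.
3. **Planning strategies.** Each plan becomes a boolean vector *f_j* over
   the mT list; plans are clustered hierarchically under the Jaccard
   distance and the dendrogram cut at a threshold; each group keeps the
   bits supported by ≥ 2 member plans, giving strategies *cl_g*.
4. **Initialisation & validation.** A chosen strategy is mapped through the
   inverse of a new subject's affine. Against a manual plan, trajectories
   are paired by minimum-cost assignment and a pair is *correctly mapped*
   when d_ep ≤ 2σ_ep and d_tp ≤ 2σ_tp.

A synthetic-cohort generator with known ground truth (planted mean
trajectories, strategies, noise, random per-subject affines, and a
block-structured label volume) makes every stage testable end to end; see
`vignette("experience-based-planning")` for the full methods account.

## Worked example

Build a model from a simulated 40-patient cohort and initialise a plan for
a held-out subject:

```r
library(seegplan)

spec   <- cohort_spec(n_plans = 50, seed = 7)   # 4 strategies, 12 planted mTs
cohort <- generate_cohort(spec)
train  <- cohort$plans[cohort$plans$patient_id %in% sprintf("P%03d", 1:40), ]

model <- build_model(train, cohort$affines, cohort$atlas,
                     cohort$zone_config, seed = 1)
model <- add_strategies(model, cut_threshold = 0.45)
model
#> <seeg_model> 12 mean trajectories, 8 patterns, 4 strategies, 40 plans

head(mt_table(model)[, c("mt_index", "entry_zone", "target_zone", "index_u",
                         "n_members", "sigma_entry", "sigma_target")])
#>   mt_index entry_zone target_zone index_u n_members sigma_entry sigma_target
#> 1        1   entry-01     deep-01       1        30    3.544470     3.158302
#> 2        2   entry-01     deep-01       2        29    3.609104     3.394571
#> 3        3   entry-02     deep-02       1        30    3.774559     3.267217
#> 4        4   entry-03     deep-03       1        29    3.307164     3.517195
#> 5        5   entry-03     deep-03       2        28    3.321843     3.573600
#> 6        6   entry-04     deep-04       1        28    3.005289     3.235282
```

The model found 8 exploratory patterns; patterns explored with two
electrodes in one plan (e.g. `entry-01 → deep-01`) yield two mean
trajectories (`index_u` 1 and 2). Each σ is the RMS spread of the ~30
member trajectories around the centroid, in mm — under 2 mm-per-axis
positional noise the expected value is 2√3 ≈ 3.46 mm.

Initialise the held-out subject P041 from strategy `S1` and score the
mapping against their manual plan with the 2σ criterion:

```r
ip     <- init_plan(model, "S1", cohort$affines[["P041"]], patient_id = "P041")
manual <- cohort$plans[cohort$plans$patient_id == "P041", ]
report <- validate_mapping(match_trajectories(ip, manual, model), model)
report
#> <validation_report> 9 pairs, fraction mapped = 1.000

head(report$pairs[, c("mt_index", "electrode_id", "d_ep", "d_tp",
                      "sigma_ep", "sigma_tp", "pass")], 4)
#>   mt_index electrode_id     d_ep     d_tp sigma_ep sigma_tp pass
#> 1        1          E04 4.333919 2.430326 3.544470 3.158302 TRUE
#> 2        2          E01 2.401601 4.311654 3.609104 3.394571 TRUE
#> 3        3          E07 5.814008 3.223891 3.774559 3.267217 TRUE
#> 4        7          E02 3.297731 2.234951 3.595822 3.969122 TRUE
```

All nine mapped trajectories land within twice the model dispersion of the
surgeon's corresponding points, so this subject's plan is fully covered by
the strategy.

The same pipeline is available from the shell via the wrapper installed at
`system.file("cli", "seegplan", package = "seegplan")`, with subcommands
`simulate`, `build-model`, `cluster-strategies`, `init-plan`, `validate`
and `metrics`.

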