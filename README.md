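# proxnet

Communities are multiplex: the same people are simultaneously embedded in
several role-specific social networks (a farming workgroup, family
households, the crowd that passes through a community hall), and any single
snapshot of "who was near whom" superposes all of them. proxnet extracts
those layers from long-term wearable-device proximity logs and relates each
participant's position in each layer to self-reported attitudes and health.

It is written for field studies that log Bluetooth-style device detections:
every record says *device A heard device B at time t*. The pipeline is

1. **Contact matrix.** Detections are binned into epochs (default 30 min)
   and unordered participant pairs (dyads), giving a nonnegative count
   matrix **Y** (I epochs × J = N(N−1)/2 dyads).
2. **Factorization.** **Y ≈ HU** with **H** (I×K) and **U** (K×J)
   nonnegative, fitted by multiplicative updates for the Euclidean
   objective ‖Y − HU‖²_F. Column k of **H** is subnetwork k's activity
   time series; row k of **U** its dyadic tie weights. The rank K is
   selected from the residual sum of squares and the cophenetic
   correlation coefficient of consensus clustering over random restarts.
3. **Subnetwork graphs.** Each **U** row becomes a weighted undirected
   graph on the participants; positions are scored by eigenvector
   centrality (max-normalized, then log-transformed so the most central
   participant scores 0.00).
4. **Survey scales.** Companion self-report scales are scored with
   PCA-loading-based item retention, Cronbach's α, McDonald's ω, and
   composite means; log centralities and composites meet in a Pearson
   correlation table with †/*/** significance flags (p < .10/.05/.01).
5. **Synthetic ground truth.** A planted-subnetwork generator (event-spike,
   diurnal, and weekday-hub activity layers) produces detection logs,
   contact matrices, and surveys with known structure, so every stage is
   testable without access to sensitive field data.

## Worked example

```r
library(proxnet)

# simulate a community with 3 planted subnetworks over six weeks
truth <- generate_truth(default_scenario(), seed = 42)
Y <- observe_contacts(truth, noise_model = "rounded")
Y
#> contact_matrix: 2016 epochs x 435 dyads (30 participants), 49440 nonzero cells

# factorize and score recovery of the planted subnetworks
model <- multistart_fit(Y, K = 3, n_starts = 5, base_seed = 1)
model
#> factor_model: K = 3, objective = 649.952, 170 iteration(s) (converged), seed 4
rec <- evaluate_recovery(truth, model)
round(rec$u_cor, 3)
#> [1] 0.998 0.968 0.970
```

Matched tie-weight correlations near 1 mean the three planted layers were
recovered almost exactly. Centralities and the survey link:

```r
ct <- centrality_table(model, truth$dyads)
k1 <- rec$assignment[1]   # fitted factor matched to the event-spike layer
head(ct[, c("participant_id", paste0("raw_", k1), paste0("log_", k1))], 3)
#>   participant_id        raw_2     log_2
#> 1            p01 1.000000e+00   0.00000
#> 2            p02 1.124459e-14 -13.81551
#> 3            p03 1.124459e-14 -13.81551

survey <- generate_survey(truth, seed = 42)
cb <- load_codebook()
vars <- data.frame(
  farming       = ct[[paste0("log_", k1)]],
  pro_community = composite_score(survey, scale_items(cb, "pro_community")))
print(correlate(vars))
#>               farming pro_community
#> farming       -       0.94**
#> pro_community 0.94**  -
```

Participant p01 is maximally central in the event-spike subnetwork (raw 1,
log 0.00); non-members sit at the log floor ln(10⁻⁶) ≈ −13.82. The planted
positive effect of event-layer centrality on the pro-community composite is
recovered as r = 0.94 (p < .01).

## Command line

```sh
Rscript -e 'quit(status = proxnet::proxnet_cli())' simulate --config cfg.json
Rscript -e 'quit(status = proxnet::proxnet_cli())' fit      --config cfg.json
Rscript -e 'quit(status = proxnet::proxnet_cli())' report   --config cfg.json
```

One JSON config drives all stages (`paths`, `epoch`, `nmf`, `centrality`,
`survey`, `scenario`, `seed`); flags `--seed/--out/--k/--k-range` override
it. Exit codes: 0 success, 1 config error, 2 I/O error, 3 numerical
failure. Every run writes a `manifest.json` (seed + config hash).

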