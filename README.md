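# ppmir

Continuous-time estimation of the **mutual information rate (MIR)** between
two point processes — processes described entirely by event times, such as
heartbeats (ECG R peaks) and the arrival times of the arterial pressure
wave at the periphery. The package targets the short, noisy records typical
of cardiovascular variability work (a few hundred events), where naive
estimates of information rates are strongly biased.

## The method

For two point processes $X = \{x_i\}$, $Y = \{y_j\}$ with no simultaneous
events, the MIR decomposes into the two directed transfer entropy rates
(TER):

$$\dot I_{X;Y} \;=\; \dot T_{X\to Y} + \dot T_{Y\to X},$$

and each TER is estimated from four nearest-neighbor entropy terms over
inter-event **history embeddings** (length-$l$ vectors of recent intervals,
observed either at target events or at random time points):

$$\hat{\dot T}_{Y\to X} = \bar\lambda_X\,[\hat H_{p_u}(J) - \hat H_{p_x}(J)
  + \hat H_{p_x}(m) - \hat H_{p_u}(m)],$$

with $\bar\lambda_X$ the mean target event rate, $J$ the joint embedding,
$m$ its target-only part, $p_x$/$p_u$ the at-event / at-random-time
sampling distributions, maximum-norm distances and $k = 30$ neighbors. In
the default shared-radius combination the radius-dependent terms cancel
per sample point and the bracket reduces to averaged digamma functions of
local neighbor counts.

Because short records bias the MIR downward, the package also computes the
**corrected MIR (cMIR)**: the median MIR over $M$ surrogate pairs
consistent with the uncoupled null hypothesis is subtracted from the MIR
estimate, and the surrogate distribution's 95th percentile provides a
significance test. Four surrogate engines are available: local permutation
of history embeddings, interval shuffling, IAAFT, and an
autocorrelation-preserving interval permutation.

Built-in simulators generate all study inputs: uncoupled renewal processes
(exponential / Gaussian / inverse Gaussian intervals), a history-dependent
inverse Gaussian (HDIG) heartbeat model coupled to AR(2) pulse-arrival
delays, and a common-driver variant in which the same low-frequency
process drives both series.

## Worked example

```r
library(ppmir)

# simulate 300 heartbeats and their pulse arrival times (sd of delays 10 ms)
x <- simulate_hdig(hdig_params(), 300, seed = 1)        # heartbeat process
y <- simulate_pat_process(x, pat_params(0.010), seed = 2)

est <- cmir(x, y,
            estimator_config(k = 30, l = 5, seed = 3),
            surrogate_config(method = "local_permutation", M = 100, seed = 4))
est
#> cMIR: 0.4361 nats/s (MIR 0.6414 - surrogate median 0.2052; local_permutation, M = 100)
#>   significant vs 95th surrogate percentile (0.2469): TRUE
```

The MIR of 0.64 nats/s says the two event streams share about two thirds
of a nat per second at this embedding length; the surrogate median (0.21
nats/s) is the part attributable to estimator bias plus what the
conservative local-permutation null retains, leaving a corrected cMIR of
0.44 nats/s, significant against the 95th surrogate percentile. Real
recordings enter the same pipeline through
`read_events()` (one timestamp per line, `#` comments) and the per-record
workflow:

```r
report <- analyze_pair("r_times.txt", "systolic_times.txt", l_grid = 1:5)
```

which returns RR/PAT interval statistics and a cMIR sweep over embedding
lengths, serializable to JSON. A thin command-line wrapper is installed at
`inst/cli/ppmir.R` (`estimate`, `simulate`, `experiment` subcommands).

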