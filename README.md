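# orderica

Ordering independent component analysis: blind source separation with a
**unique, globally ordered** solution.

Classical ICA estimates the model **X = A S** — N observed channels
(e.g. EEG electrodes) as an invertible linear mixture of N mutually
independent, non-Gaussian sources — but its solutions are notoriously
unstable: the objective is non-convex, so every run can land in a
different local optimum, and even the global solution is only defined up
to row permutation and sign. `orderica` implements a deflation FastICA
variant that removes both problems. For whom: anyone who needs ICA
decompositions that are reproducible across runs — EEG artifact and
component analysis being the motivating application.

## The method

Signals are whitened, then components are extracted one at a time under
Gram–Schmidt orthonormality. For component *i* the objective is

&nbsp;&nbsp;&nbsp;&nbsp;Φᵢ = Υ(αᵢ),&nbsp;&nbsp;&nbsp;
Υ(α) = α − 2 log(α/2 + 1),

where αᵢ = Σₘ yᵢₘ⁴/M − 3 is the excess kurtosis of the candidate
projection yᵢ = wᵢᵀX̃. Υ is strictly convex with its minimum 0 at the
Gaussian (α = 0), so its global maximum over the constraint set is
attained at a local extremum of the kurtosis — exactly what each
kurtosis fixed-point (FastICA) run finds:

&nbsp;&nbsp;&nbsp;&nbsp;w ← X̃ (y∘y∘y)ᵀ/M − 3w, then deflate and
normalise.

Launching L independently seeded restarts per component and keeping the
converged candidate with the highest Υ(α) therefore finds the per-step
global optimum with overwhelming probability, and the components emerge
in **descending order of Υ** — a unique solution (up to sign), provided
the sources are normalised, independent, non-Gaussian and none is the
symmetric two-point variable (excess kurtosis −2, where Υ is
undefined). The restarts are embarrassingly parallel; L defaults to
`cores × R` with overhead rate R = 1, K = 30 iterations and ε = 10⁻⁶.

The package also provides the matching stability toolkit: the
divergence δ = 1 − |cos| between runs, per-component mean fluctuation
δ̄(i), restart success rates μ̄ᵢ = #Ξ/L_max, the failure-rate model
νᵢᵉᵃᶜʰ = (1 − μᵢ)ᴸ with its total-failure recurrence, the log₁₀–log₁₀
regression of μ on Υ, and the analytic bound (1 − 10⁻¹·⁵)ᴸ for strongly
non-Gaussian components — plus a ground-truthed synthetic source
generator (Laplace, uniform, Gaussian, generalized Gaussian, bimodal
mixtures, Student t) so all of the above is testable without any
external dataset.

## Worked example

```r
library(orderica)
gt  <- synthesize_mixture(c("laplace", "uniform", "gaussian"), 20000, seed = 3)
fit <- ordering_ica(gt$x, l_candidates = 64, seed = 3)
fit
#> Ordering ICA fit: 3 components (L = 64, K = 30, eps = 1e-06, seed = 3)
#>  component  kurtosis    upsilon converged
#>          1  2.709700 0.99675000        64
#>          2 -1.191100 0.61937000        64
#>          3  0.024831 0.00015288        64
```

The three sources have true excess kurtosis 3 (Laplace), −1.2
(uniform) and 0 (Gaussian), i.e. true scores Υ = 1.1674, 0.6326, 0 —
the fit extracts them in exactly that order, with sample kurtosis close
to the truth and all 64 restarts agreeing at every step. Recovery
against the known mixing matrix:

```r
rs <- recovery_score(fit, gt)
round(rs$scores, 4)      #> 1.0000 0.9999 0.9999   (|cosine| to true directions)
rs$order_agreement       #> TRUE
```

And the closed-form reliability bound for strongly non-Gaussian
components (Υ > 10):

```r
analytic_failure_bound(c(128, 256))
#> 0.0163570305 0.0002675524
```

## Command line

The same stages are available as subcommands of the installed
executable (`exec/orderica`):

```sh
orderica simulate --families laplace,uniform,gaussian --samples 20000 \
         --seed 3 --output-dir sim
orderica whiten   --input sim/X.csv --output sim/Xw.csv --model sim/model.json
orderica run      --input sim/X.csv --candidates 64 --seed 3 --output-dir run1
orderica fluctuation  --runs run1,run2 --output delta.csv
orderica success-rate --input sim/X.csv --candidates 1000 --output-dir sr
```

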