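---
title: "The retrotransposon energy-balance model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The retrotransposon energy-balance model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`rtebalance` implements a coarse-grained kinetic model of the energy balance
of a human (HeLa-like) cell that carries transcriptionally active
retrotransposons: the autonomous LINE-1 (L1), which encodes the ORF1p and
ORF2p proteins of its own reverse-transcription machinery, and the
nonautonomous Alu, which parasitizes L1's ORF2p. Because Alu competes with
L1 mRNA for the reverse transcriptase, the two elements form a
predator-prey-like pair in which Alu restrains L1 abundance.

Twelve ordinary differential equations track molecule counts per cell
(m.p.c.): free ATP $a$; housekeeping mRNA $m_q$, mRNA-ribosome complexes
$c_q$ and protein $q$; L1 and Alu mRNAs $m_L$, $m_S$; the L1 mRNA-ribosome
complex $c_L$; ORF1p ($O_1$); the reverse-transcriptase complexes $b_L$
(ORF2p with L1 mRNA) and $b_S$ (ORF2p with Alu mRNA); and the genomic
counts $L$ and $S$ of actively transcribed L1 and Alu copies.

ATP obeys a single balance:

$$\frac{da}{dt} = A_0 - \lambda_a a - v_{\mathrm{repl}}
  - N_{nt}\,(N_Q\,\omega_q + N_L\,\omega_L + N_S\,\omega_S)
  - N_{aa}\,(N_q\,v_q + \tfrac{N_L}{3}\,v_L)
  - N_{nt}\,(N_L\,v_{\mathrm{int}L} + N_S\,v_{\mathrm{int}S})$$

with a constant influx $A_0$, first-order turnover $\lambda_a a$, the DNA
replication cost
$v_{\mathrm{repl}} = N_{nt}(N_g/\tau + N_L v_{\mathrm{int}L} + N_S v_{\mathrm{int}S})$,
and per-nucleotide ($N_{nt}$) and per-amino-acid ($N_{aa}$) costs for
transcription, translation and retrotransposon insertion. Note that the
nucleotide cost of newly inserted copies is charged twice — once inside
$v_{\mathrm{repl}}$ and once in the final bracket; the budget decomposition
reports the two as separate categories (`replication_insertions` and
`insertion_*`) because that is exactly how the balance equation spends
them.

Every ATP-consuming rate carries a Michaelis-Menten factor $a/(K + a)$, so
each process saturates at high energy and shuts down as ATP is depleted.
The elementary rates are:

* transcription, per active copy: $\omega_X = X\,w_X\,a/(\theta_X + a)$ for
  $X \in \{Q, L, S\}$ (housekeeping genes transcribe from a fixed count
  $Q$);
* ribosome binding/unbinding by mass action with the free pool
  $f_{\mathrm{rib}} = r_{\mathrm{tot}} - c_q - c_L$;
* translation: $v_q = (\gamma_{\max q}/N_q)\,c_q\,a/(K_{\gamma q}+a)$ and
  $v_L = (\gamma_{\max L}/(N_L/3))\,c_L\,a/(K_{\gamma L}+a)$ — the
  elongation rate in aa/min divided by the protein length gives the
  per-complex protein production rate, and the combined L1 protein output
  is measured by the L1 nucleotide length over three;
* the reversible substitution $b_L + m_S \rightleftharpoons b_S + m_L$
  (ORF2p is not a separate variable, so Alu captures the reverse
  transcriptase by swapping mRNAs in the complex);
* insertion:
  $v_{\mathrm{int}L} = (\chi_{\max L}/N_L)\,b_L\,\frac{a}{K_{\chi L}+a}\,
  \frac{K_L O_1}{1 + K_L O_1}$ (single-nucleotide incorporation rate scaled
  to the full element, with an ORF1p occupancy factor) and
  $v_{\mathrm{int}S} = (\chi_{\max S}/N_S)\,b_S\,a/(K_{\chi S}+a)$;
* first-order degradation of every species; for $L$ and $S$ the
  "degradation" constants $\lambda_L$, $\lambda_S$ are deactivation rates —
  transitions of genomic copies into silenced chromatin.

Two formula readings deserve a note because the printed units are
ambiguous. First, the translation and insertion maxima are *divided* by the
product length ($\gamma_{\max}/N$, $\chi_{\max}/N$); this reading
reproduces the published stationary ATP balance term by term (the influx
$A_0 \approx 1.31\times10^{10}$ m.p.c./min is recovered to a few percent)
and balances each species' production against its first-order loss at the
published stationary counts. Second, the bimolecular constants $k_{bq}$,
$k_{bL}$, $k_{\mathrm{sub}S}$, $k_{\mathrm{sub}L}$ are tabulated with
first-order units but multiply products of two concentrations; they are
treated as second-order constants, 1/(m.p.c. min).

## Parameters

All ~45 constants ship as `model_parameters()` defaults, in m.p.c. and
1/min units. Most are literature anchors (genome size, cell-cycle length,
ribosome count, elongation rates, per-residue ATP costs); eleven rate
constants with no direct measurement — ribosome binding/unbinding,
mRNA substitution, ATP turnover $\lambda_a$, complex degradation, and the
deactivation rates $\lambda_L$, $\lambda_S$ — are free parameters whose
published values were obtained by fitting the stationary ATP, L1 and Alu
counts to wild-type targets ($a_{wt} = 5.33\times10^9$, $L_{wt} = 1064$,
$S_{wt} = 13243$ m.p.c.). The parameters that matter most for the package's
headline results are:

* $w_L$ (1/min), the maximum per-copy L1 transcription rate, and
  $\lambda_L$ (1/min), the L1 deactivation rate. The stationary state
  depends on them only through the ratio $w_L/\lambda_L$ (see below).
* $\lambda_a = 1.47$/min, ATP turnover: together with $A_0$ it sets the
  energy scale and dominates the sensitivity ranking.
* the 30% threshold fraction in the drop metrics, the reported marker for
  cell-death initiation; it is an argument (`threshold_fraction = 0.30`)
  everywhere, not a hard-wired constant.

## Numerical choices

**Integration.** The system is stiff (time scales from $\sim$0.04 min ATP
dips to the $1/d_q \approx 1760$ min protein turnover), so trajectories use
the Radau method (`deSolve::radau`) with the analytic Jacobian, relative
tolerance $10^{-8}$ and per-variable absolute tolerances of $10^{-6}$ times
each variable's reference scale. The right-hand side is evaluated on
`max(state, 0)`; trajectories are validated post hoc and any excursion
below $-10^{-6}$ of a variable's scale voids the run. The free ribosome
pool is clamped at zero so binding fluxes stay nonnegative during extreme
transients.

**Steady states.** `find_steady_state()` integrates over doubling horizons
until the relative state change over a doubling falls below $10^{-10}$,
then polishes with a damped, column-scaled Newton iteration on the
right-hand side using the analytic Jacobian. Direct root finding from cold
starts is unreliable here because the variables span twelve orders of
magnitude. The residual norm is the maximum over equations of
$|dx_i/dt|$ relative to the gross (production plus consumption) flux of
that equation; convergence requires $\le 10^{-9}$. Equations whose gross
flux is below $10^{-12}$ of the system's largest flux are treated as
numerically stationary — in degenerate limits (e.g. all gene counts sent to
zero) entire pathways collapse to denormal scale where the ratio is
meaningless.

**The retrotransposon-free subspace.** The set $\{m_L = c_L = O_1 = b_L =
L = 0,\; m_S = b_S = S = 0\}$ is invariant, and the silenced state inside
it is locally stable, with a small basin: its linear modes decay, but
states with even a few active copies re-grow to the reference state. Two
consequences shape the numerics. Warm-started Newton solves can be dragged
onto this other root by the nonnegativity clamp, so a polished state that
moved any significant variable by more than a factor of 30 from its warm
start is discarded in favor of integrate-then-polish. And randomized
uniqueness sweeps integrate with tightened tolerances (rtol $10^{-10}$,
atol scale $10^{-10}$), because cold starts traverse deep transient troughs
in the L1 variables which looser absolute tolerances truncate to exact
zero, stranding the trajectory on the invariant subspace. With these
guards, 20 log-uniform random starts within $\pm$2 decades of the
reference (the sweep's start distribution is this package's choice — the
verification domain is not specified upstream) converge to the single
interior steady state.

**Event timing.** `drop_metrics()` measures `T_drop` as the total time the
ATP trajectory spends below the threshold. The scenario dynamics dip once,
so total time and first-interval length coincide; total is the more robust
definition. Crossing times are refined by bisection to $10^{-3}$ min,
re-integrating from the nearest stored state, appropriate for drop
durations of order 5 min. Scenario runs use a horizon of $10^4$ min,
extended tenfold (up to $10^7$ min) until ATP has returned above the
threshold; the default output grid is logarithmic so the sub-minute dip is
densely resolved.

**Sensitivity.** Response coefficients use central finite differences with
a relative step of $10^{-3}$, re-solving the steady state on each side;
the stationary ATP is smooth in every parameter and solver noise is below
$10^{-9}$, so this step balances truncation against cancellation. Both raw
derivatives $\partial a^*/\partial p$ and elasticities
$(\partial a^*/\partial p)(p/a^*)$ are reported; ranking claims use
elasticities because the parameters span ~12 orders of magnitude and raw
derivatives would rank by units. Scans default to 25 log-spaced folds per
decade over [1/10, 10] and are warm-started from neighboring grid points.

**Calibration.** `fit_free_parameters()` minimizes squared *relative*
residuals of $(a^*, L^*, S^*)$ against the targets (they span
$10^3$–$10^{10}$ m.p.c.) by Levenberg-Marquardt (`minpack.lm::nls.lm`) in
log-parameter space, which enforces positivity without constraints. With
eleven free parameters and three targets the problem is underdetermined, so
a log-space quadratic penalty toward the starting values (default weight
$10^{-4}$) makes the published optimum a reproducible fixed point; the
weight is small enough that a two-parameter fit against synthetic targets
recovers the generating values to well under 1%.

## What the model implies about its own headline numbers

Two structural facts are easy to miss and matter for interpretation.

First, $L$ enters the system only through $\omega_L = L\,w_L\,a/(\theta_L+a)$
and $\lambda_L$ only through $L^* = v_{\mathrm{int}L}/\lambda_L$, so the
stationary state depends on $w_L$ and $\lambda_L$ *only through the ratio*
$w_L/\lambda_L$. Multiplying $w_L$ by 3 and dividing $\lambda_L$ by 3
give numerically identical stationary ATP (the package computes 36.9% of
reference for both), and the equal joint fold that reaches any given ATP
level is exactly the square root of the single-parameter fold
(`fold_to_reach_fraction()` returns 3.27 for $w_L$ alone and 1.81 for the
pair, at the 30% level).

Second, every ATP cost term saturates in $a$, so a transcription burst can
consume at most $N_{nt} N_L w_L L(0)\,a/(\theta_L+a)$ ATP per minute. This
self-limits transient dips: a 100-fold L1 boost takes the trajectory
minimum only to ~64% of reference, and the smallest folds whose dips cross
the 30% threshold are ~285 (L1) and ~33 (Alu) on these parameter values.

## What the tests do and do not show

The test-suite exercises the model only on its own synthetic ground truth:
stationarity of the published reference counts, self-consistency of the
analytic Jacobian against finite differences, exact ATP bookkeeping,
parameter recovery from forward-simulated targets, and the qualitative
biology (Alu removal de-represses L1 and halves-to-thirds the energy;
copy-number boosts cause transient, not permanent, depletion). Passing
tests therefore demonstrate a correct implementation of this model, not
that the model describes any particular cell line: all parameters are
literature-scale estimates for an "average" HeLa-like cell, expression of
truncated (inactive) L1 copies is folded into effective rate constants,
and no immune signaling, p53/BRCA1 feedback or death-pathway kinetics are
represented — the 30% ATP threshold is a marker, not a mechanism.

## Known limitations

* The published stationary value of $c_L$ ($1.8\times10^5$ m.p.c.) is
  inconsistent with its own flux balance under the published rate
  constants, which give $c_L \approx 1.08\times10^5$; the solver converges
  to the latter, and $c_L$ is excluded from quantitative steady-state
  checks.
* The per-nucleotide cost $N_{nt} = 15$ is applied to both replication and
  transcription, and insertion costs are charged twice, exactly as the
  balance equation is written.
* The model is deterministic; at single-molecule counts (e.g. $b_L \sim
  10^3$) a stochastic treatment could behave differently, and no spatial or
  population structure is represented.
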