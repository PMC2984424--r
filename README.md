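# oscseg

Sequential segmentation without a posterior proliferation zone:
cellular phase oscillators on a uniformly growing 1D tissue.

## The problem

In short-germ segmented animals, new segments are added one by one from
an anterior-to-posterior wave. The textbook account couples this to a
localized *posterior proliferation zone* — a terminal pool of dividing
cells that feeds the growing body. But mitosis-marker stainings of
onychophoran (velvet worm) embryos show cell divisions scattered over
the whole blastoderm, with no posterior hotspot. `oscseg` implements
the modelling side of that observation for theorists and developmental
biologists: a cellular-oscillator segmentation model in which **every**
cell proliferates at a uniform rate, and segments still form — plus the
statistics needed to ask, of a labelled nuclei pattern, whether a
posterior proliferation zone is present at all.

## The model

Each cell carries a phase φ with visible state `z = z_max·cos(φ)` and
advances it at rate `dφ/dt = 2π/T`. The tissue grows linearly,
`L(t) = L0 + g·t` (reference: `L(t) = t + 2`), with the anterior end
fixed, so under uniform proliferation a cell's relative position
`ρ = x/L(t)` is a material coordinate. The oscillation period is set by
distance `d` from the posterior end,

```
T(d) = T0 · (1 + A·d)          (fastest, T0, at the posterior)
```

and a cell **freezes** — its oscillation arrests, its state becomes
permanent — when `T` reaches the critical period `B`, i.e. at distance
`d* = (B − T0)/(A·T0)` from the posterior. Freezing sweeps the tissue
anterior-to-posterior and the frozen states form alternating bands:
segments. The classical progress-zone variant (`localized_age`), in
which growth is purely posterior addition and the period grows with
cell age instead, is included as a contrast; it produces equal-width
bands, whereas distributed proliferation produces bands that shrink at
establishment and widen afterwards.

The reference parameter set is `A = 0.5`, `B = 5`, `T0 = 1`,
`z_max = 10`, `L(t) = t + 2`, `0 < t < 50`. Under the linear growth law
the model has closed-form freeze times and phases
(`closed_form_freeze_time()`, `closed_form_freeze_phase()`), which the
simulator is tested against to 1e-3.

## Worked example

```r
library(oscseg)

params <- model_params()           # reference parameter set
kymo   <- simulate_tissue(params)  # ~1 s
kymo
#> kymograph (distributed_distance): 501 times x 200 bins, L in [2, 52]
#>   2000 cells tracked, 1692 frozen by t = 50

first_segment_time(kymo)
#> [1] 8.761777
```

The first complete segment (one full cycle of frozen phase) is
established at t ≈ 8.8 — "just before t = 10" — and 1692/2000 ≈ 84.6%
of the tissue has segmented by t = 50, matching the closed-form front
`1 − d*/L(50) = 1 − 8/52`. The segment table shows the
anterior-to-posterior progression and the shrinking establishment
widths (band 1 abuts the tissue edge and is truncated; see the
vignette):

```r
tab <- band_labels(kymo, 50)       # 35 bands, 34 complete
head(as.data.frame(tab)[, c("band_index", "sign", "t_established",
                            "width_at_establishment")], 4)
#>   band_index sign t_established width_at_establishment
#> 1          1    1         7.165                 1.1652
#> 2          2   -1         8.533                 1.1935
#> 3          3    1         9.878                 1.0216
#> 4          4   -1        11.206                 0.8949
```

On the empirical side, `generate_embryo()` produces seeded nuclei point
patterns in three labelling regimes (uniform mitoses, a posterior
enrichment zone, an anterior ring), and `posterior_test()` asks whether
the posterior-most AP bin holds more mitoses than a uniform allocation
would give:

```r
pat <- generate_embryo("posterior_zone", E = 10, f = 0.1, seed = 7)
posterior_test(pat, seed = 7)
#> Posterior proliferation-zone test
#>   2000 nuclei, 185 mitoses, K = 5 bins, zone = bin 5
#>   zone: 100/410 mitotic; rest: 85/1590
#>   enrichment = 4.562, p_binomial = 1.017e-23, p_permutation = 0.000999 (1000 perms)
#>   REJECT uniform null (posterior enrichment) at alpha = 0.05
```

The same test on a `"uniform"` pattern reports
`enrichment = 0.684, p_binomial = 0.936` — no evidence of a posterior
zone, the onychophoran situation.

Kymographs export as tab-delimited matrices and plain PGM images, and a
command-line wrapper over the same functions is installed at
`system.file("cli", "oscseg", package = "oscseg")` (subcommands
`simulate`, `analyze`, `generate-embryo`, `zone-test`, `sweep`).

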