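# mepflux

Estimating plastidial MEP-pathway flux from ¹³CO₂→isoprene labeling
kinetics, and analysing the enzyme that ends the pathway.

## What this is for

In plants, the methylerythritol 4-phosphate (MEP) pathway supplies the
universal C5 isoprenoid precursors DMADP and IDP. Two bespoke computations
recur in studies of this pathway and are packaged here for reuse:

1. **Flux from labeling kinetics.** After switching a leaf to ¹³CO₂, the
   fraction of isoprene molecules carrying label rises along a lagged
   saturation curve. Treating the pathway as four well-mixed pools in
   series — DXP (A), MEcDP (B), HMBDP (C) and IDP+DMADP (D), each turned
   over at rate J/P — the fractional labeling is

   f(t) = m · { 1 − Σᵢ cᵢ · exp(−(J/Pᵢ)·t) },  cᵢ = Pᵢ³ / ∏ⱼ≠ᵢ (Pᵢ−Pⱼ)

   with plateau m and pathway flux J (nmol gFW⁻¹ min⁻¹). f(t)/m is the CDF
   of a hypoexponential (sum of four exponentials) lag. The package
   provides the closed form, an independent adaptive ODE integrator that
   also handles near-equal pools, least-squares flux fitting with
   multi-start, and a residual bootstrap.
2. **Pool sizes from final labeling.** Plastidial pools of the four
   intermediates are estimated from total pools by referencing each
   metabolite's final labeling fraction to that of isoprene (assumed
   purely plastidial).
3. **HDR enzyme kinetics.** Progress curves of combined DMADP+IDP product
   are fit with the Box-Lucas model y = a(1−exp(−b·t)); the initial
   velocity is the origin slope v0 = a·b. Initial velocities across
   substrate levels give Km and Vmax by nonlinear Michaelis–Menten fitting
   (default) or Lineweaver–Burk regression, then kcat = Vmax/[E] and
   catalytic efficiency kcat/Km, plus DMADP:IDP product ratios in the
   conventional "1:x" form.
4. **Precursor stoichiometry.** A prenyl diphosphate of n C5 units takes
   1 DMADP + (n−1) IDP: GDP (C10) 1, FDP (C15) 2, GGDP (C20) 3 IDP;
   tetraterpenes count as 2× GGDP. `supply_vs_demand()` runs the
   limiting-reagent balance of an HDR product ratio against a terpenoid
   product profile.

Seeded generators (`simulate_labeling`, `simulate_assay`,
`simulate_pool_table`, `write_fixture_set`) emulate the PTR-MS and
LC-MS/MS inputs so the whole pipeline is testable offline.

## Worked example

```r
library(mepflux)

p  <- pool_sizes(1.2, 2.5, 0.6, 8.0)            # nmol gFW^-1
tc <- simulate_labeling(p, flux_j = 1.8, plateau_m = 0.93,
                        noise_sd = 0.02, seed = 42)
fit_flux(tc, p)
#> MEP pathway flux fit (25 points)
#>   J = 1.843 +/- 0.0287 nmol gFW^-1 min^-1
#>   m = 0.9263 (fixed from plateau)
#>   RSS = 0.0155, converged: TRUE

b <- bootstrap_flux(tc, p, n_boot = 200, seed = 42)
c(b$ci_lower, b$ci_upper)
#> [1] 1.808 2.017        # 95% interval covers the true J = 1.8

efficiency_fold(mm_kinetics(km = 6.0, kcat = 62.0),    # poplar HDR1
                mm_kinetics(km = 21.4, kcat = 31.6))   # poplar HDR2
#> [1] 6.998              # the published ~7-fold difference

supply_vs_demand(1/7, c(GGDP = 1))   # 1:6 DMADP:IDP supply vs carotenoid demand
#> C5 supply vs demand (per unit total C5 flux):
#>   supply  DMADP 0.1429, IDP 0.8571
#>   demand  DMADP 1, IDP 3 per mole of profile
#>   max profile formation rate 0.1429; limiting: DMADP
#>   leftover DMADP 0, IDP 0.4286
```

The fitted J of 1.843 is the pathway throughput that best explains how
fast labeling swept through the four pools; the bootstrap interval
quantifies its noise-driven uncertainty. The last call shows that a 1:6
DMADP:IDP supply feeding pure GGDP demand (1:3) is DMADP-limited and
leaves 43% of the C5 flux as surplus IDP.

## Command line

```sh
Rscript -e 'mepflux::mepflux_cli()' simulate  --out fixtures/ --seed 1
Rscript -e 'mepflux::mepflux_cli()' fit-flux  --timecourse fixtures/labeling.csv \
    --pools fixtures/pools.csv --out fit.json
Rscript -e 'mepflux::mepflux_cli()' fit-kinetics --assay fixtures/assay.csv \
    --enzyme-molar-uM 0.01 --method nls
Rscript -e 'mepflux::mepflux_cli()' demand --profile fixtures/profile.csv \
    --supply-ratio 1:6
```

CSV schemas: time courses `time_min,fraction[,sd]`; assays
`substrate_uM,time_min,product_uM[,dmadp_uM,idp_uM]`; pool tables
`metabolite,total_pool_nmol_per_gfw,final_fraction` (row `isoprene`
carries the reference plateau); profiles `class,moles`.

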