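# nickbind

Analysis toolkit for host–guest studies of small-molecule ligands binding
nicked DNA duplexes — the model system for topoisomerase I poisons, whose
biological target is the nick of the enzyme/DNA cleavable complex. It
covers the three measurement channels such studies combine:

1. **DOSY diffusion NMR → association constants.** Pulsed-field-gradient
   decays are fitted with the Stejskal–Tanner law,
   *I(g) = I₀ exp(−D γ² g² δ² (Δ − δ/3))*, and converted to a 1:1
   association constant under the fast-exchange two-state model: the
   observed diffusion coefficient is a population-weighted average of the
   free and bound forms, *D*obs = MF·*D*free + (1−MF)·*D*complex, with the
   complex diffusing like the (much larger) host. From the free-ligand
   molar fraction, the mass balance gives the complex concentration and
   *K*ₐ = [HL] / ((C_H − [HL])(C_L − [HL])), in mM⁻¹. Stoichiometrically
   impossible inversions (more complex than host, the signature of excess
   ligand under a 1:1 model) produce a structured warning, not a number.

2. **NOESY volumes → conformer-ensemble scoring.** Cross-peak volumes are
   calibrated to distances against a reference spin pair by the
   isolated-spin-pair r⁻⁶ law, and multi-model PDB ensembles are scored
   by distance-threshold satisfaction percentages, hydrogen-bond
   occupancy (3.5 Å / 135° geometric criterion), chemical-shift
   perturbation tables, and RMSD k-means clustering with low-population
   pruning (Kabsch superposition, medoid representatives).

3. **ESI/MALDI peak assignment.** Formula arithmetic with an embedded
   IUPAC mass table, transformation rules for the chemistry of
   9-aminomethyl camptothecins (hydrolysis, retro-Mannich regeneration of
   SN38, quinone-methide alkylation), and tolerance-based peak
   assignment, including oligonucleotide biohybrid peaks predicted as
   observed host peak + adduct mass.

Seeded generators (`gen_decay_dataset`, `gen_titration_dataset`,
`gen_toy_ensemble`, `gen_peaklist`) produce synthetic inputs with the
statistical structure the analyses assume, so every stage is testable end
to end without instrument data. See `vignettes/methods.Rmd` for the
models, parameter choices and limitations.

## Worked example

```r
library(nickbind)

# 1. fit a diffusion coefficient from a (here simulated) DOSY decay
e <- gen_decay_dataset(D = 1.13e-10, noise_frac = 0.01, seed = 42,
                       resonance_id = "T7-CH3")
fit_diffusion(e)
#> Diffusion estimate [T7-CH3]: D = 1.1311e-10 m^2/s (se 1.15e-12), I0 = 1.006, R^2 = 0.99927

# 2. association constant from a binding-systems table
tab <- read_binding_table(system.file("extdata", "table1_synthetic.tsv",
                                      package = "nickbind"))
binding_table_constants(tab)
#>          sample MF_ligand complex_conc_mM    Ka_mM warnings
#> 1 1+2_synthetic 0.6910742        1.390166 4.069983

# 3. assign MALDI peaks: free host vs alkylated biohybrid
cand <- data.frame(
  name = c("host", "biohybrid"),
  expected_mz = c(6885.8, biohybrid_mz(6885.8, "C24H25N3O5", "CH5N")))
assign_peaks(c(6885.8, 7290.9), cand, tolerance = 2)
#>   peak_mz   species expected_mz delta_Da matched
#> 1  6885.8      host    6885.800    0.000    TRUE
#> 2  7290.9 biohybrid    7290.222    0.678    TRUE
```

The fitted *D* recovers the simulated 1.13 × 10⁻¹⁰ m²/s within 0.1%. In
step 2, 69% of the ligand is free, 1.39 mM of complex has formed from
1.5 mM host + 4.5 mM ligand, and the association constant is
4.07 mM⁻¹ — strong binding, most of the host complexed. In step 3 the
second MALDI peak sits 0.68 Da from the host-plus-adduct prediction
(6885.8 + 404.42 for the shared C23H20N2O5 quinone-methide adduct), well
within the ±2 Da window, and is assigned as the covalent biohybrid.

Configs drive the same stages from the command line or `run_stage()`:

```sh
Rscript inst/exec/nickbind inst/extdata/demo_config.yaml
```

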