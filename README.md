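# kinwire

Allosteric "wiring maps" for kinesin motor domains: residue co-evolution
analysis of a curated family alignment, a thresholded coupling network mapped
onto Cα coordinates, and experimental validation of predicted couplings by
double-mutant-cycle thermodynamics computed from steady-state ATPase
kinetics.

## The scientific problem

Kinesins convert the chemical free energy of ATP hydrolysis into mechanical
work. How the active site communicates with the microtubule-binding surface,
loop 5 and the necklinker — sites up to 30 Å away — is an allosteric
question. `kinwire` implements the full computational side of one answer:

1. **Sequence curation** (`curate_sequences()`): a raw family collection is
   pruned of fragments and of redundant entries (pairwise identity > 95%),
   because relatedness between sequences is the dominant noise source in
   co-evolution analysis.
2. **Statistical coupling analysis** (`sca_coupling()`): for each alignment
   column *i*, a conservation energy
   ΔG<sup>stat</sup><sub>i</sub> = kT\* √Σ<sub>x</sub> [ln(P<sub>x,i</sub>/q<sub>x</sub>)]²,
   and for each pair (*i*, *j*) a perturbation-based coupling energy
   ΔΔG<sup>stat</sup><sub>i|δj</sub> = kT\* √Σ<sub>x</sub> [ln(P<sub>x,i|δj</sub>/P<sub>x,i</sub>)]²,
   where P<sub>x,i|δj</sub> is the distribution at *i* in the subalignment of
   sequences carrying the dominant residue at *j*. kT\* is the statistical
   energy unit (set to 1). Perturbations whose subalignment is too small are
   masked, not zeroed. `extract_sectors()` clusters the supra-threshold
   positions into protein sectors (default 3).
3. **Network analysis** (`build_network()`, `classify_hubs()`,
   `degree_histogram()`, `divergence_at_positions()`): residues with at least
   one coupling ≥ 1.0 kT\* form the network; hubs couple to ≥ 9 partners;
   divergence between two family members is counted at the network positions.
4. **Structural mapping** (`read_ca_structure()`, `ca_distance()`,
   `distance_histogram()`): couplings are classified as contact
   (Cα–Cα < 6 Å) or distal (≥ 6 Å) on a crystal structure and binned into a
   stratified distance histogram.
5. **Double-mutant cycles** (`fit_michaelis_menten()`, `ddg_of_mutation()`,
   `coupling_energy_therm()`, `classify_epistasis()`, `additivity_offset()`):
   ATPase titrations are fit to v = k<sub>cat</sub>[S]/(K<sub>m</sub> + [S]);
   the free-energy change of a mutation is
   ΔΔG<sub>M</sub> = −RT ln[(k<sub>cat</sub>/K<sub>m</sub>)<sub>mut</sub>/(k<sub>cat</sub>/K<sub>m</sub>)<sub>wt</sub>],
   and the thermodynamic coupling of a residue pair is
   CE<sub>THERM</sub> = ΔΔG<sub>M1</sub> + ΔΔG<sub>M2</sub> − ΔΔG<sub>M1M2</sub>.
   |CE<sub>THERM</sub>| below ~1 kcal/mol is experimentally additive
   (independent residues); larger values are classified into cooperative /
   synergistic epistasis classes.

Fully seeded synthetic generators (`simulate_msa()`, `simulate_titrations()`,
`simulate_structure()`) provide alignments with planted co-varying column
pairs, ideal-geometry Cα traces and noisy titrations, so every stage is
testable against known ground truth. `run_pipeline()` chains all stages from
one configuration and writes a reproducible report.

## Worked example

```r
library(kinwire)

# a synthetic 800 x 120 family with four planted co-varying pairs
sim <- simulate_msa(msa_sim_spec(n_sequences = 800, n_columns = 120, seed = 42))
cm  <- sca_coupling(sim$alignment)
cm
#> <sca_matrix> 120 columns (120 included), 924 valid pairs

net <- build_network(cm, threshold = 1.0)
net
#> <allostery_network> 53 nodes, 108 edges (threshold 1.00 kT*), 8 hubs

# the free-energy change of a facilitating mutation: efficiencies
# 1.6e6 vs 2.5e5 1/(M s) at 298 K
ddg_of_mutation(1.6e6, 2.5e5)
#> [1] -1.098612  # kcal/mol: the mutant lowers the catalytic barrier

wt  <- tibble::tibble(mutant = "wt", k_cat = 0.05, K_m = 2e-7)
fit <- fit_michaelis_menten(
  simulate_titrations(kinetic_sim_spec(wt, noise_sd = 0.05, seed = 1)))
glance(fit)
#> # A tibble: 1 x 7
#>    k_cat k_cat_se         K_m       K_m_se efficiency converged n_points
#> 1 0.0501 0.000452 0.000000195 0.0000000159    257269. TRUE            12
```

The network's 53 nodes are the columns with at least one supra-threshold
coupling — the four planted pairs rank at the very top of the 7140 pair
energies — and the fitted `k_cat` / `K_m` recover the generative values
(0.05 s⁻¹, 200 nM) within the 5% noise level of the titration.

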