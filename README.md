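# aqpflux

Post-simulation analysis for aquaporin–lipid membrane systems in R.

Aquaporins are tetrameric water-channel proteins whose high, selective water
permeability makes them attractive for biomimetic desalination membranes. A
central design question for such membranes is the protein-to-lipid molar
ratio: permeability per channel is not constant but depends on how strongly
the surrounding bilayer is deformed by the embedded protein (hydrophobic
mismatch). `aqpflux` implements the analysis chain that turns molecular
dynamics trajectories of these systems into the quantities that answer that
question:

- **Osmotic permeability from the collective coordinate.** For each monomer
  channel, the water motion is condensed into one dimensionless coordinate,

  `dn = Σ_{i ∈ s(t)} dz_i / L`,

  where `s(t)` is the set of waters inside the channel, `dz_i` their axial
  displacements over one frame interval, and `L` the channel length; one full
  single-file permeation changes `n(t)` by exactly ±1. Treating `n(t)` as a
  1D random walk, its diffusion constant `D_n` follows from the Einstein
  relation `⟨n²(t)⟩ = 2 D_n t`: the series is cut into non-overlapping 200-ps
  windows, the windows of all four monomer channels are pooled into one
  mean-squared displacement, and the slope is fitted by ordinary least
  squares. Permeabilities follow as `p_u,mon = v_w · D_n` (with `v_w` ≈ 29.9 Å³
  the volume of a water molecule) and `p_u,tet = 4 · p_u,mon`.

- **Hydrophobic mismatch.** Bilayer hydrophobic thickness is measured as the
  phosphorus-to-phosphorus distance `d_P–P` between leaflet means. The
  thickness of the lipid shell adjacent to the protein (lateral distance ≤ 5 Å
  by default) gives the deformed value, a protein-free reference the original
  one, and `Δd_P–P,adj = d_P–P,origin − d_P–P,deform` quantifies how much the
  protein compresses its lipid annulus. The default averaging schedule is
  five per-nanosecond block averages over the first 5 ns.

- **System-level prediction.** With `ρ_prot` the number of channel proteins
  per cm² of membrane, the membrane permeability trend is
  `p_f ∝ ρ_prot / Δd_P–P,adj`, and the per-tetramer permeability correlates
  with `1/Δd_P–P,adj` (Pearson r with a two-sided t-test). Ratio arithmetic
  for protein cost vs. permeability gain across compositions is included.

- **Selectivity-filter geometry.** The filter of aquaporin Z is delimited by
  residues F43, H174, T183 and R189. Per frame, the atom of each residue
  closest to their joint center is projected onto the plane perpendicular to
  the channel axis and the quadrilateral "central area" is computed
  (angular-sort + shoelace); its relative-frequency histogram separates rigid
  (unimodal ≈ 9 Å²) from flexible (bimodal ≈ 5 and 9 Å²) filters.

Because published trajectories for such systems are rarely deposited, the
package ships synthetic-trajectory generators with analytically known ground
truth (independent Brownian channel waters with
`D_n = N_w · D_w / L²`; a bilayer with a planted Gaussian thinning profile; a
two-state Markov filter), so the entire chain is testable end to end without
any download. Standard formats are supported: fixed-column PDB (single- and
multi-model) and CHARMM/NAMD binary DCD, both read and written.

## Worked example

```r
library(aqpflux)

## permeability chain on a synthetic tetramer (8 waters/channel, D_w = 0.2
## A^2/ps, L = 20 A -> closed-form D_n = 8 * 0.2 / 20^2 = 0.004 /ps)
g <- gen_channel_water(n_channels = 4, n_waters = 8, L = 20, D_w = 0.2,
                       dt_frame = 1, n_frames = 50000, seed = 42)
estimate_permeability(g$trajectory, g$water_ids, g$channels,
                      window_ps = 200, v_w = 29.9)
#> <aqp_permeability> D_n = 0.003938 /ps (se 7.7e-06), p_u,mon = 1.18e-13 cm^3/s, p_u,tet = 4.71e-13 cm^3/s

## hydrophobic mismatch of a planted 4-A thinning (truth at 5-A cutoff: 3.07 A)
b <- gen_bilayer(A = 4, sigma = 3, sigma_z = 0.5, n_frames = 50, seed = 42)
delta_thickness(b$trajectory, b$p_ids, b$protein_ids, cutoff = 5,
                reference = b$reference)
#> <aqp_thickness> d_origin = 38.003 A, d_deform = 34.925 A, delta_adj = 3.078 A (cutoff 5 A, 5 points)

## bimodal selectivity-filter area (planted modes 5 and 9 A^2)
f <- gen_filter(A1 = 5, A2 = 9, n_frames = 2000, seed = 42)
sort(histogram_modes(area_histogram(filter_area_series(f$trajectory,
                                                       f$residue_atoms)), 2))
#> [1] 4.75 8.75

## ranking compositions by the rho/delta permeability trend
cases <- data.frame(label = c("1:50", "1:75", "1:100", "1:150"),
                    n_proteins = 9,
                    box_xy_area_A2 = c(142, 165, 190, 231)^2,
                    delta_adj = c(2.1, 2.5, 1.3, 2.9),
                    p_u_tet = c(3.0e-13, 2.5e-13, 4.2e-13, 3.1e-13))
prediction_report(cases)
#>  label rho_prot_per_cm2 delta_adj_A inverse_delta_per_A     pf_trend rank
#>   1:50     4.463400e+12         2.1           0.4761905 2.125429e+12    1
#>  1:100     2.493075e+12         1.3           0.7692308 1.917750e+12    2
#>   1:75     3.305785e+12         2.5           0.4000000 1.322314e+12    3
#>  1:150     1.686625e+12         2.9           0.3448276 5.815948e+11    4
#> Pearson r(p_u,tet, 1/delta) = 0.885, two-sided p = 0.1148, n = 4
```

The permeability estimate recovers the planted `D_n = 0.004 /ps` to ~1.5%;
the mismatch estimate recovers the shell average of the planted thinning
profile to well under 0.1 Å; the histogram modes land in the bins containing
the planted 5 and 9 Å² states; the ranked table shows the densest composition
winning on `ρ/Δd` despite not having the smallest mismatch.

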