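# hairpinreg

Beta-hairpin registry analysis of disordered peptide ensembles and amyloid
nucleation propensity.

## What this package is for

Amyloid fibril nucleation for aggregation-prone tau fragments proceeds
through monomeric beta-hairpins rather than random coils.  For the tau
295–311 peptide (`DNIKHVPGGGSVQIVYK`, PHF6 hexapeptide `VQIVYK` at
306–311), a hairpin can fold in two hydrogen-bonding *registries*: "even"
hairpins bond the even-numbered hexapeptide residues (306V, 308I, 310Y) to
the N-terminal arm, "odd" hairpins bond 305S, 307Q, 309 instead.  A
one-residue registry shift flips every hexapeptide side chain between the
two hairpin faces — the geometric degree of freedom that lets a trimer of
hairpins convert into the parallel cross-beta fibril fold.

`hairpinreg` quantifies conformational ensembles frame by frame and links
the structural statistics to aggregation kinetics:

- backbone hydrogen-bond detection (heavy-atom N–O ≤ 3.5 Å, |i−j| ≥ 2);
- per-frame hairpin classification into even / odd / none, with the
  span, parity-purity and antiparallel criteria;
- ensemble fractions `f_even`, `f_odd`, `f_coil` (hexapeptide coil content,
  normalised by 6 × frames and *orthogonal* to the hairpin calls),
  `f_beta_hex`, and the cross-beta hairpin amyloid trimer score

  **S_xHAT = f_odd · f_even²**

  (two even hairpins plus one registry-shifted monomer in the
  transition-state trimer; maximal 4/27 at f_even = 2/3, f_odd = 1/3);
- tau k18 repeat-domain statistics: local hairpin probabilities H1–H4
  around each PGGG motif, the 4×4 inter-hexapeptide beta-pairing matrix,
  segment beta totals, and per-residue SASA differentials (WT − mutant);
- ThT plate processing: blank subtraction, 4-parameter-logistic T₁/₂
  fits, aggregation speed 1/T₁/₂, and Spearman/Pearson correlation of
  structural metrics with kinetics;
- DSSP-style (Kabsch–Sander) secondary structure, Shrake–Rupley SASA with
  a deterministic golden-spiral point set, and Kabsch superposition RMSD;
- ground-truth synthetic generators for every stage (ideal even/odd
  hairpins, extended chains, self-avoiding coils, k18 frames with
  designated events, noisy ThT plates), used by the validation suite.

## Worked example

Three synthetic "mutants" with increasing hairpin content, summarised and
correlated against a matched simulated ThT experiment:

```r
library(hairpinreg)

regions <- make_region_map(tau295_sequence())

recipes <- list(
  low  = c(even = 0.10, odd = 0.05, extended = 0.15, coil = 0.70),
  mid  = c(even = 0.30, odd = 0.15, extended = 0.10, coil = 0.45),
  high = c(even = 0.45, odd = 0.25, extended = 0.05, coil = 0.25))

summaries <- do.call(rbind, lapply(names(recipes), function(id) {
  ens <- sample_ensemble(list(sequence = tau295_sequence(),
                              composition = recipes[[id]],
                              n_frames = 200, noise_sigma = 0.1,
                              seed = match(id, names(recipes))))$ensemble
  summarize_ensemble(ens, regions, mutant_id = id)
}))
print(summaries, digits = 3)
#>   mutant_id n_frames f_even f_odd f_coil f_beta_hex   S_xHAT
#> 1       low      200  0.115 0.030  0.833          0 0.000397
#> 2       mid      200  0.205 0.165  0.613          0 0.006934
#> 3      high      200  0.480 0.225  0.282          0 0.051840
```

The recovered fractions track each recipe (sampling noise at n = 200), the
coil fraction falls as hairpin content rises, and the xHAT score orders the
mutants:

```r
rank_mutants(summaries, key = "S_xHAT")
#>   mutant_id       value rank
#> 3      high 0.051840000    1
#> 2       mid 0.006934125    2
#> 1       low 0.000396750    3
```

A matched plate — faster aggregation for hairpin-rich mutants — closes the
loop from structure to kinetics:

```r
plate <- simulate_tht_plate(list(
  mutants = data.frame(id = names(recipes), T_half = c(95, 55, 28),
                       baseline = 50, plateau = 1050, slope = 0.3),
  noise_sigma_frac = 0.02, seed = 7))
speeds <- sapply(names(recipes), function(id)
  aggregation_speed(fit_tht_sigmoid(blank_subtract(
    plate_curves(plate$plate, id)))))
round(speeds, 4)
#>    low    mid   high
#> 0.0105 0.0182 0.0358

correlate(summaries$f_even + summaries$f_odd, speeds)
#> <correlation> spearman r = 1.000 (n = 3)
correlate(summaries$f_coil, speeds)
#> <correlation> spearman r = -1.000 (n = 3)
```

Hairpin content correlates positively with aggregation speed and coil
content negatively — the qualitative signature the metrics are designed to
capture.  Real ensembles are loaded with
`load_ensemble("frames.pdb")` (multi-model PDB, one MODEL per frame) and
mutant libraries with `load_mutant_table("mutants.csv")`.

For k18-scale analyses:

```r
spec <- make_repeat_spec()                       # tau k18, residues 244-372
frame <- build_k18_frame(spec, list("H2"))       # one frame with an H2 hairpin
ens <- ensemble(list(frame), numbering_offset = 243)
interhexapeptide_pairing(ens, spec)
#> <pairing_matrix> 1 frames
#>   local hairpins:  H1=0.000  H2=1.000  H3=0.000  H4=0.000
#> ...
total_beta_for_segment(0.06, 0.15)               # local + pairing components
#> [1] 0.21
```

## Layout

- `R/` — implementation (structure I/O, geometry core, hairpin registry,
  ensemble metrics, repeat domain, kinetics/correlation, synthetic
  generators)
- `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code)
- `vignettes/hairpin-registry-methods.Rmd` — the model, criteria,
  numerical choices and limitations in detail
- `scripts/acceptance.R` — reference-quantity reproduction
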