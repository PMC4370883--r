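# densref

Density-map cross-correlation restraints for simulated-annealing structure
refinement.

## What this is for

Solution NMR pins down local geometry (NOE distance bounds, hydrogen
bonds, secondary structure) but often leaves the global arrangement of an
elongated molecule — an RNA especially — poorly determined: bundles of
structures that agree with every restraint can still differ by many
Angstroms in overall shape. Electron microscopy supplies exactly the
missing information at low resolution: the molecular envelope. `densref`
implements the coupling term that lets a density map steer a restrained
simulated-annealing refinement, together with everything needed to use and
test it end to end: PDB and CCP4/MRC I/O, Gaussian-kernel map simulation,
flat-bottom distance restraints, a Cartesian annealing engine with
repeat-and-select ensemble generation, Kabsch superposition and bundle
statistics, and synthetic fixtures.

## The core quantity

For an observed map with voxel values $m_i^{obs}$ and a map
$m_i^{calc}$ back-calculated from the atomic coordinates (one Gaussian per
heavy atom, width set by the nominal resolution), the agreement is the
Pearson cross-correlation over all $N$ voxels,

$$
C = \frac{1}{N}\sum_{i=1}^{N}
    \frac{(m_i^{obs}-\overline{m^{obs}})\,(m_i^{calc}-\overline{m^{calc}})}
         {\sigma^{obs}\,\sigma^{calc}},
$$

and the map contributes the energy $E = k_c(1-C)$ to the refinement
potential, with an exact analytic gradient (including the coordinate
dependence of $\overline{m^{calc}}$ and $\sigma^{calc}$) so the map pulls
atoms during dynamics and minimization. $C$ is invariant to scale and
offset of the observed density; only shape agreement matters.

## A worked example

```r
library(densref)

ref   <- build_toy_helix(toy_spec())            # 40-residue toy helix, 160 atoms
rset  <- toy_restraints(ref, seed = 1)          # bonds + P-P + NOE-like bounds
start <- perturb_model(ref, 8, seed = 1)        # bent to 8 A RMSD from ref

sp  <- simulation_params(10)                    # 10 A map, 2 A voxels
obs <- simulate_map(ref, sp, default_selection) # the "observed" density
mp  <- map_potential_params(sp, k_c = 20000)

map_energy(start, obs, mp)$C                    # 0.32 -- poor fit at the start

sch <- annealing_schedule(n_stages = 25, equil_time = 4, stage_time = 0.5,
                          dt = 0.02, seed = 201, polish_maxit = 4000)
ens <- refine_model(start, rset, obs, mp, sch, ensemble_protocol(16, 5))
ensemble_stats(ens$models, reference = ref)
```

```
ensemble of 5 models: precision 1.66 +/- 0.18 A (pairwise RMSD)
  accuracy to reference: 1.76 +/- 0.13 A
```

The refinement pulls the bent start (8 A from the truth, C = 0.32) back to
under 2 A from the reference. The same protocol without the map gives

```
ensemble of 5 models: precision 3.15 +/- 0.09 A (pairwise RMSD)
  accuracy to reference: 8.51 +/- 0.18 A
```

— a looser bundle that never leaves the neighborhood of the wrong starting
shape, because nothing in the distance restraints says where the global
fold should sit. That contrast — the map restraint supplying exactly the
global information the local restraints lack — is the package's central
result.

The packaged study wraps this comparison across conditions:

```r
study <- resolution_study(resolutions = c(40, 25, 15, 10), seed = 1,
                          n_repeats = 5, n_select = 4)
print(study)
```

reporting bundle precision and accuracy for restraints-only, each map
resolution, and a cube-shaped control map (an intentionally wrong density,
which degrades accuracy instead of helping — the package's negative
control).

## Command line

A launcher is installed at `exec/densref` inside the package directory:

```sh
DENSREF=$(Rscript -e 'cat(system.file("exec", "densref", package = "densref"))')
Rscript $DENSREF make-fixture --out-dir fx --resolutions 40,25,15,10 --seed 1
Rscript $DENSREF score --pdb fx/reference.pdb --map fx/map_10.ccp4 --resolution 10
# C=1.000000 E=0.000000
Rscript $DENSREF refine --pdb fx/start_1.pdb --restraints fx/restraints.tbl \
        --map fx/map_10.ccp4 --resolution 10 --kc 20000 \
        --repeats 16 --select 5 --seed 1 --out-prefix out/run
Rscript $DENSREF ensemble-stats --models 'out/run_*.pdb' --reference fx/reference.pdb
```

Subcommands: `simulate-map`, `score`, `refine`, `ensemble-stats`,
`make-fixture`; every flag can also come from a YAML config file
(`--config`), with explicit flags winning. Fixed seeds give byte-identical
outputs.

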