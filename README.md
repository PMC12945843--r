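# hspscreen

Predictive preformulation screening for amorphous drug formulations:
Hansen solubility parameter (HSP) and Flory–Huggins miscibility
calculations, group-contribution property estimation, and batch-sheet
stoichiometry — for formulation scientists choosing a stabiliser (polymer,
amino-acid coformer, or mesoporous carrier) for a poorly soluble drug
before committing to the lab.

## The models

Each substance is a point $(\delta_d, \delta_p, \delta_h)$ in Hansen space
(MPa½). Drug–excipient affinity is the interaction radius

    Ra = sqrt( 4(Δδd)² + (Δδp)² + (Δδh)² )

with Ra < 7 MPa½ read as miscible and Ra > 10 as immiscible (strict
bounds, borderline in between). Thermodynamic miscibility is then checked
with the solubility-parameter form of the Flory–Huggins parameter,

    χ = Vm (δt,drug − δt,excipient)² / (R T),   δt = sqrt(δd² + δp² + δh²)

with Vm the **drug's** molar volume (cm³/mol), R = 8.314 J/(mol·K),
T = 298 K, and χ < 0.5 read as miscible. Inorganic carriers (mesoporous
silica) sit outside the lattice model and get χ = NA. Missing molar
volumes and HSP triples are estimated from functional-group counts with
the Fedors and Hoftyzer–Van Krevelen increment tables bundled as CSV; a
SMILES convenience front-end (`decompose_structure()`, via
ChemmineR/OpenBabel) produces the group counts for simple organics.

The bundled reference panel is cefdinir (BCS class IV cephalosporin) plus
seven candidate stabilisers with literature HSP components. Literature Ra
and χ columns ride along as documentation-only fields: they are not
reproducible from their own δ components under the equations above, so
the package always recomputes and flags the discrepancies in its reports.

## Worked example

```r
library(hspscreen)
fix  <- load_reference_substances()
drug <- fix$substances[[1]]                      # cefdinir
vm   <- fedors_molar_volume(cefdinir_fragments())  # 200.9 cm^3/mol
screen(drug, fix$substances[-1], chi_context(vm))
```

```
Miscibility screen: Cefdinir vs 7 excipient(s)
  Vm(drug) = 200.9 cm^3/mol, T = 298 K; Ra bounds 7/10 MPa^0.5, chi bound 0.5
  L-phenylalanine    [coformer]         Ra  2.03 (miscible)  chi 0.061 (miscible)
  HPMC 606           [polymer]          Ra  2.03 (miscible)  chi 0.046 (miscible)
  PVP K30            [polymer]          Ra  2.56 (miscible)  chi 0.134 (miscible)
  L-tryptophan       [coformer]         Ra  2.87 (miscible)  chi 0.325 (miscible)
  Eudragit L100      [polymer]          Ra  4.53 (miscible)  chi 0.084 (miscible)
  SBA-15             [mesoporous_carrier] Ra  7.40 (borderline)  chi    NA (not_applicable)
  L-arginine         [coformer]         Ra  8.76 (borderline)  chi 2.858 (not_miscible)
  Best per role: coformer = L-phenylalanine; mesoporous_carrier = SBA-15; polymer = HPMC 606
```

Reading it: every polymer sits well inside the miscible Ra range and
below χ = 0.5, with HPMC 606 the best polymer on both keys; SBA-15 is
outside the miscible Ra range — a passive nanoconfinement carrier, not a
molecular stabiliser (its w/w drug loading in the bundled composition
recomputes to 37.17%); L-arginine's large polar/H-bond components make it
the outlier among the amino acids on both measures.

The formulation side:

```r
comps <- load_compositions()
f2 <- unlist(comps$formulations$F2$components)
drug_loading_percent(f2[["Cefdinir"]], f2[["SBA-15"]])   # 37.17
equimolar_mass(300, molar_mass("C14H13N5O5S2"), 40.00)   # 30.35 mg NaOH
```

## Analysis workflow

Three thin drivers under `analysis/` narrate the full study and write
their tables under `results/`:

| script | what it does |
|---|---|
| `01_reference_screen.R` | ranked screen of the reference panel → `results/screening_report.csv`, `screening_summary.md` |
| `02_formulation_arithmetic.R` | yields, drug loading, equimolar and molar-ratio checks → `results/formulation_summary.csv` |
| `03_synthetic_screen.R` | screen against 200 generated excipients → `results/synthetic_screen.csv` |

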