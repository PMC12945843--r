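---
title: "Predictive miscibility screening for amorphous drug formulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive miscibility screening for amorphous drug formulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hspscreen)
```

## The problem

Amorphising a poorly soluble drug buys dissolution rate at the cost of a
thermodynamically unstable solid. Whether a polymer, an amino-acid
coformer or a mesoporous carrier can hold the drug in its amorphous state
depends first on miscibility, and two desk-top models dominate
preformulation practice:

* **Hansen solubility parameters (HSP).** The cohesive energy density is
  split into dispersion, polar and hydrogen-bonding parts,
  $\delta_d, \delta_p, \delta_h$ (MPa$^{1/2}$). Two substances interact
  favourably when they sit close together in Hansen space, measured by the
  interaction radius
  $$R_a = \sqrt{4(\Delta\delta_d)^2 + (\Delta\delta_p)^2 + (\Delta\delta_h)^2},$$
  with the conventional factor 4 on the dispersion term. We classify
  $R_a < 7$ MPa$^{1/2}$ as miscible and $R_a > 10$ as immiscible, with a
  borderline band in between; both comparisons are strict, so a pair
  sitting exactly on a bound is borderline. A stricter school uses
  5 MPa$^{1/2}$ for the miscible bound; `miscibility_thresholds(ra_miscible
  = 5)` selects it.

* **Flory–Huggins interaction parameter.** With total parameters
  $\delta_t = \sqrt{\delta_d^2+\delta_p^2+\delta_h^2}$, the lattice model
  estimate is
  $$\chi = \frac{V_m}{RT}\,(\delta_{t,\text{drug}} - \delta_{t,\text{excipient}})^2,$$
  where $V_m$ is the molar volume of the *drug* (cm$^3$/mol) — the
  excipient's molar volume does not enter this one-parameter form — and
  $\chi < 0.5$ (strict) is read as thermodynamic miscibility. Because
  MPa·cm$^3$ = J, the expression is dimensionless without unit juggling.
  Inorganic carriers such as mesoporous silica are outside the lattice
  model (no meaningful group-contribution $V_m$, no mixing lattice), so
  they receive `NA` and the class `not_applicable`; their affinity is
  judged on $R_a$ alone. This $\chi$ is solubility-parameter-based and is
  always $\ge 0$: it can rank candidates but cannot, by construction,
  predict exothermic (negative-$\chi$) mixing.

## Group-contribution estimation

When measured parameters are unavailable, both $V_m$ and the HSP triple
are estimated by summing tabulated functional-group increments:

* Fedors volume increments: $V_m = \sum_i n_i \,\Delta v_i$. Note the
  genuine negative increments for substituted carbons and tertiary
  nitrogen; only the *sum* must be positive, which `fedors_molar_volume()`
  enforces.
* Hoftyzer–Van Krevelen attraction constants:
  $\delta_d = \sum n_i F_{d,i}/V$, $\delta_p = \sqrt{\sum n_i F_{p,i}^2}/V$,
  $\delta_h = \sqrt{\sum n_i E_{h,i}/V}$.

These two canonical schemes are bundled as one CSV
(`groups_hvk_fedors.csv`) with literature citations in its header. They
were chosen because they are the standard published tables for this
calculation; alternative schemes (Stefanis–Panayiotou, HSPiP) are out of
scope. Group-contribution HSP estimates typically carry roughly
±1 MPa$^{1/2}$ scheme-dependence, which is why the bundled reference panel
carries literature $\delta$ values directly rather than re-deriving them.

```{r}
tab <- group_contribution_table()
ethanol <- c(CH3 = 1, CH2 = 1, OH = 1)
vm_eth <- fedors_molar_volume(ethanol, tab)
vm_eth
hvk_hsp(ethanol, tab, vm_eth)
```

The primary input path is a user-supplied fragment multiset, so the
package works without any chemistry dependency. As a convenience,
`decompose_structure()` turns a SMILES string into a multiset: parsing and
valence perception are delegated to ChemmineR/OpenBabel, and atoms are then
assigned to groups most-specific-first (carboxyl before ester before
ketone before bare carbons) with first-match-wins overlap resolution and
one ring correction per independent cycle, sized by the smallest closing
cycle. The deterministic priority order trades cleverness for
reproducibility: the same SMILES always yields the same multiset. Only
C/H/N/O/S molecules are covered; silicas and other inorganics are
rejected, matching the convention above. Zwitterionisable molecules are
treated in their neutral form, since increment tables are defined for
neutral groups.

## The reference panel

The bundled fixture holds cefdinir (a BCS class IV cephalosporin) and
seven candidate stabilisers — three polymers (PVP K30, HPMC 606, Eudragit
L100), the mesoporous silica SBA-15, and three amino-acid coformers — with
literature Hansen components. The fixture also carries the literature's
own reported $R_a$ and $\chi$ columns, but as *documentation-only* fields:
those printed values are not reproducible from the printed $\delta$
components under the stated equations (recomputation gives e.g. 2.56
instead of 4.11 for PVP K30, and the printed $\chi$ set implies mutually
inconsistent drug molar volumes). The package therefore always recomputes
from components and attaches a discrepancy note to any assessment whose
literature value disagrees, rather than silently adopting either number.

```{r}
fix <- load_reference_substances()
drug <- fix$substances[[1]]
vm <- fedors_molar_volume(cefdinir_fragments())
vm
report <- screen(drug, fix$substances[-1], chi_context(vm))
report
```

Cefdinir's $V_m$ comes from a bundled manual Fedors decomposition
(26 heavy atoms, consistent with C14H13N5O5S2), giving 200.9 cm$^3$/mol;
any standard Fedors table puts it in the 150–400 cm$^3$/mol range, and the
classification conclusions below are stable across that whole range for
all pairs except L-tryptophan, whose $\chi$ crosses 0.5 above
$V_m \approx 310$ cm$^3$/mol.

The ranking key is $R_a$ first, then $\chi$, then name, because $R_a$
exists for every pair including inorganic carriers; the tie-breaks make
the sort total, so regenerating a report from the same inputs is
byte-identical. Report files round to table precision (2 decimals for
parameters, 3 for $\chi$); full precision is kept internally.

## Formulation arithmetic

The second half of the toolkit is the batch-sheet arithmetic used once
candidates are chosen: percent yield (actual over initial mass × 100, with
values over 100% flagged by a warning, not an error — residual solvent can
legitimately produce them), single-point external-standard HPLC drug
content, equimolar component masses from molar masses (computed from
Hill-notation formulas and bundled IUPAC 2021 atomic weights rounded to
3 decimals, with user overrides accepted), and w/w drug loading.

```{r}
comps <- load_compositions()
f2 <- unlist(comps$formulations$F2$components)
drug_loading_percent(f2[["Cefdinir"]], f2[["SBA-15"]])
stoichiometry_check(
  unlist(comps$formulations$F3$components),
  c(Cefdinir = molar_mass("C14H13N5O5S2"),
    `L-arginine` = molar_mass("C6H14N4O2"),
    `L-phenylalanine` = molar_mass("C9H11NO2")))
```

The stoichiometry checker deliberately reports the molar ratio the weighed
masses imply (here 0.759 : 1 : 1 for a nominally "1:1:1" co-amorphous
batch) instead of resolving the discrepancy: transparency over silent
correction.

## Synthetic data: what it does and does not emulate

`generate_synthetic_excipients()` draws HSP triples uniformly over the
envelope observed for common pharmaceutical stabilisers ($\delta_d$ 15–19,
$\delta_p$ 3–15, $\delta_h$ 7–18 MPa$^{1/2}$), with a
polymer/coformer/inorganic role mix defaulting to 0.5/0.3/0.2 — polymers
dominate real ASD screens, and inorganic carriers are the rarest class. A
uniform distribution is the least-assumption choice given no published
distribution for such panels. `generate_synthetic_fragments()` draws group
multisets from the increment table, padded with CH2 where needed so the
Fedors sum stays positive, as it is for any real molecule.

The generators exist to make the algebraic properties testable at scale:
symmetry, identity and the defining quadratic form of $R_a$;
non-negativity, zero-iff-equal-$\delta_t$ and exact $V_m$-linearity of
$\chi$; additivity of Fedors sums. Passing those suites shows the
arithmetic is right, not that the models predict real miscibility —
uniform, independently drawn components have no chemistry in them (no
correlation between $\delta_p$ and $\delta_h$, no real molecules attached),
and the thresholds themselves are heuristics calibrated on small molecules
and polymers, not guarantees.

## Numerical choices and limitations

* Strict inequalities at every threshold; boundary values fall to the
  conservative side (borderline / not miscible).
* All randomness flows through explicit integer seeds; generators restore
  the caller's RNG state.
* Property tests use 1000 synthetic pairs, 50 fragment draws and a
  15-molecule decomposition panel — enough to exercise every branch while
  keeping the suite under a minute.
* Known limitations: no temperature-dependent $\chi(T)$, no
  melting-enthalpy or Hansen-sphere (RED) methods, no negative $\chi$, no
  polymer repeat-unit averaging, and no claim that borderline $R_a$ plus
  applicable $\chi < 0.5$ resolves to a single verdict — both classes are
  reported side by side precisely because they can disagree (L-arginine is
  the bundled example: borderline-to-poor on $R_a$, yet historically
  reported favourable when ionic interactions, which neither model
  captures, are in play).
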