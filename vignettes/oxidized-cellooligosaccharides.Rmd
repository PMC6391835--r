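---
title: "Annotating oxidized cello-oligosaccharides: the mass model behind oxocello"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating oxidized cello-oligosaccharides: the mass model behind oxocello}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxocello)
```

## The problem

Lytic polysaccharide monooxygenases (LPMOs) of CAZy family AA9 attack
crystalline cellulose oxidatively. Oxidation at C1 or C4 cleaves the chain
directly, leaving an aldonic acid at a new reducing end (RE) or a ketone at a
new non-reducing end (NRE). Oxidation at C6 does not cleave: it converts the
hydroxymethyl group to an aldehyde (a C6-hexodialdose) and, for some enzymes,
onward to a carboxyl — a glucuronic-acid unit embedded in a cello-chain.

None of this is observed directly. What is observed is:

* **MALDI-TOF spectra** of the soluble oligosaccharides, where each species
  appears as a sodiated peak whose mass deviates from the unmodified
  cello-oligosaccharide ladder (`162·DP + 18 + 23`) by a small integer — the
  *delta class* (`+16`, `−2`, `+14`, `+12`, `+28`, ...). Delta classes are
  highly degenerate: `+14` can be one in-chain uronic acid or a C1 acid paired
  with a C4 ketone, and `−2` cannot distinguish a C4 ketone from a C6
  aldehyde at all.
* **Full-scan ESI spectra** of the monosaccharide end products after
  exo-glycosidase digestion, where every analyte appears many times over as
  adduct/cluster ions: one or two analyte molecules, cationized by H⁺, Na⁺ or
  NH₄⁺ (or deprotonated, with occasional Na-for-H exchange, in negative
  mode), and solvated by H₂O, NH₃, CH₃OH, HCOOH or CH₃COOH from the reaction
  and LC solvents.

oxocello implements the bookkeeping that turns those observations into
structural statements: a compositional mass model for the oxidation states, a
complete adduct-ion enumerator, the bromine-water transform that breaks the
`−2` degeneracy chemically, and a rule-based simulator of the enzymatic
degradation pathways that connect chain-level oxidation to the monosaccharide
standards seen at the instrument.

## The compositional mass model

An oligosaccharide is an ordered chain of glucosyl residues (residue 1 = NRE,
last = RE), each carrying an oxidation state. In the nominal integer dialect
the neutral mass is

$$M = 162\,\mathrm{DP} + 18 + \sum_i \delta_i$$

with additive per-residue deltas:

| state | delta | elemental change |
|---|---|---|
| C1 carboxyl (aldonic acid; RE only) | +16 | +O |
| C4 ketone | −2 | −H₂ |
| C6 aldehyde (hexodialdose) | −2 | −H₂ |
| C6 carboxyl (uronic acid) | +14 | +O −H₂ |
| lactone ring closure (per ring) | −18 | −H₂O |
| 4,5-unsaturation (lyase NRE) | −18 | −H₂O |

Expressing the deltas as elemental changes keeps the monoisotopic and average
dialects consistent with the same state algebra; the nominal dialect is the
default because the printed tables this package is validated against are
integer arithmetic. Lactones are modeled as `−18` modifiers on
carboxyl-bearing residues rather than as distinct residue types: that keeps
the algebra additive and reproduces the acid/lactone mass pairs of the
monosaccharide standards (196/178, 194/176, 210/192). Invariants are
enforced at construction: a C1 acid only on the RE, unsaturation only on the
NRE, lactone count bounded by the carboxyl count of its residue.

`delta_explanations()` inverts the class arithmetic: it enumerates every
composition multiset of oxidation events consistent with an observed delta,
up to a cap of 3 events per chain (the largest combination annotated on the
spectra this model targets; configurable). It returns compositions, not
positioned isomers, because an in-chain C6 oxidation is positionally
degenerate on a mass spectrum; `positions = TRUE` expands a composition into
its distinct positioned chains when needed. The two `−2` states (C4 ketone,
C6 aldehyde) are deliberately never collapsed, so explanation sets can be
larger than a spectrum annotation that treats "−2" as one thing. The C6
aldehyde hydrate (a `+16` gem-diol reported as an intermediate for some
AA5-family oxidases) is not modeled as a distinct state.

## Adduct-ion enumeration

`ion_table()` materializes *every* ion species within configured bounds — no
pruning heuristics — and `annotate_peaklist()`/`enumerate_candidates()`
filter it per peak. The default bounds are the smallest that cover the
package's golden tables of printed decompositions: at most 2 analyte
molecules, net charge at most 2, at most 6 neutral adduct molecules, at most
1 sodium-for-proton exchange in negative mode. (Six neutrals is not
decorative: negative-mode rows like `180 − 2H+ + 4H2O + 2HCOOH/2` genuinely
carry six solvent molecules.) Negative-mode sodium is modeled as an exchange
that reduces the net negative charge, with the invariant
`z = deprotonations − exchanges ≥ 1`.

Nominal-mode matching is exact integer equality after half-up rounding,
because the reference arithmetic is integer; other dialects use a float
tolerance. The electron mass is ignored in nominal mode and carried
(±0.00055) in monoisotopic carrier masses. Candidates are ranked by
parsimony — fewest total components, then fewest analytes, then lowest
charge, then label — a deterministic convention chosen here, since the
source tables imply no ranking.

The golden fixtures (`golden_tables()`, `golden_check()`) carry a per-row
confidence flag. One positive-mode row (m/z 103, analyte mass 182) matches
no species in the closed library and is flagged low-confidence and excluded
from hard assertions; one negative-mode row prints `CH3O` where the
arithmetic requires `CH3OH` and is transcribed as methanol with a note. All
other rows re-evaluate exactly at load time.

## The bromine-water transform

Br₂ in water oxidizes free aldehydes to carboxyls and leaves ketones alone.
`br2_transform()` therefore sends every C6 aldehyde to a C6 carboxyl (+16
each) and, by default, oxidizes an unmodified reducing end to the aldonic
acid (+16); `br2_delta_map()` is the class-level shortcut
`post = pre + 16·(#aldehydes, RE included)`. This separates the two readings
of `−2`: a C6 aldehyde lands at `+30`, a C4 ketone at `+14`. The annotated
post-treatment spectrum shows both a `+44` and a `+26` class under the same
three-oxidation label; this package models `+26` as the mono-lactone of the
`+44` class (44 − 18), keeps that reading low-confidence in the golden
fixture, and surfaces both the raw label and the lactone interpretation.
Lactone fate under the reagent is configurable (`preserve`, the default;
`open`; or `equilibrate_both`).

## Enzymatic degradation

`digest()` models the two exo-hydrolases that convert
glucuronic-acid-containing chains to monosaccharide standards:
beta-glucosidase (BGL) releases an unmodified glucosyl NRE, and
beta-glucuronidase (GUS) releases a C6-carboxyl NRE, alternating down the
chain to a fixed point; DP 1 species resolve through
`monosaccharide_identity()`. Residues neither enzyme accepts (C4 ketone, C6
aldehyde, lactone, unsaturated end) **stall** the chain by default — they are
not natural substrates of either enzyme; the source work is silent, so this
is configurable (`pass_through` removes them anyway and records them under
their state label). Whether BGL would release a glucosyl unit *adjacent* to
an oxidized residue is likewise unaddressed; here release is gated only by
the NRE residue's own state. Every hydrolytic release consumes one water, and
a mass ledger asserts `Σ products = Σ parents + 18·cleavages` after every
digestion.

`pl_cleave()` implements lyase-type beta-elimination at a uronate: the bond
on the 4-side of a C6-carboxyl residue is cleaved without water, the proximal
fragment gains an ordinary reducing end and the uronate becomes the
4,5-unsaturated NRE (−18) of the distal fragment, so fragment masses sum
exactly to the parent. Sites are indexed 1-based from the NRE, so the valid
sites are `2..DP` — the uronate itself cannot be the outermost NRE residue,
which has no 4-side bond.

`pmo_simulate()` is a discrete-step, site-uniform stochastic model with four
independent per-site-per-step event probabilities: C1 cleavage (aldonic acid
on the proximal fragment's new RE), C4 cleavage (ketone on the distal
fragment's new NRE — the polarity conventional for this enzyme family), C6
hydroxymethyl→aldehyde, and C6 aldehyde→acid. No kinetic constants for these
activities are published in usable numeric form (the product-formation rates
exist only as a bar chart), so the rates are free parameters with documented
defaults; the simulator records per-step eligible-site and event counts so
that realized event totals can be checked against `rate × site-steps`
expectations, and is exactly reproducible under a seed.

## Synthetic data: what it does and does not emulate

`generate_pool()` wraps the simulator with named scenarios. `C1-only` and
`C6-only` isolate single activities. `paper-like-mixed` (150 chains of DP 15,
80 steps, rates `c1 = 0.004`, `c4 = 0.002`, `c6→aldehyde = 0.006`,
`c6→acid = 0.003`) runs both cleavage activities and the C6 ladder
concurrently and is sized so the pool reliably populates the delta classes
seen on annotated spectra of such digests — 0, −2, +12, +14, +16 and +28 —
at small seeds. These numbers were fixed once, by reasoning about event
co-occurrence (the +12 and +28 classes need two oxidation events on one
fragment), and are the package's standing definition of that scenario.

`render_spectrum()` plants one peak per distinct species at its cationized
m/z with log-normal intensities scaled by species count (log-normal is
generic MS practice; no intensity model is published for these data),
optional Gaussian m/z jitter, uniform noise peaks, and a detection threshold.
Ground truth is returned as a separate table sharing a run id with the peak
list — never embedded in the peaks — and `recovery_benchmark()` refuses
mismatched runs. The generator does **not** emulate MALDI matrix effects,
isotope clusters, detector saturation, or mass-dependent resolution; a
perfect noise-free round trip (recall 1.0, verified in the tests) therefore
shows the annotation plumbing is lossless, not that real spectra are this
clean.

## Numerical choices and problem sizes

* Half-up rounding (`floor(x + 0.5)`) everywhere an m/z is compared in
  nominal mode, so doubly charged half-integer masses behave predictably.
* Enumeration completeness is tested against an independently written naive
  nested enumeration over m/z 50–300 in both polarities; explanation
  completeness against an exhaustive positioned-state enumeration for
  DP ≤ 4, |delta| ≤ 40, cap ≤ 3.
* Mass conservation is checked over 1000 random digests; the event-rate
  check uses 20 chains of DP 100 for 200 steps; these sizes keep the whole
  suite around two minutes on one core while leaving the statistical checks
  well-powered.
* The mature-protein mass (34.89979 kDa) enters only as an input to the
  glycosylation arithmetic; recomputing it from sequence would require a
  database accession and is out of scope here.

## Limitations

The model is compositional, not structural: no stereochemistry, ring
conformation, anomeric state, isotope patterns, or charge-state inference
from isotope spacing. The degradation rules are qualitative pathway logic,
not Michaelis–Menten kinetics. mzML/mzXML readers are deliberately absent —
the package's native inputs are plain CSV/TSV peak lists with a JSON
sidecar — and would be a thin adapter if ever needed.
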