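# oxocello

Mass-spectrometric annotation of oxidized cello-oligosaccharides.

Fungal lytic polysaccharide monooxygenases (LPMOs, CAZy family AA9) degrade
cellulose oxidatively at C1, C4 and C6. The evidence for what an enzyme did
to a chain arrives as arithmetic: small integer mass shifts ("delta
classes") on the sodiated MALDI-TOF ladder of cello-oligosaccharides, dense
adduct/cluster-ion forests in full-scan ESI spectra of the monosaccharide
end products, and the way those shifts move after chemical (Br₂) oxidation
or enzymatic (beta-glucosidase / beta-glucuronidase / lyase) degradation.
oxocello is for analysts doing that arithmetic: it models the oxidation
states compositionally, enumerates candidate ions completely within explicit
bounds, and simulates the degradation pathways, so that peak assignments are
reproducible computations instead of margin notes.

## The model in brief

A chain of `DP` glucosyl residues (non-reducing end first) has nominal
neutral mass

```
M = 162·DP + 18 + Σ δ_i
```

with additive per-residue oxidation deltas: C1 carboxyl +16 (reducing end
only), C4 ketone −2, C6 aldehyde −2, C6 carboxyl +14, each lactone −18,
lyase-type 4,5-unsaturation −18. Observed MALDI peaks are `M + 23` (Na⁺);
ESI ions are `(Σ analytes + Σ carriers + Σ neutral adducts) / z` over
carriers {H⁺, Na⁺, NH₄⁺} (positive) or deprotonations with optional
Na-for-H exchange (negative), and neutral adducts {H₂O, NH₃, CH₃OH, HCOOH,
CH₃COOH}. Bromine water sends every free aldehyde (in-chain C6 and the free
reducing end) to a carboxyl: `post = pre + 16·(#aldehydes)`, ketones inert.

## Worked example

A chain string describes residues and their oxidation flags
(`c1` C1 acid, `c4k` C4 ketone, `c6d` C6 aldehyde, `c6a` C6 acid, `L`
lactone, `u` 4,5-unsaturation):

```r
library(oxocello)

oligo("G(c6d)-G-G")
#> <oligo> G(c6d)-G-G  dp=3  nominal mass=502 (delta -2)

maldi_series(3, -2)          # the sodiated ladder position of that species
#>      dp delta label     mz
#> 1     3    -2 DP3-2    525
```

A `−2` peak is ambiguous and a `+14` peak triply so; the explanation
enumerator makes the degeneracy explicit:

```r
delta_explanations(14, dp = 3)[, c("label", "delta")]
#> 1 C6-acid                  14
#> 2 C1-acid + C6-aldehyde    14
#> 3 C1-acid + C4-keto        14
```

Bromine-water oxidation resolves it — a C6 aldehyde moves to +30, a C4
ketone only to +14:

```r
delta_class(br2_transform(oligo("G(c6d)-G-G")))
#> [1] 30
```

Exo-digestion of a doubly oxidized chain releases the diagnostic
monosaccharides, with the water ledger checked on every run:

```r
digest(list(oligo("G(c6a)-G-G(c1,c6a)")))
#> <product_census>
#>   released monosaccharides:
#>     glucose x1
#>     glucuronic acid x1
#>     saccharic acid x1
#>   mass ledger: parents 548 + 36 (2 cleavages) = products 584
```

ESI peaks are annotated against the complete in-bounds enumeration, ranked
by parsimony:

```r
cfg <- annotation_config("positive")
enumerate_candidates(228, cfg)[1:3, c("rank", "label", "mz")]
#>  1     1 210 + NH4+           228
#>  2     2 178 + NH4+ + CH3OH   228
#>  3     3 192 + NH4+ + H2O     228

glance(annotate_peaklist(peaklist(c(195, 217, 228), polarity = "positive"), cfg))
#>   n_peaks n_assigned assignment_rate mean_candidates
#> 1       3          3               1            525.
```

The top hit at m/z 228 is ammoniated saccharic acid — the C1-/C6-dioxidized
end product whose presence demonstrates C6 oxidation at the reducing end.
`golden_check()` re-derives every transcribed decomposition of the published
positive- and negative-mode tables the same way.

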