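# hrdot

Characterization of hyperreflective dots in paired structural and
angiographic OCT B-scan stacks of the macula.

Hyperreflective dots are small bright foci seen in the nuclear layers of
the retina on optical coherence tomography (OCT) B-scans. In the vascular
inner nuclear layer (INL) most of them are capillaries of the deep plexus
seen in cross-section; in the avascular outer nuclear layer (ONL) they are
granular structures. Telling these apart — and, for presumed capillaries,
telling perfused from occluded segments using the motion-contrast channel
of angiographic OCT — is a route to mapping capillary non-perfusion in
vivo, e.g. in diabetic retinopathy. `hrdot` implements that grading
procedure as an automated, tested pipeline, together with a synthetic OCT
phantom that provides ground truth for validating every stage.

## The procedure

Given a dense structural B-scan stack (131 scans spaced 11 µm, 100-frame
averaging, 4.5 × 1 mm field), an angiographic stack (5.9 µm spacing,
7-frame averaging, 3 × 3 mm field, structural + motion-contrast channels)
and retinal layer boundaries:

1. **Detection** — after adaptive speckle suppression, local intensity
   maxima standing out ≥ 1.5× above the local background are marked in the
   INL band of the 500–1500 µm temporal parafoveal region, and over the
   full ONL (where only dots with axial diameter > 15 µm, clear of the
   adjacent layers by more than their own width, are counted). Each dot's
   axial diameter is its full width at half maximum; its location is
   `near_IPL` / `near_OPL` if attached to a plexiform layer boundary
   within half an axial pixel, else `inside_INL`.
2. **Tracing** — dots are linked greedily across adjacent B-scans (no
   gaps) into 3D elements; the conservative transverse extent of an
   element spanning *n* scans at spacing *s* is *s*(*n* − 1), a deliberate
   underestimate. Elements on ≤ 3 adjacent scans are **granules**
   (conservative extent ≤ 22 µm), elements on > 3 scans are **elongated**
   (≥ 33 µm).
3. **Perfusion** — the two stacks are aligned by maximizing the normalized
   cross-correlation of their en-face projections (shift + rotation;
   per-scan mapping trusted to ± 1 B-scan), each element's footprint is
   mapped onto the angiographic frame, and the fraction of its scans with
   interior motion-contrast signal decides between `perfused_filiform`,
   `nonperfused_filiform` (no interior signal, or signal consistently
   adjacent), `granule`, and `unclassifiable` (no angiographic correlate
   or inconsistent spatial characteristics). Projection artifacts from
   superficial vessels are flagged, never reclassified.
4. **Statistics** — per-subject grading rows (counts, class and location
   tallies with integer percentages, mean extents), group medians, and a
   two-sided unpaired Wilcoxon rank-sum test (exact for combined n ≤ 20
   without ties, tie-corrected normal approximation otherwise).

The package ships the per-subject grading table of the 8 diabetic patients
and 8 healthy controls (`table2_fixture()`) and a phantom generator
(`simulate_phantom()`) that renders paired stacks with layered
reflectivity, a foveal pit, gamma speckle whose variance scales as
1/(frames averaged), planted granules and capillary segments with a
perfusion flag, superficial vessels casting projection artifacts, and a
small rigid misregistration between the stacks.

## Worked example

```r
library(hrdot)

# reproduce the grading-table group medians from the packaged fixture
rep <- reproduce_table2()
head(rep, 4)
#>        row   group computed printed match
#> 1 inl_dots patient     13.0    13.0  TRUE
#> 2 inl_dots control      9.5     9.5  TRUE
#> 3 granules patient      3.0     3.0  TRUE
#> 4 granules control      2.0     2.0  TRUE

# group comparison of INL dot counts (patients vs controls)
fx <- table2_fixture()
w <- wilcoxon_rank_sum(fx$inl_dots[fx$group == "patient"],
                       fx$inl_dots[fx$group == "control"])
sprintf("U = %.1f, p = %.3f", w$statistic, w$p.value)
#> "U = 46.5, p = 0.122"

# simulate a phantom and run the full pipeline on it
ph  <- simulate_phantom(phantom_config(seed = 1))
res <- run_pipeline(ph$structural, ph$angio, ph$layers,
                    subject_id = "phantom-1", group = "patient")
res$transform
#> <alignment_transform> shift (16.5, 9.0) um, rotation 0.41 deg, r = 0.951
res$summary[, c("inl_dots", "granules", "elongated",
                "class_perfused", "class_nonperfused", "onl_dots")]
#>   inl_dots granules elongated class_perfused class_nonperfused onl_dots
#> 1       16        4        12             10                 2        2
```

The phantom planted 12 capillaries (2 non-perfused) and 4 granules in the
parafoveal INL plus 2 ONL granules; the pipeline recovered all 16 INL
elements, called both occluded capillaries non-perfused, and recovered the
planted misregistration of (15 µm, 8 µm, 0.5°) within the manual ± 1-scan
alignment tolerance.

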