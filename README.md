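# contactr

Quantification of lipid droplet–mitochondria membrane contact sites in
multi-channel confocal fluorescence images, with full per-cell
organelle morphometry.

Lipid droplets (LDs) and mitochondria form "metabolic synapse" contacts
through which lipids are transferred. Electron microscopy resolves
these contacts but does not scale; confocal microscopy scales but
cannot resolve a ~20 nm apposition directly. contactr implements the
standard image-analysis proxy: where a mitochondrion wraps a droplet,
the two channels are jointly bright and of comparable intensity, so a
contact can be detected as a colocalized band on the droplet boundary
and measured as a line.

## Method

For a three-channel section (nucleus *N*, lipid droplets *L*,
mitochondria *M*; pixel size *s* µm):

1. **Cells** are individualized without a membrane marker: maxima of
   the composite `0.2·L₈ + 0.2·M₈ + 255·nucleus_mask` (prominence 100)
   seed a watershed partition; the Huang-thresholded, median-filtered
   flattened image gives the cell foreground, which is cut along the
   watershed ridge lines and filtered by particle analysis
   (area ≥ 50 µm², must contain a nucleus).
2. **Droplets** are segmented by a trainable random-forest pixel
   classifier (Gaussian, difference-of-Gaussians, Sobel, Hessian and
   membrane-projection features), or by Yen thresholding as a
   fallback; touching droplets are split by a watershed on the
   distance transform.
3. **Mitochondria** are segmented by Otsu thresholding.
4. **Contacts**: a pixel is colocalized iff

   `L₈ > t_Yen(L)  ∧  M₈ > t_Otsu(M)  ∧  100·min(L₈,M₈)/max(L₈,M₈) > 50`

   The colocalization mask, cut per droplet, is skeletonized
   (Zhang–Suen) and every 8-connected skeleton component is one
   contact site of length `n_orth·s + n_diag·s·√2` (isolated pixel:
   `s`).
5. **Per-cell table**: areas, perimeters, counts, contact totals, and
   the contact efficiency `Σ contact length / Σ LD perimeter`.

Everything is deterministic: seeded training, single-threaded forests,
bit-reproducible watersheds.

## Worked example

The package ships a scene generator with analytic ground truth, so the
whole pipeline can be exercised without data:

```r
library(contactr)

# train the droplet classifier on one synthetic scene
train_scene <- generate_scene(scene_spec(width = 320, height = 320,
                                         n_cells = 1, n_ld_per_cell = 4,
                                         cell_radius_um = 8, snr = 20,
                                         seed = 1))
model <- train_ld_classifier(
  list(list(plane = train_scene$stack$planes$ld,
            labels = train_scene$truth$ld_labels > 0)),
  config = feature_config(sigmas = c(1, 2, 4)), n_trees = 100, seed = 1)

# analyse a different scene
scene <- generate_scene(scene_spec(width = 320, height = 320, n_cells = 1,
                                   n_ld_per_cell = 4, cell_radius_um = 8,
                                   snr = 20, seed = 42))
analysis <- analyze_stack(scene$stack, contactj_config(), model = model,
                          image_id = "demo")
analysis
#> contactj_analysis 'demo': 1 cell(s), 4 LD(s), 2 contact(s), total 2.967 um

round(t(analysis$records[, c("cell_area_um2", "n_ld", "n_mito",
                             "ld_total_perimeter_um", "n_contacts",
                             "contact_total_length_um",
                             "contact_efficiency")]), 3)
#> cell_area_um2           138.150
#> n_ld                      4.000
#> n_mito                   13.000
#> ld_total_perimeter_um    30.858
#> n_contacts                2.000
#> contact_total_length_um   2.967
#> contact_efficiency        0.096

sum(scene$truth$contacts$length_um)   # planted ground truth
#> [1] 3.046851
```

The scene carried two planted contact arcs totalling 3.047 µm; the
pipeline reports both contacts with a total of 2.967 µm (−2.6%). The
cell holds all four droplets (30.9 µm of droplet perimeter), of which
9.6% is engaged in contacts.

For folders of real TIFFs use `run_batch(input_dir, output_dir,
contactj_config(...))`, which writes `results.txt` (one row per cell,
traceable by image and cell id), a per-contact CSV, per-image label
maps and a JSON run log. A command-line wrapper with `analyze`,
`train` and `simulate` subcommands is installed at
`system.file("cli", "contactr.R", package = "contactr")`.

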