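# sddliver

Fully automatic segmentation of the liver in abdominal CT slices, and 3D
reconstruction of its surface, for image-analysis work where no training data
is available.  The package is aimed at medical-image researchers who want a
deterministic, training-free baseline segmentation, and at method developers
who need its building blocks (multilevel histogram thresholding, binary
Markov-random-field denoising, constraint-based segmentation, contour
resampling and stacking) as tested, reusable functions.

## The method

The liver borders organs whose CT intensity can equal its own, so no single
threshold delineates it.  `sddliver` instead derives **multiple thresholds**
from the **slope difference distribution** of the slice histogram: with the
histogram `P` rescaled to intensities 1..255, max-normalized and band-limited
by a low-pass DFT filter (bandwidth `W = 12`), two lines are fit by least
squares through the `N = 20` points left and right of every intensity `i`,
and

```
s(i) = a_left(i) - a_right(i)
```

dips to a negative valley at every class-separating intensity.  The detected
valleys are assigned anatomical roles by rank and class mass — `T1` bones,
`T2` body, `T3` adjacent organ, `T4` liver — and each structure is segmented
by its own threshold.  The bright bones yield a least-squares quadratic
**rib curve** through the rib and spine centroids; the body mask minus its
`N_c`-fold erosion (`N_c` = average rib width) yields a **margin ring**; the
organ threshold, cleaned by Ising-prior ICM denoising and
erosion/dilation-based morphological filtering and merging, yields the
**organ constraint**.  The liver is then

```
I_liver = 1  iff  I >= T4  and  curve = ring = organ = 0 ,
```

cleaned, reduced to its largest blob, and its boundary smoothed with a
penalized spline (weight `1 - alpha` on fidelity, `alpha = 0.5` on curvature).
Per-slice boundaries are resampled to 200 equally spaced points, aligned,
stacked at physical spacing, smoothed along z with the same spline criterion,
and exported as a watertight triangle mesh.  Segmentation quality is reported
with the community metrics VOE, RVD, ASD, RMSD, MSSD and Dice.

A deterministic synthetic abdominal phantom (elliptical body, rib arc, spine,
liver, same-intensity muscle wedge, case-dependent adjacent organ, Gaussian
noise, full ground-truth masks, stack mode) makes every stage testable
without any external data.

## Worked example

```r
library(sddliver)

ph  <- generate_slice(phantom_spec("stomach", seed = 42))
ph
#> Phantom slice (stomach case): 220x220 px, liver area 6259 px

res <- process_slice(ph$image)
res
#> Liver slice segmentation
#>   thresholds: T1=213 (bones) T2=35 (body) T3=138 (organ) T4=102 (liver)
#>   liver area: 6747 px; boundary: 270 vertices

evaluate_segmentation(res$liver, ph$masks$liver)
#> VOE 7.94%  RVD +7.80%  ASD 1.748 mm  RMSD 3.828 mm  MSSD 12.000 mm  Dice 0.9586
```

The four thresholds land in the four inter-class gaps of the phantom
(background|body, body|liver, liver|stomach, stomach|bone); the segmented
liver overlaps the ground truth with Dice 0.96, the +7.8 % volume excess
being the sliver of same-intensity body-wall muscle that survives inside the
rib curve.  A stack reconstructs to a surface whose enclosed volume matches
the voxel ground truth:

```r
st      <- generate_stack(phantom_spec("stomach", seed = 42), n_slices = 20,
                          profile = "sphere")
results <- process_stack(lapply(st$slices, function(s) s$image))
reconstruct_surface(results)
#> Reconstructed liver surface: 20 slices x 200 boundary points
#>   enclosed volume: 84283.7
st$liver_volume
#> [1] 84108
```

A thin command-line interface wraps the same functions
(`inst/cli/liverseg.R`; subcommands `phantom`, `segment`, `reconstruct`,
`evaluate`, `calibrate`).

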