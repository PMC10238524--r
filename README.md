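# mvmar: metal artifact reduction for kV-CT using a megavoltage CBCT prior

Dental implants and other metal hardware produce severe streak and shading
artifacts in kilovoltage CT of the head and neck — photon starvation along
metal rays and beam hardening corrupt exactly the slices radiotherapy
planning depends on, and with several metal objects the artifacts interact
and get worse. Megavoltage CBCT acquired on the treatment linac sees the
same anatomy almost without metal artifacts (at MV energies metal is nearly
transparent), but its gray values are not accurate enough to plan on.

`mvmar` implements a projection-domain correction that uses the MV image
only for what it is good at — anatomy — and keeps the kV image for what it
is good at — CT values:

1. The MV prior is segmented block-wise (8×8-pixel blocks, two-threshold
   Otsu per block) into high-density **M1** (bone + metal), medium-density
   **M2** (soft tissue) and low-density **M3** (cavities/air). The metal
   region **M**<sub>metal</sub> is thresholded directly in the kV image.
2. A template image is built from the kV image:

   *I*<sub>template</sub> = *I*<sub>CT</sub> on M1, mean(*I*<sub>CT</sub> | M2) on M2,
   mean(*I*<sub>CT</sub> | M3) on M3.

3. The sinogram difference *P*<sub>MetalDiff</sub>(θ,k) =
   FP(*I*<sub>CT</sub>) − FP(*I*<sub>template</sub>), restricted to the metal trace
   {(θ,k) : FP(M<sub>metal</sub>) ≠ 0}, isolates the metal-induced signal
   deviation; linear boundary ramps take it smoothly to zero so the cut
   itself does not back-project into new streaks.
4. The artifact image HFF[BP(*P*<sub>interp</sub>)] (filtered back-projection
   followed by a Gaussian high-frequency suppression) is subtracted from
   the original kV image; metal pixels are restored from the input.
5. The template means are recomputed from the corrected image and the pass
   repeats (3 iterations by default), de-biasing the fill values step by
   step.

The package also provides **LIMAR** (plain linear interpolation of the
metal trace) and **NMAR** (prior-normalized interpolation) baselines, the
standard evaluation metrics (ROI mean CT value, noise SD, MRE, NRMSD,
MAD), a parallel-beam projector/FBP pair, and a polychromatic dual-energy
simulator (Beer–Lambert with a discrete spectrum, Poisson counting noise,
photon-starvation clamp, water beam-hardening precorrection) that
generates co-registered kV / MV / ground-truth slice triples, so the whole
pipeline is testable without scanner data.

## Worked example

Simulate the multi-metal dental phantom (three amalgam-like inserts along
a jaw arc, 128×128 grid, 2 mm pixels), correct it with all three methods
and compare against the noiseless ground truth:

```r
library(mvmar)
res <- mar_demo(out_dir = "demo_out", seed = 1, size = 128)
res$report[res$report$roi == "inter_metal",
           c("method", "mean_hu", "noise_hu", "ref_mean_hu", "mre_2dp", "nrmsd", "mad")]
```

```
   method mean_hu noise_hu ref_mean_hu mre_2dp nrmsd   mad
 original   405.3    324.0       64.49    5.28 2.105 379.4
 proposed   108.6    232.2       64.49    0.68 1.259 218.3
    limar   162.7    167.8       64.49    1.52 1.358 241.7
     nmar   319.4    299.6       64.49    3.95 1.879 316.9
```

The `inter_metal` ROI sits in soft tissue between the dental inserts,
where their artifacts interact. The uncorrected kV mean is 405 HU against
a 64 HU reference — the bright/dark streak bias — with NRMSD 2.11. The
MV-prior correction brings the mean to 109 HU and has the lowest NRMSD
and MAD of all methods; LIMAR and NMAR improve on the original but are
limited by interpolation information loss and by their artifact-corrupted
self-prior, respectively. `demo_out/` contains every image as CSV, the
report as CSV/JSON and a provenance sidecar; rerunning with the same seed
reproduces all of them byte for byte.

The same pipeline runs from the shell:

```sh
exec/mvmar demo --out demo_out --seed 1 --size 128
exec/mvmar correct --kv kv.nii.gz --mv mv.nii.gz --out corrected.nii.gz --method proposed
exec/mvmar evaluate --images prop=corrected.csv --reference truth.csv --rois rois.yaml --out report.csv
```

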