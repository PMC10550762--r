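# noiseletHE

Noiselet-space background removal for nuclei detection in H&E
histopathology images.

## The problem

Computer-aided diagnosis in digital pathology starts with detecting and
segmenting cell nuclei in hematoxylin & eosin (H&E) stained images.
Classical detectors struggle because non-nuclei structures — fibrous
stroma, tissue folds, interstitial tissue, vessels — span a broad
frequency spectrum and are easily mistaken for nuclei. `noiseletHE`
implements a preprocessing step that learns what this background looks
like and removes it *before* detection, plus the baseline detector and
the evaluation machinery to measure the effect.

## The method

1. **Stain separation.** The RGB image is converted to optical density
   (Beer–Lambert, `od = -log(I/I0)`) and unmixed into hematoxylin and
   eosin concentration maps with Macenko-style estimation: the stain
   vectors are the extreme-angle directions of the foreground OD cloud
   in its top-2 singular plane.
2. **Noiselet patch coding.** The hematoxylin map is split into small
   patches (2×2 to 8×8). Each patch is projected onto the noiselet
   basis, the complex Haar–Walsh family built from the recursion

       f1(x)     = χ[0,1)(x)
       f2n(x)    = (1-i) fn(2x) + (1+i) fn(2x-1)
       f2n+1(x)  = (1+i) fn(2x) + (1-i) fn(2x-1)

   normalized to be unitary. Noiselets spread localized signals flatly
   across the spectrum and place low- and high-frequency content 90°
   apart in the complex plane, so smooth nuclear patches and broadband
   stromal patches land in different regions of feature space.
3. **Code-book.** Patch features (real and imaginary coefficient
   blocks) are clustered by k-means under city-block (L1) distance with
   coordinate-wise-median updates; the K centroids form the code-book.
4. **Tile classification.** Non-overlapping tiles (8–24 px) are encoded
   as histograms of their patches' codeword assignments, and an
   AdaBoost ensemble of decision stumps classifies each tile as
   nuclei vs non-nuclei. Non-nuclei tiles are blanked.
5. **Detection/segmentation.** A fast radial symmetry transform (FRST)
   seeds a marker-controlled watershed on the (cleaned) hematoxylin
   map; regions are filtered by area, roundness (4π·area/perimeter²)
   and solidity.
6. **Evaluation.** Detection F1 with one-to-one centroid matching
   (true positive when masks intersect and centroids are < 12 px
   apart; `F1 = TP / (TP + (FP+FN)/2)`), segmentation Dice
   `2|A∩B|/(|A|+|B|)`, and the Pearson correlation between annotated
   and detected nucleus counts.

A seeded synthetic H&E generator (elliptical hematoxylin-dominant
nuclei with unimodal or bimodal chromatin over eosin-dominant fibrous /
fold textures) provides ground truth so the whole pipeline is testable
without external data.

## Worked example

Leave-one-out experiment on four synthetic fields: for each held-out
image a code-book and tile denoiser are trained on the other three,
and the held-out image is segmented with and without background
removal.

```r
library(noiseletHE)

samples <- generateDataset(4, syntheticParams(imageSize = c(256L, 256L),
                                              nNuclei = c(8L, 14L)), seed = 7)
res <- runExperiment(samples, pipelineConfig())
round(res$perImage[, c("nTrue", "fBaseline", "fDenoised",
                       "diceBaseline", "diceDenoised")], 3)
#>   nTrue fBaseline fDenoised diceBaseline diceDenoised
#> 1    12     0.783     1.000        0.656        0.907
#> 2    12     0.800     0.762        0.874        0.788
#> 3     9     0.824     0.941        0.731        0.889
#> 4     8     0.875     0.941        0.761        0.881
```

Mean detection F-score rises from 0.820 to 0.911 and mean Dice from
0.756 to 0.866: removing stromal and fold signal both recovers nuclei
the baseline missed (fewer false negatives) and suppresses spurious
blob detections in textured background (fewer false positives). At
this small scale the count correlation is computed over only four
images and is unstable; the acceptance script (below) measures it over
eight larger fields.

Single-image use:

```r
s   <- generateSample(syntheticParams(seed = 1))
seg <- segmentNuclei(sampleImage(s))      # baseline watershed pipeline
seg                                       # NucleiSegmentation, shows count
matchNuclei(seg, segmentationFromMask(nucleiMask(s)))
```

A thin command-line wrapper with `simulate`, `segment`, `evaluate` and
`grid-search` subcommands lives at `inst/scripts/noiselethe-cli.R`.

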