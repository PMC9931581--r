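# spotcode

Barcoded smFISH simulation, decoding and spatial analysis.

## What this is for

Highly multiplexed single-molecule FISH encodes each gene as a binary
codeword over cyclic hybridization rounds: a gene's molecules fluoresce
only in the rounds where its codeword bit is 1, so hundreds of genes fit
into 16 imaging rounds of a single color channel. Turning the raw
per-round spot tables into a cells × genes expression matrix — and then
into tissue-level spatial statistics — requires a chain of well-defined
computational steps, each of which this package implements and tests:

* **Codebook** — constant-weight binary codes (16 bits, weight 6, minimum
  pairwise Hamming distance 4, ≥ 448 codewords) built by a deterministic
  checksum-class construction; nearest-neighbour decoding that corrects
  one bit error and refuses ambiguous words; blank (empty) barcodes for
  false-positive estimation.
* **Probe design** — tiled 26–32 nt encoding probes filtered on
  nearest-neighbour binding energy (ΔG°₃₇ ≤ −28 kcal/mol), G+C 40–60%,
  self-structure (hairpin/homodimer ΔG ≥ −9 kcal/mol) and a k-mer
  off-target screen; greedy tiling with a 2 nt gap, ≤ 28 probes per gene,
  genes with < 10 probes dropped; full oligo assembly with six readout
  tails and alternating 2-nt spacers.
* **Simulation** — ground-truth scenes (cells, molecules, ambient
  background, fiducial beads), a per-round bit-error model (dropout,
  spurious gain, localization jitter, per-round drift), and 16-bit image
  rendering, so every downstream stage can be scored against known truth.
* **Spot pipeline** — difference-of-Gaussians filtering, robust-threshold
  local-maximum detection with subpixel refinement, annulus SNR, and
  iterative nearest-neighbour similarity registration on fiducial beads
  (across rounds and across magnifications).
* **Decode & assign** — spot aggregation into molecules via a proximity
  graph, codebook decoding, blank-based false-positive rates,
  segmentation-mask expansion by 8 µm without overlap, and k-d-tree-style
  molecule-to-cell assignment into a sparse count matrix.
* **Spatial statistics** — hexagonal-bin regionalization
  (connectivity-constrained Ward on PCA/LDA reductions, spectral region
  colours, random-forest colour mixing), border strength/angle fields,
  Ripley's K/L with isotropic edge correction, DBSCAN-based
  lateral-diffusion profiling, optical-crowding simulation against the
  Abbe limit, and cross-section region linking.

The mathematical core: codewords are weight-6 words x ∈ {0,1}¹⁶ in the
largest residue class of the checksum s(x) = Σᵢ i·xᵢ mod 16, which
guarantees pairwise distance ≥ 4; decoding calls the unique codeword c
with d_H(w, c) ≤ 1; border strength at a point is
max over split angles θ of ‖n₁(θ) − n₂(θ)‖₂ over per-gene half-disk
counts; Ripley's L is √(K/π) with K(r) = (A/n²) Σ wᵢⱼ 1(dᵢⱼ ≤ r).

## Worked example

```r
library(spotcode)

## codebook: 504 codewords exist; a 448-word panel leaves 8 blanks
cb <- generate_codebook(16, 6, 4)
cb448 <- subset_codebook(cb, 448)
cb448
#> codebook: 448 codewords (16 bits, weight 6, min distance 4)
length(assign_genes(cb448, sprintf("Gene%03d", 1:440))$blanks)
#> [1] 8

## simulate a 20-gene, 200-cell acquisition with 5% bit dropout
prof  <- example_profiles(n_genes = 20, n_types = 4)
asg   <- assign_genes(cb, rownames(prof))
scene <- simulate_scene(prof, n_cells = 200, extent = c(600, 600),
                        ambient_rate = 8e-4, bead_density = 6e-4,
                        cell_radius_um = 6, seed = 1)
scene
#> scene: 600 x 600 um, 200 cells, 1116 molecules, 205 beads
ro <- simulate_readout(scene, asg$codebook,
                       acquisition_config(p_dropout = 0.05, seed = 2))
nrow(ro$spots)          # per-round spots incl. beads
#> [1] 9637

## aggregate spots into molecules and decode
dec <- decode_molecules(aggregate_rounds(ro$spots, 0.3), asg$codebook)
nrow(dec$molecules) / nrow(ro$truth)   # recall vs ground truth
#> [1] 0.955
blank_fpr(dec, asg$codebook)$mean      # blank rate: no gain errors -> 0
#> [1] 0
cor(as.numeric(table(factor(ro$truth$gene, levels = rownames(prof)))),
    as.numeric(dec$per_label[rownames(prof)]))
#> [1] 0.9994
```

The recall of 0.955 sits just below the binomial prediction for one
correctable dropout, 0.95⁶ + 6·0.05·0.95⁵ ≈ 0.967; the gap is the
percent-level loss from molecules closer together than the 0.3 µm link
radius. The per-gene count correlation with truth exceeds 0.999 and the
eight blank barcodes are never called when no spurious bits are
simulated.

A thin command-line wrapper over the same functions is installed at
`inst/cli/spotcode.R` (subcommands `codebook`, `design`, `simulate`,
`decode`, `crowding`).

## Documentation

Every exported function carries roxygen documentation; the methods
vignette (`vignettes/spotcode-methods.Rmd`) describes the models, the
error model and its assumptions, parameter defaults with units, the
numerical choices, and known limitations.
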