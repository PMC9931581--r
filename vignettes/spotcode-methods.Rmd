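---
title: "spotcode: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotcode: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotcode)
```

# Overview

`spotcode` implements the computational core of highly multiplexed,
barcoded single-molecule FISH: instead of imaging one gene per round, each
gene is assigned a binary codeword over 16 cyclic hybridization rounds, and
a molecule is called by the pattern of rounds in which it fluoresces. The
package covers the full in-silico path — codebook construction and
error-correcting decoding, encoding-probe panel design, simulation of
multi-round acquisitions with a known ground truth, spot detection and
fiducial-bead registration, molecule aggregation and cell assignment, and
the spatial statistics used to analyse the resulting molecule maps
(regionalization, border fields, Ripley's L, diffusion profiling, optical
crowding).

Everything downstream of the codebook is validated against simulation:
the scene generator knows every molecule's gene, position and source cell,
so detection recall, decoding recall, registration accuracy and the
spatial statistics can all be scored exactly.

# Barcode codebook

Codewords are binary vectors of length $n = 16$ (one bit per readout
round) with constant Hamming weight $w = 6$ and minimum pairwise distance
$d = 4$. Weight constancy equalizes the per-gene fluorescence budget;
$d = 4$ allows correcting one bit error per molecule while detecting two.

For $d = 4$ the construction is deterministic and seed-free: enumerate all
$\binom{16}{6} = 8008$ weight-6 words, compute the position checksum
$s(x) = \sum_i i\,x_i \bmod 16$ (positions 0-based) and keep the largest
residue class, breaking ties toward the smallest residue. Two distinct
equal-weight words in one class cannot differ in exactly two bits — moving
a single set bit from position $i$ to $j$ changes the checksum by
$j - i \not\equiv 0 \pmod{16}$ — so the class has $d \ge 4$. The largest
class has 504 codewords, comfortably above both the pigeonhole bound
$\lceil 8008/16 \rceil = 501$ and the 448 words a single-channel panel
uses. Experiments that want a specific capacity take a deterministic
prefix with `subset_codebook()` (e.g. 448 words so a 440-gene panel
carries exactly 8 blank controls). For distances other than 4 the
generator falls back to a greedy lexicographic accept/reject scan.

Decoding is nearest-neighbour with bounded correction: a word is called
as the unique codeword within Hamming distance `max_correct` (default 1).
Ambiguity — two codewords at the same minimal distance — is a no-call,
never an arbitrary pick, because blank-based false-positive estimation
would otherwise be biased by silent mis-calls. Codewords left unassigned
after `assign_genes()` become blanks, ordered lexicographically so the
blank set is reproducible.

When co-expression groups are supplied, gene-to-codeword assignment
minimizes, summed over rounds, the number of same-group gene pairs lit in
the same round (optical space in a round is a shared resource). The
optimizer is greedy insertion followed by pairwise-swap hill climbing
under a fixed seed; without groups the assignment is deterministic in
input order.

# Probe design

Each encoding probe carries a 26–32 nt transcript-binding sequence plus a
tail with the six 20-nt readout sequences of the gene's "on" bits.
Candidate windows are scored by:

* **Binding energy** — nearest-neighbour $\Delta G^\circ_{37}$ summed over
  stacked dimers with terminal initiation penalties (unified DNA/DNA
  parameter table shipped as a CSV asset). Kept if $\le -28$ kcal/mol.
  Probes bind RNA; the DNA/DNA table is the calibration reference for the
  threshold, and no salt or temperature corrections beyond the 37 °C table
  are applied.
* **Composition** — G+C between 40 and 60%.
* **Self-structure** — minimum $\Delta G$ over self-complementary stems,
  found by scanning all antiparallel self-alignment registers; every
  hairpin stem is also an ungapped self-alignment with the same stem
  energy, so the register scan covers both hairpins and homodimers.
  Kept if $\ge -9$ kcal/mol.
* **Specificity** — a seed-and-extend screen (12-mer exact seeds, ungapped
  extension) against the other panel transcripts; a probe fails when five
  or more distinct off-target species contain a window above 60%
  identity. This is a deliberate proxy for a full alignment search, which
  is out of scope.

Surviving candidates are tiled greedily left-to-right with a minimum
inter-probe gap of 2 nt, capped at 28 probes; genes retaining fewer than
10 probes are dropped and reported. Assembled oligos place the entire
binding sequence 5′, followed by the six readouts in a per-probe
randomized order (seeded), each preceded by a 2-nt spacer cycling TT, AT,
TA, AA. The spacer-before-every-readout convention (total tail
$6 \times 22 = 132$ nt) is recorded in the panel file header, since the
alternative (no spacer before the first readout) is equally defensible.

# Scene simulation

`simulate_scene()` draws non-overlapping cell disks uniformly (rejection
sampling), Poisson per-cell molecule counts from per-type rate profiles,
uniform molecule positions within each disk, a homogeneous ambient
molecule background and uniform fiducial beads.
`example_profiles()` provides the default study conditions: log-normal
rates with per-type marker blocks, scaled to a mean of 4 molecules per
cell for a 20-gene panel — matching the sparse per-cell loads of
surface-captured data once a genome-scale panel is cut down to 20 genes —
on a 600 × 600 µm extent with 200 cells of 6 µm radius and an ambient
rate of 8 × 10⁻⁴ µm⁻².

`simulate_readout()` implements the bit-error model: each "on" bit emits
a spot with probability $1 - p_\text{dropout}$; each "off" round gains a
spurious colocated spot with probability $p_\text{gain}$ (modelling probe
cross-talk; a uniform false-spot rate would be a separate mechanism).
Spots are jittered by a localization error $\sigma_\text{loc}$ (default
0.05 µm) and mapped through per-round similarity drift transforms.
No published quantitative bit-error rates exist for this class of
protocol; the defaults exercise the decoder rather than estimate a real
instrument.

`render_round_image()` produces 16-bit images as sums of Gaussian PSF
kernels (default $\sigma = 1.2$ px at 0.18 µm/px — an 11 µm camera pixel
behind a 60× objective) over constant background with Poisson shot noise
and Gaussian read noise. One coordinate convention holds package-wide:
microns, origin at the image top-left, y down, pixel index
$\lfloor \text{coord}/\text{pixel size} \rfloor$ (0-based).

What the generator does *not* emulate: z-structure (everything is 2D, as
appropriate for surface-captured molecules), optical aberrations and
field curvature, intensity variation between probes of one gene,
stitching of overlapping fields, and autofluorescent debris. Passing the
simulation benches therefore demonstrates correctness of the algorithms
under the stated error model, not end-to-end performance on real images.

# Spot detection and registration

Images are band-passed by difference of Gaussians (defaults 1 and 5 px)
with negatives clipped; spots are strict 3×3 local maxima above
`median + 5 × robust sd`. The robust sd is the larger of the MAD and an
upper-quartile half-normal estimate — on a zero-clipped DoG image half
the pixels are exactly zero, which can collapse the MAD to zero or nearly
so. Non-maximum suppression keeps the brightest detection within 3 px,
and subpixel positions come from Gaussian (log-parabolic) interpolation
over the 3×3 window with an intensity-weighted-centroid fallback; on the
package's simulated bench this localizes isolated spots to well under
0.1 px RMSE.

Per-spot SNR follows the annulus definition: peak signal over the
standard deviation of background pixels in a 3–9 px annulus, with pixels
near other detected spots excluded from the background.

Rounds are registered on fiducial beads by iterative nearest-neighbour
similarity estimation: mutual (symmetric) nearest-neighbour matching
within 2 µm, closed-form least-squares similarity fit (Procrustes/
Umeyama) on the matches, iterated to a 10⁻⁶ parameter tolerance.
Mutual matching suppresses false pairs from unpaired beads; the
translation is initialized from coordinate medians for outlier
robustness. Registration across magnifications uses the same estimator
with the known objective ratio as the scale initialization. With 200
beads and 0.05 µm localization noise, simulated drift (scale 0.99–1.01,
rotation up to 2°, shifts up to 5 µm) is recovered to a translation error
well below 0.05 µm at the field centre.

# Molecule aggregation, decoding and cell assignment

Registered spots from different rounds within 0.3 µm are joined into a
graph whose connected components are candidate molecules; a component's
word has bit $r$ set iff it holds a spot from round $r$. Components with
several spots in one round are deduplicated by keeping the spot nearest
the component centroid. The 0.3 µm default is about six times the
localization error, small enough that distinct molecules rarely chain;
two same-gene molecules closer than the radius still merge into one
candidate — an intrinsic resolution limit shared with the real assay
(optical crowding), which is why the per-cell loads of the default bench
matter. Under the default conditions with $p_\text{dropout} = 0.05$ the
decoded recall tracks the binomial prediction
$0.95^6 + 6 \cdot 0.05 \cdot 0.95^5 \approx 0.967$ minus a percent-level
crowding loss.

The blank false-positive rate is, per blank codeword, its decoded count
over all decoded molecules, summarized as mean ± sd across blanks. The
"per gene" normalization of such rates is ambiguous in general; the
formula used here is fixed and recorded so numbers are comparable across
runs. Blank calls require at least two dropouts plus two gains landing on
a neighbouring codeword, so the rate is exactly zero at zero error rates
and grows with the gain rate.

Nuclear segmentation masks (consumed as label images; segmentation itself
is out of scope) are expanded by 8 µm via a per-label Euclidean distance
transform: a background pixel takes the label of its nearest labelled
pixel if within range, ties to the smaller label, original labels never
reassigned — so expanded cells are disjoint by construction. Molecules
are assigned by direct pixel lookup after mapping through the
stain-to-molecule transform; counts aggregate into a sparse cells × genes
matrix with blanks excluded but reported, and
`assigned + unassigned = total` holds exactly.

# Spatial statistics

**Hex binning.** Pointy-top axial lattice, default spacing 100 µm (the
bin size is an analysis resolution choice, not a measured constant);
molecules map to the nearest centre by cube rounding, so counts are
conserved exactly.

**Regionalization.** Per-hex counts are depth-normalized (scaled to the
median hex total, then log1p — a conventional choice, recorded here
because no canonical normalization exists for binned molecule counts),
reduced by PCA or a small collapsed-Gibbs LDA topic model, and clustered
by Ward agglomeration constrained to merge only lattice neighbours, so
regions are spatially connected by construction. Region colours are
assigned along the Fiedler vector of a region-similarity graph
(correlation of region mean expression), giving transcriptionally similar
regions similar hues. `mix_region_colors()` trains a random forest (100
trees, fixed seed) on hex expression versus region label and colours each
hex by the probability-weighted mixture of region colours, rendering
gradients that hard labels hide.

**Border field.** At each grid point, molecules within 200 µm are split
in half by 12 equally spaced lines; the border strength is the maximum
Euclidean distance between the per-gene count vectors of the two
half-disks, and the border angle is the maximizing line's orientation in
[0, 180)°. The raw count distance is the default metric (a
count-normalized variant is available via `normalize = TRUE`). Near the
edge of the sampled tissue the disk itself is asymmetric, which produces
genuine nonzero strengths unrelated to expression borders; interpret the
field inside the data margin.

**Ripley's L.** $K(r) = \frac{A}{n^2}\sum_{i \ne j} w_{ij}\,
\mathbf{1}(d_{ij} \le r)$ with isotropic edge correction (the inverse
fraction of the pair circle inside the rectangular window; toroidal and
uncorrected variants available), reported as $L(r) - r = \sqrt{K/\pi} - r$.
Complete spatial randomness stays within its Monte-Carlo envelope;
cell-sized molecule clusters peak near the cell diameter (~10 µm).

**Diffusion profile.** Molecules of a marker gene are clustered with
DBSCAN (default eps 8 µm, min 5 points — eps must exceed the expected
molecule spread, otherwise the displacement tail is truncated and the
median biased low); distances to cluster centroids are pooled and the
50% radius reported. For isotropic Gaussian spread the expected median is
$\sigma\sqrt{2\ln 2}$.

**Optical crowding.** Uniformly scattered points in a 10 × 10 µm² area
are resolvable iff the nearest neighbour is at least the Abbe limit
$\lambda/(2\,\mathrm{NA})$ away; the mean resolvable fraction versus
point count tracks the Poisson void-probability approximation
$\exp(-n\pi d^2/A)$ in the sparse limit.

**Cross-section linking.** Regions of two sections are linked by Pearson
correlation of their mean-expression vectors over shared genes, greedily
matched above a threshold (default 0.7).

# Numerical and implementation notes

* DBSCAN, the constrained Ward agglomeration, the Ripley estimator with
  isotropic rectangle correction and the collapsed-Gibbs LDA are
  implemented in the package (no installed R package provides them in the
  required constrained/edge-corrected form); each is validated against
  constructed ground truth or closed-form expectations in the test suite.
* Pair searches over spot tables use a uniform grid hash, so aggregation
  scales with local density rather than the square of the table size.
* Decoding uses the identity $d_H(w, c) = |w| + |c| - 2\langle w, c
  \rangle$, reducing bulk decoding to one matrix product.
* All stochastic steps take explicit seeds; equal seeds give
  byte-identical outputs.
* Test and bench problem sizes — 200-cell scenes, ~200 beads, 512² px
  images, a few thousand molecules for the spatial statistics — were
  chosen so the full suite exercises every code path at desk scale while
  keeping the statistical tolerances meaningful (e.g. 3-seed recall
  averages against a ±2% band).

# Known limitations

* The point-based spot-to-molecule aggregation is one formalization of an
  under-specified step; it is validated against simulation ground truth
  only.
* Probe thermodynamics uses DNA/DNA parameters at 37 °C for DNA–RNA
  hybrids and the off-target screen is a k-mer proxy, not an aligner.
* Merged same-gene molecules within the link radius are counted once;
  recall benches account for this crowding loss only through the sparse
  default conditions.
* Multi-channel panels are supported only as independent per-channel
  codebooks; maximal code search and stitching of overlapping fields of
  view are out of scope.
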