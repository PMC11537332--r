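---
title: "framedock: model, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{framedock: model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

framedock predicts the bound pose of a small-molecule ligand against a
rigid protein without being told where the binding pocket is (blind rigid
docking), and additionally predicts a binding affinity and exposes an
interpretability analysis of its learned ligand representation. This
vignette documents the model, its assumptions, the tunable parameters, and
the design decisions made where more than one reasonable choice existed.

## The model

The network follows the two-stage design used by modern structure
prediction models. Inputs are a protein backbone (N/Cα/C per residue) and a
ligand chemical graph with a 3D conformer.

**Representations.** A *single* representation stacks one row per protein
residue and one row per ligand heavy atom. A *pair* representation holds
one feature vector per ordered row pair, laid out as a protein block, a
ligand block and two mixed off-diagonal blocks. Protein rows embed residue
identity and a chain-position scalar. Ligand rows embed element, heavy-atom
degree, formal charge, aromaticity, ring membership, implicit-hydrogen
count, and the canonical atom index (one-hot up to 32 plus a scalar).
The index features deserve a note: they give each atom a stable identity
under the deterministic canonical ordering and, after mean pooling, give
molecule-level embeddings access to molecule size — an extensive quantity
that intensive per-atom features alone cannot carry through an arithmetic
mean. The pair representation receives linear embeddings of the single
rows (all blocks) plus block-internal geometry: residue–residue Cα
distances as 16 Gaussian radial basis functions with centers spanning
0–20 Å, relative sequence positions clipped at ±32, atom–atom conformer
distances (same RBFs), the ligand adjacency matrix and bond orders.
Crucially the mixed blocks carry **no** distances — the pose is unknown at
input time — which makes the whole feature pipeline independent of how the
input conformer is placed relative to the protein.

**Trunk.** A stack of attention blocks (12 in the shipping configuration)
updates both representations. Each block applies row-wise gated
self-attention with pair bias, a feed-forward transition, a low-rank outer
product update from the single into the pair, triangle multiplicative
updates (outgoing and incoming edges), triangle attention (starting and
ending node) and a pair transition. There is no column-wise attention
because there is no alignment axis: the model sees a single sequence, not a
multiple sequence alignment, and no templates. Triangle updates are
retained; the main architectural statement is the removal of the alignment
axis, and nothing in our design motivated dropping the pair-consistency
machinery.

**Reference frames.** Every residue carries a local frame: translation at
Cα, rotation built by Gram–Schmidt from N, Cα, C (first basis vector along
Cα→C, second orthogonalized from Cα→N, third their cross product). Ligand
atoms have no canonical backbone, so each heavy atom is framed the same
way using itself as the Cα slot and its two bonded neighbours with the
lowest canonical indices as the N and C slots (lowest index → N slot; this
tie-break is our convention — any fixed assignment works, and taking the
order in which the neighbour list is sorted is the deterministic choice).
Atoms with exactly one bond use a dummy anchor placed 1 Å from the atom,
orthogonal to its single bond, along the cross product of the bond vector
with the coordinate axis least aligned with it. The distance and direction
of the dummy are not forced by anything except determinism and
non-collinearity; both are package conventions and marked as such. Atoms
with no bonds are rejected rather than framed: a free ion has no
orientation to define. A config enum `frame_mode = "nearest_atoms"`
(frames from the two spatially closest atoms, the strategy used by some
co-folding models) is recognized but unimplemented.

**Structure module.** Eight iterations (two in the tiny configuration) of
a shared-weight block: gated invariant point attention (IPA) over all
rows, a transition, cross attention in which ligand rows attend over
protein rows, and a per-atom frame update — a quaternion with fixed real
part 1 plus a local-frame translation scaled by 10 Å. Only ligand frames
are updated; protein frames are bitwise constant through the whole forward
pass, which is the rigid-docking contract. IPA computes its geometric
attention terms in the local frames, so its output is invariant under any
global rigid motion, and the coordinate updates expressed in local frames
make the predicted pose equivariant: moving the inputs by a rigid
transform moves the output pose by exactly the same transform (checked to
1e-3 Å in the test suite). Attention outputs pass through a learned
per-channel sigmoid gate before the output projection. The initial ligand
placement is the input conformer centered on the protein's Cα centroid —
blind docking needs a canonical start, and the trunk features cannot leak
the true pose because they contain no protein–ligand geometry. Frames are
composed from the per-block updates rather than rebuilt from coordinates
between blocks; composition is what "updating the rotation" means
operationally, and it keeps the update path differentiable.

## Losses

Training minimizes a docking-specific frame-aligned point error (FAPE).
For a set of alignment frames, predicted points are expressed in the
predicted frames and target points in the target frames; pointwise
distances are clamped at 10 Å, averaged over frames and points, and
divided by a 10 Å scale (both values are the conventional choice for this
loss family; the clamp bounds the influence of far-away placements early
in training). For docking the loss has exactly two useful frame sets, both
evaluated on ligand atoms only (the protein is rigid and given):

* **ligand-frame component** — alignment on the per-atom ligand frames;
  measures internal ligand geometry and is zero for any rigid motion of
  the whole ligand;
* **residue-frame component** — alignment on the (fixed) residue frames;
  measures placement in the pocket. Because the predicted and target
  residue frames coincide, this component reduces to the mean clamped
  per-atom deviation.

The training objective is `1.0 * (mean of the two components at the final
block) + 0.5 * (mean over blocks of the per-block combined FAPE) + 0.5 *
(Kabsch RMSD of the final pose)`. Intermediate per-block FAPE gives every
structure block a direct training signal; the Kabsch term (optimal
proper-rotation superposition, reflections excluded) rewards getting the
ligand's internal structure right even while its placement is still wrong,
and is applied to the final block only. Loss weights are configuration
values; the defaults above were chosen once, a priori, as a balanced
combination. Symmetry correction is **not** applied inside the training
loss — it defines the evaluation metric, and an evaluation-only correction
keeps the loss cheap and smooth.

Optimization is full-graph Adam (learning rate 1e-3 for the tiny
configuration, β = 0.9/0.999). Gradients flow through the whole network
including the frame-update translations; rotation gradients are stopped
where frames are consumed (IPA geometry, frame composition, FAPE alignment
rotations). Stopping rotation gradients is a known stabilization for
frame-based structure modules; here it also keeps the differentiation
engine compact. The practical consequence is that the rotation head is
shaped only indirectly (rotations still act in the forward pass); the
translation path, which determines the coordinates, is trained exactly.

## The differentiation engine

No neural-network framework is available to this package at run time, so
the layers and their gradients are implemented directly in R: a dynamic
tape of closures over plain numeric matrices, with fused operators for
attention, triangle updates, IPA, FAPE and the Kabsch loss (the Kabsch
gradient uses the envelope theorem — the optimal rotation is treated as
fixed at the optimum). Every fused operator's backward pass is verified
against central finite differences in the test suite at 1e-5 relative
tolerance. All arithmetic is double precision and single-threaded, which
is why evaluation-mode forward passes and CLI runs are bitwise
reproducible.

## Affinity head

A two-layer perceptron (concatenated mean-pooled protein and ligand single
rows → 64 hidden units with ReLU → scalar) predicts affinity on the pKd
scale (−log10 of molar affinity). Pooling is the unweighted arithmetic
mean over each entity's rows, applied before any further projection. The
head is trained separately from the docking model with the embeddings
frozen, by full-batch Adam on squared error with per-feature
standardization. The head reads the trunk-stage single representation by
default — the same stage the interpretability pipeline reads — since the
structure module specializes the representation toward geometry; the
`stage = "final"` option uses the post-structure-module representation
instead.

## Evaluation and interpretability

The headline metric is the **success rate**: the percentage of predictions
whose symmetry-corrected ligand heavy-atom RMSD is strictly below 2 Å.
Symmetry correction minimizes the in-place RMSD (no re-superposition —
the pose is evaluated in the docked frame, as docking convention implies)
over all graph automorphisms of the heavy-atom graph that preserve
element, formal charge and bond order. Automorphisms are enumerated with
colored VF2; if a molecule has more than 10,000 of them the naive RMSD is
reported with a warning. The strictness of the 2 Å inequality matters at
the boundary: an RMSD of exactly 2.0 Å is a failure.

The interpretability pipeline mean-pools the ligand rows of the
trunk-stage single representation (64 channels in the shipping
configuration) across each molecule and computes, for every channel, the
Pearson correlation with eight physicochemical descriptors, in a fixed
order: total hydrophobic surface area, molecular weight, H-bond acceptor
count, H-bond donor count, polar surface area, rotatable-bond count,
octanol–water partition coefficient, and aromatic ring count. Two-sided
p-values are reported without multiple-testing correction — with 64
channels the multiplicity is modest and corrected and uncorrected
conclusions coincide for the effect sizes of interest. The best descriptor
per channel maximizes |R|. The surface-area, polar-surface-area and logP
descriptors are approximate additive per-atom schemes implemented in the
package and documented as approximations; weight, donor/acceptor,
rotatable-bond and ring counts are exact graph quantities.

## Synthetic complexes

The fixture generator produces a deterministic complex from a single seed:
residues on a golden-angle spiral over a hemispherical shell (radius
chosen so consecutive Cα sit near 3.8 Å) forming a concave pocket around
the origin; a random small-molecule graph of 5–30 heavy atoms (C/N/O,
optionally seeded with an aromatic six-ring) embedded by a seeded harmonic
conformer generator (covalent-radius bond targets, 1–3 angle terms,
nonbonded repulsion, refined by L-BFGS); and a true pose placed near the
pocket center with a random rotation, re-drawn with shrinking jitter until
no ligand–protein contact is below 2 Å. The affinity label is the fixed
composition function `0.5 × heavy-atom count + ring-atom count / 6`,
chosen to be linearly recoverable from composition-aware embeddings.
Dataset splits are disjoint in ligand topology: complexes whose ligands
share a chemical graph always land in the same split.

What the generator does **not** emulate is important for reading the test
results: there is no real energetics, no side chains, no induced fit, no
crystallographic noise, and the chemical diversity is far below a real
screening library. Green tests therefore demonstrate that the
implementation honors its mathematical contracts (equivariance,
invariance, loss identities, trainability) — they say nothing about
accuracy on experimental structures, which would require external data and
long training runs outside this package's scope.

## Problem sizes and numerical choices

The test suite and the acceptance script run the *tiny* configuration: 2
trunk blocks, 2 structure blocks, width 32, 4 heads, with 15–20-residue
proteins and 5–8-atom ligands for the trained experiments; the overfit
demonstration runs 600 Adam steps on one complex, and the affinity
experiment uses 250 fixtures (200 train / 50 held out). These sizes were
chosen as the smallest at which every contract is exercised end to end on
one CPU core. The shipping configuration (12 + 8 blocks, 64 channels) uses
the same code paths. Orthonormality of constructed rotations is asserted
to 1e-6 and frame equivariance to 1e-5 — comfortable bounds for float64
while remaining meaningful if a float32 backend were substituted.
Collinearity in frame construction is detected at a relative 1e-8 on the
orthogonalized component; degenerate Kabsch inputs (fewer than three
points, or rank < 2 after centering) fall back to the naive RMSD with a
warning; zero-variance channels or descriptors are excluded from
best-descriptor selection rather than given an undefined correlation.

## Known limitations

* Rigid protein, rigid evaluation: no backbone or side-chain flexibility.
* No recycling and no confidence estimate; a pose is returned even when
  the model is unsure.
* The rotation-update head receives no direct gradient (see above).
* Structural validity of poses (bond lengths, clashes) is not enforced;
  an external validity checker can be attached through the
  `validity_hook` slot of `evaluate_poses()`, and no energy minimization
  is applied.
* The approximate descriptors are ranking-quality, not reference-quality.
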