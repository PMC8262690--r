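---
title: "Methods: contact areas, bond networks and charge patterning in foldnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact areas, bond networks and charge patterning in foldnets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldnets)
```

`foldnets` bundles four structural analyses that share one input — a
normalised atom table parsed from a PDB file — and one philosophy:
simple, fully deterministic geometric criteria with every tunable
parameter exposed and logged. This vignette explains each method, the
defaults and why they were chosen, the numerical behaviour of the
section algorithm, and what the synthetic fixtures do and do not
demonstrate.

## Structure normalisation

`read_structure()` delegates record parsing to `bio3d::read.pdb()` and
then applies the package's conventions: only the first MODEL of a
multi-model (NMR) file is kept; within each alternate-location group
only the first-encountered conformer survives; waters are always
removed and other heteroatoms are removed unless requested;
selenomethionine is folded into methionine. Residue identity is the
(chain, author residue number, insertion code, residue name) tuple
taken verbatim from the file, so author numbering — including gaps and
insertions — is preserved in every table. Hydrogens present in the
input are kept and respected by the protonation step.

The van der Waals radii (Å) are C 1.88, N 1.64, O 1.42, S 1.77, H 1.0,
with 1.8 as the fallback for anything else. The carbon value is not
free: two carbons are contact candidates within
$2\,(r_\mathrm{C} + r_\mathrm{w}) = 6.56$ Å with the water probe
$r_\mathrm{w} = 1.4$ Å, which pins $r_\mathrm{C} = 1.88$. All radii and
the probe are overridable through `radius_table()`.

## The surface-section contact algorithm

For each heavy atom $A$ the sphere of radius $r_A + r_\mathrm{w}$ (the
surface on which a water-probe centre glides) is discretised into
$n = 610$ directions of a golden-angle Fibonacci lattice, each
representing an equal share $1/n \approx 0.0016$ of the sphere. For a
direction $u$ the probe position $P = c_A + (r_A + r_\mathrm{w})\,u$ is
tested against every candidate neighbour $B$ (heavy atoms of other
residues within $(r_A + r_\mathrm{w}) + (r_B + r_\mathrm{w})$, found
with a uniform-grid spatial index): the section is claimed when
$|P - c_B| \le r_B + r_\mathrm{w}$, and among several claimants it is
owned by the neighbour whose centre is closest to $c_A$, ties broken by
lower atom serial. Owned sections contribute
$4\pi (r_A + r_\mathrm{w})^2 / n$ to the (residue of $A$, residue of
the owner) cell; the residue matrix is finally symmetrised by summing
the two directed totals.

Two conventions here were genuinely open and are settable in
`contact_params()`:

- **Which sphere carries the area.** The default measures area on the
  solvent-extended sphere, because the sections *are* probe positions
  on that sphere; a switch (`area_sphere = "van-der-waals"`) measures
  on the bare atomic sphere instead.
- **Who competes for sections.** By default every heavy atom of the
  structure occludes (physical occlusion), while only selection pairs
  accumulate area; `occluder_scope = "selection-only"` restricts
  competition to the selection itself.

Numerical behaviour, verified in the tests against a
100 000-direction Monte-Carlo oracle and the analytic spherical-cap
area: per-atom area is conserved exactly (owned plus unowned sections
always sum to the full sphere); directed areas match the oracle to
better than 3 % for separations of 3–6 Å; refinement from 610 to 6100
sections moves fixture areas by under 5 %. Two limits are inherent to
a fixed-direction lattice and are documented rather than hidden: the
two directed areas of an identical atom pair agree only to section
quantisation (about one section, $4\pi r^2/610 \approx 0.2$ Å², not
exactly), and the matrix is exactly invariant under translation but
only quantisation-stable (≈1–2 %) under rotation. Likewise, within
0.1 Å of the candidacy cutoff the true overlap cap shrinks below a few
sections and only its magnitude, not a 3 % relative accuracy, is
meaningful at $n = 610$.

## ILV hydrophobic clusters

Contact areas are computed over all heavy atoms of Ile, Leu and Val
residues (backbone included by default — a sidechain-only flag exists),
with the rest of the structure still occluding. Residue pairs with a
symmetrised area of at least 10 Å² become graph edges; connected
components with at least two members are the clusters, ordered by
total area. Singleton hydrophobic residues are never reported. A
cluster's `total_area` is the sum of its contact areas with each pair
counted once, and two normalisations are reported side by side:
`area_per_contact` (total area over the number of contacting pairs —
the statistic some reports label "area per residue") and
`area_per_residue` (total area over the member count). Both are kept
because the two labels circulate for the same quantity; nothing in the
package guesses which one a reader means.

## Protonation and hydrogen-bond networks

Full pKa estimation and sidechain-flip optimisation are deliberately
out of scope: `protonate()` assigns the standard pH-7 states with
deterministic geometric placement — lysine ammonium (3 H, staggered
sp³), arginine guanidinium (5 H, in-plane sp²), Ser/Thr/Tyr hydroxyls
(1 H), Asn/Gln amides (2 H), tryptophan indole (1 H), bare Asp/Glu
carboxylates — with N–H 1.01 Å and O–H 0.96 Å. Histidine gets the
single neutral tautomer (ND1- or NE2-protonated) that maximises the
count of potential partners within 3.5 Å of the placed hydrogen,
preferring NE2 on ties. Rotatable hydroxyl torsions are scanned in 5°
steps and oriented toward the nearest acceptor within 3.5 Å, else left
staggered. Donors that already carry hydrogens (e.g. from an externally
protonated file) are left untouched, which is the hook for users who
want a pKa-aware pipeline: protonate elsewhere, then analyse here.
This simplification is reproducible and dependency-free, but marginal
bonds can differ from pKa-aware protonation — network counts on real
structures should be read with that caveat.

Bond detection is the Baker–Hubbard criterion with strict cutoffs
ϑ > 120° and d < 2.5 Å between any N/O-attached hydrogen and any N/O
acceptor of a different residue; the default scope restricts both
partners to sidechain atoms. A residue pair linked by several bonds
contributes one edge; networks are the connected components of the
residue graph, computed by union-find and cross-checked in the tests
against `igraph`. Geometry matters more than cutoffs here: the tests
include a fixture demonstrating that a hydroxyl donor *cannot* bond to
an acceptor sitting on the extension of its C–O bond (the best
achievable angle is 90°), which is why the fixture generator can place
partners at an oblique approach angle.

## Salt bridges and charge patterning

Salt bridges are acidic-oxygen/basic-nitrogen pairs strictly below
4 Å, heavy atoms only, no hydrogens needed. Histidine is excluded by
default, consistent with the neutral-His convention used elsewhere in
the package, and can be opted in; chain termini likewise. Networks are
built with the same partition machinery as the hydrogen bonds.

For a sequence with per-position charges (+1 for K/R, −1 for D/E, 0
otherwise, His neutral by default), the composition metrics are
$f^+ , f^-$, FCR $= f^+ + f^-$, NCPR $= f^+ - f^-$ and the asymmetry
$\sigma = (f^+ - f^-)^2/\mathrm{FCR}$. For blob sizes $g \in \{5, 6\}$
the blob asymmetries $\sigma_i$ over all overlapping windows give
$\delta_g = \sum_i (\sigma_i - \sigma)^2 / N_\mathrm{blob}$, and
$\kappa = \tfrac12 (\delta_5/\delta_5^{max} +
\delta_6/\delta_6^{max})$, where $\delta_g^{max}$ is the largest
$\delta_g$ over rearrangements of the same composition. Whenever the
number of distinct arrangements is at most $10^5$ — which covers every
composition up to length 10 and many beyond — $\delta^{max}$ is found
by exhaustive enumeration and is exact. Beyond that a candidate-set
heuristic is used: contiguous charge blocks with the neutral block at
every split position, charges split across both termini in all
proportions, plus the observed arrangement itself. Enumeration shows
the true maximiser can interleave neutrals between charges, so the
heuristic is a documented lower bound on $\delta^{max}$ (hence a mild
upper-bias on κ); including the observed arrangement guarantees
κ ≤ 1 always. Two degenerate cases return the `NA` sentinel: uncharged
sequences, and length-6 sequences, where the single $g = 6$ blob makes
$\delta_6^{max} = 0$.

## Contact maps

The map entry for residues $i, j$ is the minimum distance over their
heavy-atom pairs (hydrogens can be opted in), zero on the diagonal. Raw
distances are reported — no contact threshold is baked in — and the
long-format export carries one row per ordered pair.

## Synthetic fixtures and what the tests show

The fixture generator builds residues from idealised internal
coordinates (standard bond lengths and angles, sidechains extended at
χ = 180° except where branching dictates) and places pairs so that
their closest heavy atoms sit at an exact requested separation, with an
optional oblique approach angle; decorators add altloc duplicates,
a second MODEL and a HETATM water for parser tests. The composite
"mini-protein" used in the end-to-end tests packs a Leu/Ile/Val triad
at van der Waals contact distances (closest-atom separations of
3.3–5.1 Å, chosen as typical core packing), a Lys–Glu pair at 3.5 Å
and a Ser–Asp pair at 2.8 Å. These scaffolds have exactly known
geometry, which is the point: they verify cutoffs, ownership rules,
conservation and graph logic bit-for-bit. They are not decoys — they
have no compact fold, no competing occluders around each contact and
no protonation ambiguity — so passing tests demonstrates correctness
of the algorithms, not agreement with any particular experimental
structure. Analyses of real PDB entries additionally depend on the
protonation model and on the area-sphere convention discussed above.

Problem sizes in the default test run were chosen to keep the whole
suite around a minute on one core: 500 random graphs for the
cluster-component oracle, 50 each for the bond and bridge partitions,
a 3 × 10⁵-direction Monte-Carlo check of the section areas, the full
brute-force δ-max sweep over every charge composition of length ≤ 10,
and 150 random sequences (length 20–80) for the κ bounds and
invariances.

## Determinism and limitations

Every analysis is a pure function of coordinates and parameters: fixed
lattice, deterministic tie-breaks (lower serial; NE2 tautomer), stable
orderings (clusters by area; networks by size then first residue
number), so repeated runs give byte-identical CSVs. Known limitations:
protonation ignores pKa shifts and sidechain flips; the section areas
carry lattice quantisation of roughly one section per atom pair and
are rotation-stable only to that accuracy; κ relies on a heuristic
normaliser for long charge-rich sequences; and mmCIF inputs,
occupancy-weighted altlocs and ligand interactions are out of scope.
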