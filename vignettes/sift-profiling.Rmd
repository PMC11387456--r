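---
title: "Interaction-fingerprint profiling of GPCR ligand collections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-fingerprint profiling of GPCR ligand collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrsift)
```

## The problem this package addresses

Serotonin 5-HT5A receptor ligands are scattered across heterogeneous
sources — ChEMBL exports, patents, screening databases — with activity
reported as Ki, IC50 or EC50 in mixed units, under exact or censored
relations ("Ki below 600 nM"), and with the same molecule drawn in different
SMILES. Downstream structural work asks which binding-site residues
distinguish active from inactive chemotypes: ligand poses in the receptor
are encoded as structural interaction fingerprints (SIFts) — per-residue,
per-interaction-type bit vectors — and compared between groups.

`gpcrsift` implements that pipeline end to end: curation and activity
labeling, chemotype classification, SIFt encoding with GPCRdb generic
residue numbering, group contact frequencies and active/inactive
differentials, agonist-exclusion filtering, Spearman correlation of contact
frequency with activity, ligand RMSF over trajectory frames, and a
descriptive join against mutagenesis data. Because docking and
molecular-dynamics engines are commercial and their outputs are rarely
deposited, the package ships a first-class synthetic-data module that
generates every input the statistics consume, with ground truth attached.

## Curation model

A bioactivity record is (structure, parameter, relation, value, unit,
source). Reading normalizes units to nM, validates rows, and canonicalizes
SMILES with Open Babel; invalid rows are returned as rejects with reasons,
never dropped silently. Records merge into compounds by canonical SMILES.
Per parameter the best determined value is the minimum over `=`-relation
records (configurable to the median); censored `<` / `>` bounds are stored
separately.

Activity labeling uses a 1000 nM threshold: strictly below is active, at or
above is inactive. The boundary value is classified inactive — the
convention has to be fixed somewhere, and a strict "below" reading keeps the
active set conservative. Censored records contribute only unambiguous
evidence: a `< 600 nM` bound is active evidence at a 1000 nM threshold,
a `> 1000 nM` bound is inactive evidence, anything else is undetermined.
Compounds are counted in a Ki/IC50/EC50 Venn cell only when they have at
least one determined (`=`) value for the parameter; bound-only compounds are
deliberately excluded from "determined" summaries.

## Chemotype classification

The named ligand classes of this receptor's literature (acylguanidines,
2-aminoquinolines, benzoxazines, 2-amino-dihydroquinazolines,
N'-benzyl-N-(pyridin-2-yl)guanidines, benzimidazoles, biarylmethylamines,
aminoimidazoles, carbolines, arylpiperazines, lysergic acid derivatives,
isoquinoline amides, 1-(quinolin-8-yl)methanamines, quinazolines,
tryptamines) are encoded as an ordered SMARTS rule library
(`chemotype_rules()`). Each rule is authored against its class scaffold and
the library is unit-tested as an all-pairs identity matrix: every exemplar
matches exactly its own rule. Rule priority resolves overlapping chemistry —
the guanidine-containing classes are the delicate case, and the priorities
encode one defensible reading (most specific substructure first), not an
authoritative membership criterion.

For unlabeled collections a reproducible similarity route stands beside the
rules: Open Babel ECFP4 circular fingerprints (radius 2; the 4096-bit
variant Open Babel emits) with Butina sphere-exclusion clustering on the
Tanimoto matrix. Compounds are processed in descending neighbor count with
ties broken by ascending canonical key, which makes the partition
deterministic and stable (up to cluster relabeling) under input
permutation. The cutoff default of 0.4 is the usual leader-clustering
operating point for ECFP-type fingerprints; it is a parameter, not a claim.

## Geometry and SIFt encoding

Receptors are read from PDB (via bio3d), ligand poses from SDF (via
ChemmineR) or extracted from HETATM records with Open Babel bond
perception — in the latter case the PDB coordinates are authoritative and
only the bond graph is taken from the perception step. GPCRdb generic
numbers ("3x32" = helix 3, position 32) are supplied as a mapping table,
never computed: deriving them needs a curated structural alignment, which
is out of scope. A synthetic-numbered mapping fixture ships with the
package for the positions studied here; its residue numbers are
placeholders consistent with the synthetic receptor fixtures (hence the
`_synthetic` suffix), while its generic labels are the scientifically
meaningful content. The literature occasionally prints corrupted labels
(e.g. an "A5x461"); the fixture includes 5x46 as the presumed intent but
the position is not otherwise used.

Ligand chemical features are perceived from the element/bond graph: donors
are N/O/S bearing hydrogen (explicit, or implicit by standard valence);
acceptors are N/O with an available lone pair, excluding amide nitrogens,
pyrrole-type aromatic NH and positively charged atoms; cations come from
formal charges plus amidinium/guanidinium chargeable-group rules; anions
from formal charges plus carboxylates; hydrophobes are carbons with no
N/O/S neighbor. Aromatic rings are 5- or 6-membered rings that are either
aromatic-flagged or Kekule-alternating and coplanar within 0.1 angstrom.
Residue features come from a hand-built per-amino-acid lookup (side-chain
donors/acceptors/charges/rings/hydrophobes plus backbone N donor and O
acceptor); glycine contributes no side-chain contacts by construction, and
tryptophan contributes its two rings independently.

The SIFt uses the classic nine-type scheme: any contact, backbone contact,
side-chain contact, polar, hydrophobic, hydrogen bond with the protein as
acceptor, hydrogen bond with the protein as donor, aromatic, charged.
Default geometric cutoffs (all configurable and recorded in every
fingerprint) are literature-standard values: heavy-atom contact 4.5 A,
hydrophobic C-C 4.5 A, polar-polar 4.0 A, donor-acceptor 3.5 A with a
120-degree D-H...A angle when explicit hydrogens exist (distance-only
"no-H mode" otherwise, as is typical for docked poses), charged group
centers 4.0 A, ring centroids 5.5 A. Encoding enforces the bit hierarchy:
any typed bit implies the contact bit, and hydrogen-bond or charged bits
imply the polar bit. Detection is deterministic, independent of atom
ordering, and rigid-motion invariant; a cell-list grid accelerates the
residue search and is property-tested to agree event-for-event with the
brute-force all-pairs scan.

## Statistics

Group contact frequency is the fraction of fingerprints with any bit set at
a residue (per-type frequencies by flag). The "frequent positions" view
keeps residues exceeding a strict 60% threshold in at least one group. The
differential analysis ranks residues by |f(active) − f(inactive)|, with
ties broken by panel order; the default report truncates at the top 10 but
the full table is always available. Agonist exclusion removes residues the
reference agonist fingerprint touches, preserving rank order.

Correlation of per-compound contact frequency with activity uses Spearman's
coefficient with midranks on ties, so raw nM and log-nM activities give
identical results (property-tested). Residues with constant frequency have
an undefined coefficient and are reported as such — coercing them to zero
would corrupt the ±1 sets that the analysis exists to find. With three
compounds and distinct ranks the coefficient is exactly one of
{−1, −0.5, 0.5, 1}, which the tests verify against the closed form
1 − 6Σd²/(n(n²−1)) by enumerating all six permutations.

Ligand RMSF is computed per heavy atom around its mean position over frames
superposed on the receptor (Kabsch least-squares fit on alpha-carbons by
default; rotations are proper, det +1). Under isotropic per-coordinate
Gaussian jitter of σ the per-atom RMSF converges to σ√3, which serves as a
closed-form oracle. Pose RMSD is computed in place (no refitting), because
re-docking comparisons live in one receptor frame; symmetry-aware mode
minimizes over element-colored bond-graph automorphisms (enumerated with
igraph, capped at 10,000 with a warning-and-fallback beyond that), so a
benzene ring rotated by 60 degrees scores exactly zero.

The mutagenesis confrontation is deliberately descriptive: a table join
reporting, per flagged residue, whether mutation data exist and which
effect categories (increase, decrease, loss, no_change, mixed) they report,
plus overlap counts. No significance test is attached, because the mutation
records are too heterogeneous (different ligands, substitutions and assays)
for a meaningful null.

## The synthetic-data module

The generators define the study conditions; they are tested code, not
throwaway fixtures, and every generator returns its ground truth.

* **Activity tables**: compounds are drawn from a chemotype mix, each class
  scaffold decorated with a unique alkyl substituent (binary-encoded branch
  pattern, so decorations are injective and pure-carbon — they can never
  create a different chemotype). Activity values are log-normal on the nM
  scale (defaults μ = log 500, σ = 1.5, spanning the nM-to-μM range around
  the 1000 nM threshold), truncated below/above the threshold for the
  active/inactive groups; a 15% duplication fraction exercises
  deduplication.
* **Contact panels**: unplanted residues fire Bernoulli(null_p) in both
  groups, planted residues Bernoulli(null_p + δ) in actives. Defaults
  null_p = 0.3 and δ = 0.4 represent a moderately sticky background with a
  pharmacologically meaningful group difference.
* **Toy pockets**: pseudo-pockets built from ideal-geometry amino-acid
  templates (serine, aspartate, phenylalanine, leucine, glycine spaced 14 A
  apart) with minimal rigid ligands placed to realize exactly one
  interaction archetype. The ionic archetype separates the charged-group
  centers by 3.6 A — inside the 4.0 A salt-bridge cutoff but outside the
  3.5 A hydrogen-bond cutoff — so the planted event list is unambiguous.
  Real residue templates (rather than abstract spheres) mean feature
  perception is exercised genuinely.
* **Trajectories**: the receptor stays fixed; per frame the ligand occupies
  the contact pose with the planted persistence probability or is displaced
  12 A along the pocket exit axis (beyond every cutoff), with Gaussian
  coordinate jitter added. Random streams are split per generator component
  so adding one generator never shifts another's draws.

What the generators do **not** emulate: conformational flexibility,
solvation, force-field energetics, pose uncertainty correlated across
residues, and the class imbalance and assay noise of real collections.
Passing tests therefore demonstrate that the statistics and geometry are
implemented correctly, not that the pipeline's conclusions transfer to any
particular receptor or dataset.

## Statistical behavior of planted-signal recovery

With 50 compounds per group, background 0.3 and one planted δ = 0.4 on a
31-residue panel, the planted residue's estimated differential is
approximately normal with mean 0.4 and standard deviation
√(2·0.21/50) ≈ 0.092, while each of the 30 null residues contributes a
half-normal of the same scale. The probability that the planted residue
outranks all nulls is therefore about 0.97 per replicate (Monte Carlo over
plain binomial draws confirms 0.968), not 1: in a hundred seeded
replicates a handful of misses are expected, and the acceptance suite's
strict 99/100 bound reflects an idealization rather than the statistic's
actual behavior. Larger groups, a larger δ, or a smaller panel push
recovery toward certainty; the defaults were kept at the stated study
conditions rather than adjusted to make the bound pass.

## Numerical and degenerate-input choices

* Bin edges for activity histograms are left-closed, right-open; values
  outside the range are counted in an `n_outside` attribute rather than
  silently dropped or erroring.
* An empty fingerprint list is an error (frequency over n = 0 is
  undefined), as is an empty group in the differential analysis and fewer
  than three compounds in the correlation.
* Tanimoto similarity of all-zero fingerprints is defined as 0 off-diagonal
  and 1 on the diagonal to keep the matrix well-formed.
* PDB coordinates round-trip at the format's 3-decimal precision; tests use
  1e-3 tolerances accordingly.
* Problem sizes in the test and acceptance runs — 200 random complexes for
  the grid/brute equivalence, 100 panel replicates, 2000 trajectory frames
  for the RMSF closed form, 150–500 frames elsewhere — were chosen so each
  statistical check has comfortable power while the whole suite stays quick
  to run on one core.

## Known limitations

* Chemotype rule priorities are one defensible reading of overlapping
  chemistry, not the original curators' intent; collections annotated by
  other criteria will disagree at the margins.
* Generic numbers are input data; a wrong mapping table silently produces
  wrongly-labeled (though internally consistent) profiles. The unmatched
  report is the guard rail.
* Hydrogen-bond detection without explicit hydrogens is distance-only and
  therefore permissive; events carry a "no-H mode" note so downstream
  consumers can tell.
* The residue feature lookup covers the 20 standard amino acids; modified
  residues are skipped with a warning (or an error, by option).
* Aromaticity perception is rule-based (flags or Kekule alternation plus
  planarity); exotic aromatic systems outside those rules are not
  perceived.
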