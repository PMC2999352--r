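---
title: "Methods: template-based interolog mapping and its scoring model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-based interolog mapping and its scoring model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interolog3d)
```

## The model

`interolog3d` infers protein–protein interactions by homology to a solved
heterodimer. The template contributes two things: a *contact topology* (the
inter-chain residue pairs of its interface) and two *chain profiles*. A
candidate pair of same-species sequences is threaded onto that topology via
profile-to-sequence alignments, and scored

$$E_{tot} = E_{vdw} + E_{SF} + E_{sim} + w\,E_{cons}, \qquad w = 3.$$

The working assumptions are those of all template-based interaction
transfer: (i) interfaces diverge more slowly than sequences, so a pair
whose residues still "fit" a homologous interface is likely to interact;
(ii) contact-level fitness is separable into per-pair terms (the energy is
a sum over template contact pairs); (iii) a candidate residue aligned onto
a template position inherits that position's contacts — no remodelling of
the interface geometry is attempted.

### Template construction

Contacts use the standard heavy-atom criterion: two residues on opposite
chains are in contact when any heavy-atom pair lies within 4.5 Å. Each
contact pair carries classes `ss`, `sb`, `bs` according to which atoms meet
(sidechain = any heavy atom outside N, CA, C, O/OXT; CB is sidechain, so
glycine contributes only backbone classes). Contacts whose only
atom pairs are backbone–backbone carry no scoreable class; they are
excluded from the pair list, although their residues still count as contact
residues under the any-heavy-atom rule. A template is retained when both
chains have ≥ 30 residues, both sides contribute ≥ 5 contact residues, and
the interface has more than 25 contact pairs; libraries are deduplicated at
\> 98% identity on both chains (transitive clustering, largest interface
kept, ties by template id).

Special bonds are annotated with geometric rules that have no single
standard definition; we use common structural-biology defaults, exposed in the
configuration: hydrogen bond when any inter-residue N/O pair is ≤ 3.5 Å,
salt bridge when a charged-group nitrogen (Arg NE/NH1/NH2, Lys NZ, His
ND1/NE2) is ≤ 4.0 Å from a charged-group oxygen (Asp OD1/OD2, Glu OE1/OE2),
disulfide when Cys SG–SG ≤ 2.5 Å; precedence disulfide > salt bridge >
hydrogen bond.

### The four matrices

`count_pairs()` tallies contact pairs of a training library into four 20×20
tables (`ss`/`sb` × van der Waals/special). `ss` counts are symmetrized;
`sb` counts are directional with the sidechain residue on rows. Scores are
natural-log odds $S_{ij} = \ln(q_{ij}/e_{ij})$ with $q$ the pseudocounted
observed pair probability and $e_{ij} = p_i p_j$ from the table's own
marginals. Two deliberate choices here, both genuinely open:

* the expected frequencies use **interface marginals** of the same count
  table, not whole-chain composition — the matrix then measures pairing
  preference *given* presence at an interface, which is the quantity the
  energy sums over;
* pseudocount 0.5 per cell for the van der Waals classes; the special
  classes are derived the same way but cells with **zero raw count are
  reset to 0**, encoding that chemically impossible special-bond pairs
  (e.g. a nonpolar partner in a salt bridge) carry no special-bond energy.

The log base is irrelevant to ranking (it rescales all vdW/special terms
jointly) but is fixed to natural log for definiteness.

### Similarity and conservation terms

The similarity and conservation terms admit several reasonable
normalisations; the forms used here were chosen so that the template's
self-alignment is an exact fixed point:

$$E_{sim} = \sum_{(i,j) \in CP} \frac{K_{ii'} + K_{jj'}}{K_{ii} + K_{jj}},
\qquad
E_{cons} = \sum_{(i,j) \in CP} \frac{M_{i'p} + M_{j'p'}}{K_{ii} + K_{jj}},$$

with $K$ = BLOSUM62, $M$ = the chain profiles, and $i', j'$ the candidate
residues aligned at the pair's template positions $p, p'$. Because BLOSUM62
diagonals dominate their rows, each pair contributes exactly 1 to $E_{sim}$
at self-alignment, hence $E_{sim} = CP$ — a property the tests pin down. An
alternative 1/CP-averaged normalisation is available via
`normalize = "mean"`; it changes the scale of $E_{sim}$/$E_{cons}$ but not
within-template ranking.

Gaps contribute 0 to every term they touch, never an error: coverage is
already policed by the CR filter, so a gap at a contact position simply
forfeits that pair's score.

### Profiles and alignment

PSI-BLAST is not executed. Profiles are built in-house from star MSAs:
Henikoff position-based sequence weights, BLOSUM62-conditional pseudocounts
with per-column weight $\alpha_p = (\text{distinct residues}) - 1$ and
$\beta = 10$, scores in half-bit log-odds against the BLOSUM62 background.
With a single sequence, $\alpha = 0$ and the profile collapses to
(approximately) the BLOSUM62 rows of the template residues — a useful
degeneracy: the pipeline works template-only, and sharpening is exactly
what additional homologs buy. PSI-BLAST ASCII PSSMs can be imported
verbatim for fidelity runs.

Alignment is full Smith–Waterman against the profile, affine gaps at the
BLAST 11/1 convention (a gap of length $k$ costs $11 + k$), deterministic
traceback (highest-scoring cell first in row-major order; moves tie-broken
diagonal, then up, then left). Identity is computed **over aligned
columns** — identity denominators vary between tools; aligned-columns is
the more conservative choice for a local aligner, and the strict
\> 30% filter is applied to it. Homolog families are gathered with
Karlin–Altschul E-values ($E = Kmn e^{-\lambda S}$, gapped BLOSUM62
constants $\lambda = 0.267$, $K = 0.041$) at the E ≤ 1e-10 threshold — an
explicit desk-scale approximation to BLASTP.

### The null model and acceptance

For each template, `build_null_model()` scores randomized interfaces:
each sample mutates $\lceil 0.6 \cdot n \rceil$ of the pooled contact
residues (both chains together — per-chain application is the other
reading; pooling was chosen as the stricter null, since it allows samples
that concentrate damage on one side) to residues drawn from the interface
background, excluding the wild type. Each randomized interface is scored
with the **full four-term** $E_{tot}$, and the normal approximation
$(mean, sd)$ defines $Z = (E_{tot} - \mu)/\sigma$. A template whose null
has zero variance (e.g. mutation fraction 0) is a flagged degenerate error,
not a silent NaN. The sampler runs from a single seeded generator, restores
the caller's RNG state, and records its seed.

Acceptance keeps candidates with $Z \ge 3.0$ ranked within the top 25 of
their species; "above 3.0" is implemented inclusively (configurable), and
ranks are dense with deterministic tie-breaks (Z, then $E_{tot}$, then id
pair), so the "top 25" boundary is reproducible under ties. Ranking within
species — rather than globally — is what suppresses out-paralogs: a
eukaryote genome's paralog cloud can emit hundreds of passable candidates,
but only the best-fitting few per species survive.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 4.5 | Å | heavy-atom contact distance |
| `min_chain_len` | 30 | residues | template chain filter |
| `min_contact_res` / `min_cp` | 5 / 25 | count | interface extensiveness (CP strict >) |
| `min_identity` / `min_cr` | 0.30 / 0.5 | fraction | candidate filters, strict > |
| `w` | 3 | — | weight of $E_{cons}$ |
| `z_min` / `rank_max` | 3.0 / 25 | — | acceptance cascade |
| `null_n` / `null_fraction` | 10000 / 0.6 | — | null-model size and mutation load |
| `evalue_max` | 1e-10 | — | homolog-family gathering |
| `gap_open` / `gap_extend` | 11 / 1 | score | alignment penalties |
| `pseudocount` | 0.5 | counts | matrix derivation |
| `hbond_max` / `salt_max` / `ss_max` | 3.5 / 4.0 / 2.5 | Å | special-bond geometry |
| `conservation_threshold` | 0.7 | fraction | interface-evolution annotation |
| `cc_threshold` | 0.4 | RSS | negative-pair labelling |

## What the synthetic generators emulate — and what they do not

`make_toy_dimer()` places residues on a lattice: backbones on parallel axes
20 Å apart, contact sidechains reaching into a band where every planned
cross pair sits at 4.0–4.13 Å, special-bond atom pairs isolated at their
compliant distances. The design guarantees *contact exclusivity* — the
planned contacts are provably the only inter-chain heavy-atom pairs within
the cutoff — without needing a clash model, which is exactly what the
contact-extraction, class-assignment and special-bond rules need to be
tested against a brute-force oracle. It does **not** emulate real protein
geometry: no dihedrals, no rotamers, no packing; atoms within a residue can
be unphysically close. Conclusions about coordinate-noise robustness or
real-interface contact statistics cannot be drawn from it.

`make_homolog_family()` mutates a template chain to controlled identity
(realized within 0.5/L of target) with BLOSUM-conditional substitutions,
holding planned conserved couples fixed; the `adversarial` mode substitutes
each targeted residue by its worst BLOSUM62 partner to build decoys that
pass the identity and coverage filters but fail the Z threshold. Families
therefore have star-like topology around the template with independent
mutations — no phylogenetic correlation structure, no indels except the
explicit interface-deletion decoy. Passing the planted-recovery test shows
the filter cascade and the Z statistic separate planted signal from these
decoy modes; it does not certify performance on real paralog clouds.

`make_alascan_set()` draws ddG values from the model's own per-residue
contributions plus Gaussian noise at $\sigma = 0.25 \times$ the signal's
standard deviation. It is a parameter-recovery surrogate: it verifies the
alanine-scan machinery (mutate-to-Ala rescoring of all four terms) recovers
its own signal under calibrated noise, not that the model predicts
experimental energetics.

## Numerical choices and degenerate inputs

* Altloc resolution: highest occupancy, first-listed on ties. Insertion
  codes collapse into 1-based chain positions in order of appearance.
* Non-standard residues: MSE/SEC/PYL/HYP/SEP/TPO/PTR map to parents; others
  stay in coordinates but are flagged and skipped by every scoring table.
* Unknown candidate letters (X) score a flat −4 in alignment and are
  treated as gaps by the energy terms.
* `E_sim`/`E_cons` denominators are BLOSUM62 diagonal sums, always ≥ 8, so
  no division guards are needed.
* All generators snapshot and restore `.Random.seed`, so fixture creation
  never perturbs user RNG streams.

## Problem sizes

The test-suite and acceptance script run at desk scale, chosen to exercise
every code path with comfortable margins: toy chains of 12–60 residues,
interfaces of 30–600 contact pairs, null models of 200–2000 samples
(10,000 remains the production default), 100 contact-oracle fixtures, 100
planted-recovery pipeline replicates with two species and four candidate
roles each, and 50-residue alanine scans.

## Known limitations

* The $E_{sim}$/$E_{cons}$ forms are reconstructions (see above); absolute
  energies are not comparable to other implementations, though all
  fixed-point and ordering properties are pinned by tests.
* Family gathering approximates BLASTP with profile-alignment E-values;
  borderline family membership can differ from a true BLASTP run.
* Matrices derived from small or single-template libraries are sharp
  (pseudocount-dominated off-pattern); production use should train on a
  nonredundant library of hundreds of dimers.
* No mmCIF input, no biological-assembly reconstruction, no SCOP/Pfam
  domain decomposition: the template is the whole chain-pair interface.
* GO-based RSS scores are consumed as given; the package does not compute
  semantic similarity from the GO graph.
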