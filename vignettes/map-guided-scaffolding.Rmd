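---
title: "Map-guided scaffolding: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-guided scaffolding: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapscaffold)
```

## The model

A mate pair constrains two contigs twice over: the fragment length bounds
their distance, and the read orientations fix their relative orientation.
`mapscaffold` exploits the observation that a *genome map* provides the
same two constraints without any sequencing: two markers at known
chromosomal positions $p_i < p_j$ behave like the two reads of a virtual
fragment of length $p_j - p_i$, read 1 pointing toward increasing map
coordinate and read 2 toward decreasing coordinate (innie/FR geometry).
Composing that convention with each marker's alignment strand on its
contig yields, per contig, a *gap-facing end* (`high` for a `+` placement
of a forward virtual read, `low` for `-`, and vice versa for the reverse
read) and a *tail*, the distance from the marker to that end. Sequence
read pairs from SAM produce links of exactly the same shape, so one link
model serves both data types; they differ only in priority.

For any link, the implied gap between the facing contig ends is

$$\hat g = \mu - t_a - t_b$$

with $\mu$ the implied insert and $t_a, t_b$ the tails. $\hat g < 0$ means
the contigs overlap. Links sharing (canonical contig pair, facing ends,
priority) are bundled; the bundle's gap is the member median — robust to
the occasional chimeric pair — and its weight is the member count.

Scaffolding is greedy over bundles sorted by priority (ascending), weight
(descending), $|\hat g|$ (ascending), then lexicographic pair/end id. The
last key makes the order total, so identical inputs give byte-identical
output. Contig placements live in a union-find forest in which each node
stores an affine map $T(x) = o + s\,x$ ($s = \pm 1$) into its parent's
frame; merging two scaffolds is a single re-parenting, and a bundle whose
contigs already share a root is a *consistency check*: accepted iff the
implied orientation matches exactly and the implied offset agrees within
the bundle's tolerance. Because sequence bundles (priority 1) are consumed
first, a contradicting map bundle always arrives to find the sequence
layout in place and is rejected — the "sequence overrides map" contract is
an emergent property of the processing order, not a special case.

### Assumptions

* Both data types follow FR geometry; RF (outie) jumping libraries would
  need their ends flipped before entering the link model.
* Map positions and contig coordinates are on comparable bp scales; the
  map's positional error is absorbed by the minimum pair separation (see
  below), not modelled per marker.
* Repeats are handled only by *exclusion* (ambiguous markers dropped,
  multi-mapping reads filtered), not by untangling. The original
  hierarchical scaffolder this emulates had repeat heuristics; this
  reimplementation keeps the priority-aware core, which is the part the
  map-integration method actually exercises.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `d_start`, `d_end`, `d_step` | 5 Mb, 10 Mb, 1 Mb | bp | FISH localizes a marker only to within a few Mb; starting at 5 Mb makes marker *order* within a pair trustworthy. The grid yields 6 libraries. |
| library bin | $[d - s/2,\, d + s/2)$ | bp | half-open, disjoint, contiguous; each pair contributes exactly one constraint and the library mean insert is exactly $d$. |
| sequence insert bounds | ±10% of nominal | bp | typical Illumina insert dispersion; user-overridable in `make_seq_library()`. |
| `max_mismatches` | 3 | per mate | the standard permissive short-read mapping cap for a diverged/low-quality draft. |
| `min_weight` | priority 1 → 2, priority 2 → 1 | links | two independent read pairs de-noise stochastic sequence data; a pseudo pair is a curated map fact and stands alone. |
| consistency tolerance | $\max(\text{insert range}, 1000)$ | bp | an internal bundle cannot be held to better accuracy than its library's insert spread; the 1 kb floor keeps tight libraries from rejecting correct sub-kb jitter. |

## Design choices where the ground truth was open

* **Binned, not nested, distance libraries.** A "set distance" per library
  could mean either separations *near* $d$ or separations *up to* $d$.
  Binning was chosen: bins are disjoint, each marker pair yields one
  constraint, and each library has a meaningful mean insert. A nested
  variant would multiply-count close pairs without adding information.
* **Pseudo-link insert = exact separation.** Unlike a sequencing library,
  a map pair's "fragment length" is known exactly, so links store the
  pair's separation rather than the library mean (the exported Bambus
  mates file still carries only the library, whose bin half-width bounds
  the discretisation anyone re-running the legacy binary would see).
* **Ambiguity is conservative.** Best-hit ties across distinct contigs
  drop the marker entirely: a wrong placement creates a false join, and
  false joins are the expensive error in scaffolding.
* **Multi-mapper proxy.** The original pipeline discarded multi-mappers at
  the mapper. Mapper-independent SAM evidence is used instead: MAPQ 0 or
  any secondary/supplementary record marks the read multi-mapping.
* **Scaffold counting.** Singleton contigs count as one-contig scaffolds
  in `n_scaffolds`, in the N50 denominator, and in total span; the
  percentage scaffolded counts only contigs in scaffolds of ≥ 2 members.
* **AGP and negative gaps.** AGP v2.0 cannot encode a negative gap, so
  emitted AGP/FASTA floor gaps at 20 bp while the raw estimates are kept
  in the layout TSV and the in-memory object.

## Numerical and degenerate-input behaviour

Coordinates are 0-based half-open everywhere internally (PSL is native;
SAM's 1-based POS is shifted on entry). Linearisation sorts by offset with
contig id as tie-break and nudges exactly-coincident offsets apart by
1 bp, so offsets are strictly increasing even for heavily overlapping
placements. Empty inputs flow through: an empty map, PSL, or link set
produces empty (but well-typed) outputs and a pipeline of all-singleton
scaffolds; `n50()` of an empty span list is an error, as is a map table
with duplicate marker ids or a SAM without `@SQ` lines.

## What the simulator does and does not emulate

`sim_config()` defaults state a small world with realistic *structure*:
one 10 Mb chromosome; log-normal contigs (mean 30 kb, sd 15 kb — the
fragmentation scale of a 2× draft); uniform 0.5–3.5 kb sequencing gaps;
markers at 5/Mb (the density of a ~14k-marker map on a ~3 Gb genome);
uniform ±2 Mb map noise, the FISH scale that motivates the 5 Mb minimum
interval (separations ≥ 4.5 Mb preserve marker order with certainty at
that noise); and two FR libraries, 4 kb (sd 200) and 8 kb (sd 400),
100 bp reads at 1.5× coverage each. Coverage-based uniform fragment
sampling was chosen over a pairs-per-adjacency mode: with these defaults
the expected number of fragments spanning an adjacency with gap $g$ is
$N (i - g - 2L)/G \approx 13$ for the 4 kb library at the mean 2 kb gap
and $\approx 45$ for the 8 kb library, so every adjacency is recovered
with high probability without placing reads by fiat.

Deliberately **not** emulated: base-level sequencing error (reads carry
`NM:i:0`; the mismatch filter is exercised by constructed SAM records in
the tests), chimeric pairs, repeat-induced mismapping (only a flag that
plants MAPQ-0 pairs), GC or coverage bias, and map errors other than
positional noise (no wrong-chromosome assignments). A green end-to-end
test therefore establishes that the *geometry* — link construction,
bundling, priority resolution, orientation algebra — is right, not that
the filters would clean real noisy data; the per-filter unit tests carry
that weight.

The simulator stores each contig in a random orientation relative to the
chromosome, so orientation recovery is genuinely tested rather than
trivially all-`+`.

## Known limitations

* No repeat untangling: a contig occurring twice in the genome will be
  placed once (or mis-placed), as in any weight-greedy scaffolder.
* Map bundles joining contigs ~5 Mb apart place them with the map's
  positional error (± up to the noise scale); downstream consumers should
  treat long-range map-only gaps as order/orientation constraints, not
  bp-accurate distances.
* The Bambus mates/contig writers are best-effort legacy interop,
  validated by round-trip tests, not against the original binary.
* `summarize_assembly`'s percentage counts contigs, not bases; a
  base-weighted variant would be a one-line change but is not what the
  reference statistics reported.
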