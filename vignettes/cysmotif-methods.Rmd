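---
title: "Methods: scaffold classification and motif-pattern fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaffold classification and motif-pattern fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysmotif)
```

`cysmotif` classifies candidate insect nonreceptor olfactory proteins —
odorant-binding proteins (OBPs), chemosensory proteins (CSPs) and sensory
neuron membrane proteins (SNMPs) — and summarises their de novo sequence
motifs as per-protein "motif patterns" that can be placed on a phylogeny.
This vignette explains the models and procedures, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## Conserved-cysteine scaffolds

Small soluble chemosensory proteins are classified by the number and
spacing of their conserved cysteines, which form the disulfide bridges
that hold the binding pocket together. A scaffold here is an ordered
list of anchors — a required residue preceded by a bounded spacer gap —
matched anywhere in the sequence (PROSITE-style `C-x(23,44)-C-...`).
The shipped profiles are:

* **classic OBP** (six cysteines, three disulfide bridges):
  `C1-X(23-44)-C2-X(3)-C3-X(36-43)-C4-X(8-12)-C5-X(8)-C6`, the spacing
  profile reported for Coleoptera OBPs;
* **minus-C OBP**: the classic profile with C2 and C5 absent. No
  empirical minus-C spacing is established, so the shipped bounds are
  *derived* by deleting C2 and C5 and merging each deleted anchor's
  flanking gaps (summing bounds, plus one for the absorbed anchor
  position): `C1-X(27-48)-C3-X(36-43)-C4-X(17-21)-C6`. The middle gap is
  untouched because neither deleted cysteine borders it. The derived
  profile is overridable through `scaffold_pattern()` or the YAML
  pattern config;
* **plus-C OBP**: a classic match plus at least `extra_cys_min`
  additional cysteines after C6 and a proline after the last of them.
  Descriptions of the subclass range from 4–6 extra cysteines to the
  seven carried by the archetypal bark-beetle plus-C OBP; the default
  minimum is 4 and the synthetic archetype plants 7, both configurable;
* **CSP** (four cysteines, two interhelical bridges):
  `C1-X(6)-C2-X(18)-C3-X(2)-C4`, fixed spacings.

`match_scaffold()` enumerates *all* satisfying anchor tuples by
depth-first search in lexicographic order; classification only needs
existence, but the full enumeration is what the brute-force oracle in
the test suite checks.

Subclass calls use the precedence **plus-C > classic > minus-C**. Every
classic match is also compatible with the four-anchor minus-C profile
(its cysteines are a subset), and plus-C is classic-with-extras, so
without precedence a sequence could receive two labels; the precedence
makes the three subclasses mutually exclusive, matching how family
surveys count them. Patterns are matched anywhere in the sequence — no
signal-peptide trimming — because signal-peptide prediction is outside
this package's scope and not every real OBP has a predicted signal
peptide; anchoring to a presumed mature N-terminus would be unsafe.

## SNMP topology screen

SNMPs (CD36 family) are recognised by topology, not by a cysteine
scaffold: two transmembrane helices near the N- and C-termini with a
large extracellular loop. The screen is a sliding-window Kyte–Doolittle
hydropathy heuristic written for this package (it is not a reimplementation
of any dedicated topology predictor): windows of `tm_window = 19`
residues (the classical membrane-spanning length) whose mean hydropathy
reaches `tm_threshold = 1.6` are merged into candidate segments. A
sequence is called SNMP-like when there are exactly two segments, the
first starting in the N-terminal quarter, the second ending in the
C-terminal quarter, separated by a loop of at least `min_loop = 100`
residues. SNMP1-vs-SNMP2 subfamily assignment is deliberately not
attempted: that split is resolved phylogenetically, not by a printed
sequence rule.

## ORF extraction

`find_orfs()` is a six-frame stop-to-stop extractor with a minimum
translated length, default `min_len = 100` residues — the conventional
minimum-ORF setting for coding-region prediction in de novo
transcriptomes. Whether such minima are quoted in residues or
nucleotides varies between tools, so `run_config()` accepts both units
(`orf_min_unit`). Stop-to-stop (rather than ATG-anchored) extraction is
the default because assembled transcripts are frequently fragments;
`require_start = TRUE` trims each ORF to its first ATG and re-filters.
ORFs running off the sequence end are reported with `has_stop = FALSE`
rather than dropped, for the same reason. Ties in the longest-ORF rule
are broken by frame (+1 … −3) then position, making `longest_orf()`
deterministic. Codons containing `N` translate to `X`.

## Motif discovery

The de novo motif model is the standard ZOOPS (zero-or-one occurrence
per sequence) position-probability-matrix model, fitted by
expectation-maximization. ZOOPS matches the downstream fingerprint
semantics, where a motif is simply present or absent in a protein.
Discovery is greedy with masking:

1. For each width on the grid (`minw`–`maxw`, step `width_step`),
   candidate seeds are distinct window subsequences, preferring repeated
   words (a repeated exact word is the strongest cheap evidence of a
   shared motif), capped at `n_starts = 200`; the top `n_score = 30` by
   the log-likelihood ratio (LLR) of their initial model are scored, and
   full EM runs from the top `n_refine = 3`. Running EM from every
   candidate would cost an order of magnitude more compute for no
   observed change in which motif wins on either planted or null data.
2. Widths are compared by **LLR per free parameter**, `LLR / (19 w)` — a
   wider matrix must buy its extra 19 parameters per column with extra
   likelihood.
3. The winning model is tested against an empirical null: residues are
   shuffled within each sequence (composition-preserving), the same
   width-search is run on each shuffled set, and
   `p = (1 + #{null >= observed}) / (1 + n_shuffles)`.
4. Accepted motifs have their occurrences masked with `X` (windows
   containing `X` are excluded from all later site sets), and discovery
   repeats until `nmotifs` motifs or a non-significant round.

EM numerical choices: pseudocount `0.01 * background` per matrix cell;
convergence at relative LLR improvement below `1e-6`; at most 200
iterations inside discovery (500 in the exported `em_zoops()`), with
non-convergence flagged on the model rather than raised as an error.
The E-step is exact (log-sum-exp with a global shift), so widths up to
95 residues are safe.

Two consequences of the empirical null deserve emphasis. First, its
smallest attainable p-value is `1/(1 + n_shuffles)`; a threshold of
`1e-4` with the default 99 shuffles is below that floor, so
`discover_motifs()` accepts a motif when `p <= max(p_threshold, floor)`
— a motif that no shuffled dataset can match is the strongest statement
the test can make, and the per-candidate false-acceptance probability
remains `1/(1 + n_shuffles)`. Second, the null sample is drawn once per
run on the input set and reused across rounds; later rounds search
masked, signal-depleted data against a null built from the full data,
which if anything makes the test conservative for them. The exported
`motif_significance()` instead draws fresh shuffles for one given model
and replicates that model's search policy exactly, which is what the
calibration tests exercise.

The analytic significance machinery of mature motif-discovery suites
(E-values from a per-column statistical theory) is intentionally not
reproduced; the shuffle null is transparent, testable, and adequate for
the prevalence questions this package answers. Scanning uses summed
log-odds in bits with a default threshold of 60% of the motif's maximum
attainable score and greedy non-overlapping selection.

## Fingerprints and motif patterns

A fingerprint is the ordered (by start position) list of motifs present
in a protein; sequences with identical fingerprints form one *motif
pattern*, numbered by descending group size with a family suffix
(`1c`, `2c`, …). Motif identity is the discovery rank within a run;
across runs, motifs are compared by consensus string, since rank is an
artifact of each run. If threshold lowering ever yields two occurrences
of one motif in a sequence, only the best-scoring one enters the
fingerprint, preserving ZOOPS semantics. Pattern groups are stable
under input reordering except for rank ties, which are broken by first
appearance.

## Tree annotation

`annotate_leaves()` joins pattern membership onto the leaves of any
user-supplied newick tree (consensus trees from Bayesian samplers,
exported to newick, are the expected source; tree inference itself is
out of scope). Output is an iTOL `DATASET_COLORSTRIP` text block with a
fixed palette indexed by pattern rank (wrapping with a warning beyond
16 patterns, keeping outputs diffable). `clade_homogeneity()` reports,
for every internal node with at least two annotated leaves, the
majority pattern and its fraction — the root value equals the global
majority fraction, and values near 1 below the root indicate that motif
patterns track clades. Polytomies are accepted as-is.

## The synthetic-data generator

Real chemosensory transcriptomes and their curated ortholog sets are
not redistributable at package scale, so every stage is exercised
against generated families with recorded ground truth
(`generate_family_set()`):

* scaffolds are planted with spacers drawn uniformly within each gap's
  printed bounds, at a uniform random offset;
* background residues are uniform over the 20 amino acids with
  **cysteine weight 0 by default**: the subclasses are defined by
  conserved cysteine counts, and stray cysteines would make truth
  labels ambiguous. This is configurable (`synthetic_background()`);
* for SNMPs the background additionally suppresses I/L/V/F outside the
  two planted terminal poly-hydrophobic stretches, emulating a
  hydrophilic ectodomain loop — the same reasoning as cysteine
  suppression, applied to the hydropathy screen's signal;
* planted motifs are exact consensus copies (information content ≈ 4.3
  bits per column) written over background at non-anchor positions, in
  rank order left to right, with backtracking placement so a feasible
  arrangement is always found or an explicit infeasibility error is
  raised before emission;
* motif carriers are deterministic: exactly `round(prevalence * n)`
  records per motif, chosen by a seeded shuffle — so a planted 46/51
  yields exactly 90.2%, not a Bernoulli approximation;
* a `background` family (no scaffold, no membrane plan) provides a
  neutral substrate for motif-recovery properties where scaffold
  cysteines would themselves be discovered as (real) motifs;
* transcripts are reverse-translated with uniform codon choice, the
  leading methionine encoded by the start ATG, and UTRs carrying stop
  codons in all three frames (including an 11-nt three-phase stop
  cassette at each ORF boundary) so no spurious ORF can outgrow the
  planted one.

What the generator does **not** emulate: real amino-acid composition
(beyond the configurable background), signal peptides, indel variation
around motifs, degenerate motif instances, codon-usage bias, or
sequencing/assembly error. Passing recovery tests on these families
therefore shows the machinery is correct under its own model — exact
prevalence recovery, identity confusion matrices — not that field data
will be as clean; on real proteins, scaffold spacing outside the
printed bounds or motif instances with substitutions will reduce
sensitivity accordingly.

Problem sizes used in the shipped checks — 30 classic / 51 minus-C /
20 CSP / 12 SNMP sequences, widths 6–10 (OBP/CSP) and 45–95 step 5
(SNMP), 99 (or 49 for the SNMP set) null shuffles — were chosen once as
desk-scale counterparts of the family-survey set sizes and are stated
here as the package's reference conditions. For the SNMP width range,
the two quoted conventions (minimum 40 vs 45) are both accepted by
`run_config()`; 45 is the default.

## Known limitations

* The minus-C gap bounds are derived, not empirical; real minus-C OBPs
  whose C1–C3 spacing falls outside the merged bounds will be missed
  (the profile is user-overridable).
* The hydropathy screen is a heuristic: strongly hydrophobic globular
  stretches can mimic a transmembrane segment, and marginal helices
  below the 1.6 threshold are missed.
* The empirical motif p-value is bounded below by the shuffle count;
  reported floor values mean "stronger than every shuffle", not a
  calibrated `1e-6`.
* One conflicting pair of printed subclass counts for the motivating
  family survey (15 vs 16 classic OBPs of 27) is noted here for
  completeness; the classifier takes no side — it reports what the
  profiles match.
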