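---
title: "RRHP profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RRHP profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrhp)
```

# The assay in computational terms

Reduced representation 5-hydroxymethylcytosine profiling (RRHP) is a
positive-display sequencing assay. Genomic DNA is digested with MspI,
which cuts C^CGG irrespective of CpG methylation state. Fragments are
ligated to modified Illumina adapters so that the CCGG site is
reconstituted at the P5 junction but destroyed at the P7 junction. After
glucosylation of 5hmC by beta-glucosyltransferase (beta-GT), a second
MspI digestion removes the P5 adapter from every fragment whose junction
cytosine is unmodified C or 5mC; only glucosyl-5hmC blocks the enzyme.
Surviving fragments amplify and sequence, so every read that begins with
`CCGG` and starts exactly at an MspI junction reports one 5hmC event, on
a known strand. There is no subtractive library and no bisulfite
conversion: the read count at a site is itself the display signal.

This package implements everything downstream of (and, in silico,
upstream of) the sequencer: the digestion model that defines which sites
are interrogable, a molecule-level simulator of the library chemistry
that provides ground truth, the junction profiler that turns reads into
strand-specific per-site counts, replicate QC statistics, false-call
calibration against bisulfite (RRBS) data, and the locus-specific
glucMS-qPCR quantitation formula.

# In silico digestion and detectable sites

Coordinates are 0-based and half-open throughout; files on disk use BED
conventions. A site is keyed by the position of the first C of its CCGG.
The top-strand cut of a site at `pos` is placed at `pos + 1` (between C
and CGG), and a fragment's length is the distance between consecutive
top-strand cuts. The 2-nt 5'-CG overhang is deliberately not
double-counted: this convention gives every contig an exact tiling by
its fragments (first fragment starts at 0, last ends at the contig
length, fragment count = site count + 1), which is the invariant the
test suite leans on. Overlapping CCGG occurrences each produce a cut; an
N anywhere in the 4-mer disables the site. The recognition motif is a
parameter (`CCGG` by default), so isoschizomer or alternative-enzyme
catalogs can be built with the same machinery, but ambiguity codes and
circular contigs are out of scope.

Size selection operates in insert space. The laboratory protocol cuts
adapter-ligated material at 110-500 bp from a gel; with roughly 70 bp of
total adapter this maps to a 40-430 bp insert window, which is the
package default. After selection, a site is *forward-detectable* when a
retained fragment begins at its cut (a read there interrogates the
forward-strand CpG cytosine at `pos + 1`) and *reverse-detectable* when
a retained fragment ends at its cut (interrogating `pos + 2`). Contig
ends carry no adapter junction, so fragments touching a boundary
contribute no detectability from that side. Widening the size window can
only add detectable sites, never remove them — a property test checks
this, alongside a brute-force oracle that re-derives detectability by
scanning every motif occurrence against every retained fragment.

Digestion summaries report *site* counts. There is no well-defined
notion of a "read" in a purely in silico digestion (one per junction?
per strand? per retained fragment?), so the package does not invent
one; simulated read counts come only from the library simulator, where
a read is a concrete molecule copy.

# The library simulator

`simulate_library()` follows one molecule at a time through the
chemistry, because every downstream contract (exact round-trips,
survival-set nesting, calibration expectations) is most naturally stated
at molecule level.

For each retained fragment, `n_molecules_per_fragment` molecules are
processed in five stages:

1. **Adapterization.** With probability `hetero_adapter_prob` (default
   0.5 — two adapter species at equal molarity; the protocol does not
   pin this number, so it is exposed) the molecule is hetero-adapterized
   P5/P7, and the P5 end falls on either fragment end with equal
   probability. Homo-adapterized molecules form the inhibitory hairpin
   and emit nothing; so does a P5 end at a contig boundary, where no
   junction exists.
2. **Junction state.** The cytosine state at the P5-junction CpG on the
   molecule's read strand is drawn once from the profile:
   5hmC / 5mC / unmodified with probabilities `(hmc, mc, 1 - hmc - mc)`.
   Internal CpGs are irrelevant to survival — only the junction is
   re-cut — and are emitted as unmodified sequence.
3. **Glucosylation.** If `beta_gt` is on, a junction 5hmC becomes
   glucosyl-5hmC. Turning it off is the assay's negative control.
4. **Second digestion.** MspI cleaves (molecule lost) unless the
   junction carries glucosyl-5hmC; HpaII cleaves unless it carries 5mC,
   5hmC or glucosyl-5hmC. A cleavable molecule escapes with probability
   `digestion_failure_rate`, the incomplete-digestion background
   (default 0 for clean property tests; around `1e-3` is a realistic
   residue, and the calibration machinery is designed to measure exactly
   this kind of leakage).
5. **Amplification and sequencing.** Each survivor yields
   `1 + Geometric(1/pcr_duplicate_mean)` reads (mean
   `pcr_duplicate_mean`, exactly one read when the mean is 1); the
   geometric family was chosen for its monotone tail and single
   parameter, and it is documented here because the exact family is a
   modelling choice, not chemistry. Each read is the reconstituted CCGG
   followed by the fragment sequence from the junction, on the
   molecule's strand, truncated to `read_length`, with independent
   per-base substitution errors at `seq_error_rate`. Base qualities are
   a constant placeholder; quality modelling is out of scope.

Read names encode `contig|site|strand|molecule|copy`, and the returned
truth table records, per (site, strand): the true fractions, molecules
drawn, molecules surviving and reads emitted. That makes every
downstream stage testable without external data or an external aligner.

Two reproducibility guarantees matter. First, the whole simulation is a
pure function of `(genome, profile, config)` — identical inputs give
byte-identical FASTQ and truth tables. Second, all molecule-level
randomness is drawn up front in a fixed order, so two runs sharing a
seed but differing in `second_enzyme` or `beta_gt` process identical
molecule draws. Because glucosyl-5hmC resists both enzymes while 5mC and
5hmC resist only HpaII, the survivors of MspI-with-glucosylation are
then a strict subset of the HpaII survivors, molecule by molecule — the
simulator-level restatement of the observation that hydroxymethylated
junctions form a subset of the methylated ones.

The profile generator `make_profile()` draws per-(site, strand) 5hmC
fractions from a zero-inflated Beta: with probability
`zero_hmc_fraction` (default 0.3) a pair has exactly no 5hmC, otherwise
Beta(2, 5) (mean ~0.29); 5mC fractions are Beta(5, 2) (mean ~0.71,
typical of somatic CpG methylation), clipped so the two sum to at most
1. The zero inflation plus the low-mean Beta reproduces the
heavily-skewed coverage distributions real brain libraries show, where
roughly half the detected sites sit below a handful of tagged reads.

# From reads to counts

The profiler applies two exact rules. A read is *tagged* when its first
four bases are exactly `CCGG` (case-insensitive); an error inside the
tag drops the read, which is conservative and mirrors the fact that
real libraries report tagged percentages below 100. A tagged `+` read is
assigned to site `s` when its leftmost position equals `s` (the tag
spans the genomic CCGG); a `-` read when its rightmost position equals
`s + 3`; assignment also requires the corresponding detectability flag.
Tagged reads at no cataloged junction are reported in a separate
off-junction tally, never as sites. PCR duplicates are intentionally
counted — in a positive display the read count is the signal, so
duplicate marking would destroy the measurement.

External SAM/BAM alignments are accepted (minus-strand sequences are
reverse-complemented back to sequencing orientation before the tag
check, and records with fewer than the mandatory fields are skipped
with a warning). For self-contained work the built-in junction matcher
indexes the expected read sequence of every junction of a fragment
catalog and compares each read base-by-base, truncated to the read
length. Among junctions within `max_mismatches`, a unique best match
aligns the read; ties — including genuinely identical fragment starts —
leave it unmapped. This is an exact-search substitute for a general
aligner, adequate because simulated reads are ungapped by construction;
it makes no attempt at indels or clipping. Multi-mapped (ambiguous)
reads are excluded by default on the argument that a junction count
should never be invented; there is no rescue heuristic.

# Replicate statistics and comparisons

The replicate correlation is Pearson's r between per-site total counts
over a configurable site universe: the union of detected sites with
absent sites counted 0 (the default, since the scatter being emulated
plots counts, including sites seen in only one library) or the
intersection; a `binary` flag switches to presence/absence. With
`min_count > 0`, sites below the cutoff in both libraries are excluded.
Overlap reports the Venn split of detected site sets at `total >= 1`
(no evidence suggested a higher detection threshold, and 1 is the
natural positive-display reading), plus quartile summaries of counts at
shared versus unique sites. Strand asymmetry uses
`log2((fwd + 1) / (rev + 1))` for the reported ratio — the pseudocount
only stabilises the log — while the two-fold flag is computed on raw
counts, with the convention that a zero strand flags when the other
strand reaches the fold threshold. Paired tumor/normal comparison ranks
sites by absolute count difference with coordinate tie-breaks; no
p-values are attached, because inventing a significance model for a
quantity whose normalisation is explicitly unresolved (equal-volume
multiplexing keeps relative abundance, nothing more) would be
misleading.

# False-call calibration and glucMS-qPCR

RRBS shares MspI fragmentation with RRHP, so a CpG that RRBS shows as
deeply covered (strictly more than `min_coverage` reads, default 50)
and completely unmethylated should produce no RRHP reads. Qualifying
CpGs are mapped to site keys by testing membership in the CCGG 4-mer on
either strand (forward CpG cytosine at `pos + 1`, reverse at
`pos + 2`), and only cataloged detectable sites count. The error table
reports, for each read cutoff i, the fraction `E_i = N_i / N` of
qualifying sites showing **at least** i RRHP reads. The at-least
reading is deliberate and worth stating prominently: it is what makes
`E_i` monotone non-increasing in i and is the only reading under which
a "minimal read count for an error rate below 5%" is well defined;
`min_cutoff()` computes that minimum from the table rather than
hard-coding any published row. Under the simulator with no 5hmC and
failure rate f, the per-site false-call probability has a closed
binomial form, and the calibration tests require the measured curve to
match it within three Monte-Carlo standard deviations.

The glucMS-qPCR estimator is
`5hmC% = 100 * (Ct_digested-minus - Ct_digested-plus) / (Ct_digested-minus - Ct_intact)`,
where minus/plus refer to mock/real glucosylation before digestion.
It is invariant under a common Ct shift, hits 100% when glucosylation
fully protects the locus and 0% when it does nothing. Ct noise can push
the raw value outside [0, 100]; both the raw and the clamped value are
returned, and a digested-mock Ct below the intact Ct (chemically
implausible) warns rather than errors, since a single noisy triplicate
should not kill a batch.

# Problem sizes and numerical choices

The package's study system — used by the acceptance script and the
end-to-end tests — is a single 100 kb synthetic contig carrying ~300
CCGG sites at GC content 0.4, digested and selected to 40-430 bp. That
scale gives a few hundred detectable (site, strand) pairs: large enough
for distributional checks (binomial expectations within three standard
deviations; parameter-recovery correlations), small enough that the
exhaustive junction matcher is exact and fast. Property tests run the
digestion oracle over a thousand random genomes up to 10 kb. Simulation
depths are chosen per question: 40 molecules/fragment for round-trip
exactness, 400 (= 100 junction-eligible molecules per site and strand)
for parameter recovery, and 1,000 with failure rate `1e-3` for the
calibration curve.

Degenerate inputs are defined, not crashed on: zero reads produce an
all-zero summary; an empty size-selected catalog yields an empty site
catalog and an empty BED; correlation over fewer than two sites or with
zero variance returns `NA` with a warning; a calibration with no
qualifying sites is an error because no rate can be estimated.

# What the simulator does and does not establish

The simulator emulates the chemistry's logic faithfully — protection,
digestion, adapter orientation, background leakage, duplication,
substitution errors — so green tests establish that the *pipeline*
measures what the chemistry displays. They do not establish performance
on real libraries, whose dominant noise modes are precisely the ones
excluded here: mapping ambiguity in a repetitive genome, indels,
quality-dependent errors, fragment-specific amplification efficiency,
and incomplete adapter trimming.

One concrete consequence was found while validating the replicate QC.
In real libraries, the replicate Pearson correlation tends to rise as
low-count sites are excluded. Under this generative model it does not:
across many depth and noise settings the mean correlation over replicate
pairs stays flat or falls slightly as `min_count` grows, for both site
universes. The mechanism is visible in the scatter geometry — with
union-with-zeros, the cloud of noise sites near the origin acts as
correlated leverage that inflates r, so removing it cannot raise the
coefficient. The rising trend in real data therefore likely reflects
noise the simulator deliberately omits (mapping artifacts and
amplification jackpots that scatter low counts off the diagonal), and
the package tests the behaviour its own model actually implies: high
replicate correlation at realistic depth, the exact `min_count`
exclusion contract, and overlap stability for confidently detected
sites. Analyses of real libraries should treat the cutoff-correlation
trend as an empirical QC readout, not a model prediction.

Other knowingly unmodelled territory: paired-end reads, adapter
read-through, gel mobility, molarity-to-molecule conversion, and any
between-sample normalisation beyond documenting that comparative
samples must be sequenced at matched depth.
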