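---
title: "Consensus-seeded transcript assembly: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-seeded transcript assembly: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopath)
```

## The assembly problem

Genome-guided transcriptome assembly reconstructs the set of expressed
isoforms of each gene from spliced short-read alignments. Because isoforms
of one gene share exons and differ widely in abundance, the per-locus
problem — finding a path cover of a splicing graph in which every path is a
real transcript — is underdetermined from read data alone. No single
upstream assembler wins on all data sets, so `isopath` treats the
transcript sets of several assemblers as an additional evidence channel:
sub-chains on which two or more independent assemblers agree are taken as
trustworthy fragments of real isoforms and used to seed and steer the path
search, alongside sub-paths phased directly by paired-end reads.

## Splicing graphs

Alignments are filtered (primary, mapped, MAPQ at least `min_mapq`,
default 1), converted to block chains (CIGAR `N` splits blocks; `D`
consumes reference within a block; `I`/`S`/`H` consume none), mated by
query name, and clustered into loci by single linkage on the pairs'
intron-spanning hulls with a bridging gap of `max_gap` (default 50 bp —
chosen as a conservative separation for compact genomes and configurable;
read data rarely support finer resolution of adjacent genes). Strand comes
from the aligner's `XS` tag, else from GT-AG/CT-AC intron motifs when a
FASTA is supplied, else stays unknown; unknown-strand pairs join the
overlapping stranded locus rather than founding a duplicate one.

Per locus, every block gap is a candidate intron and must be supported by
at least `min_junction_reads` fragments (default 1: the toy scale carries
no mapping noise; raise it on real data). The locus is cut at every donor
and acceptor; maximal covered runs between cuts become exon segments
(nodes). Junction edges join donor-matching to acceptor-matching segments
with weight = supporting fragments; adjacency edges join abutting segments
crossed by at least one read, so alternative transcript ends and retained
introns are representable as paths. Coordinate order makes every graph a
DAG.

## Paired subpaths

A read pair whose mates span node paths $P_1$ (length $p$) and $P_2$
(length $q$) is phased into a single paired subpath when **exactly one**
connecting path (with $s$ interior nodes) exists between them and
$p + s + q \ge 3$. The count applies to the mate paths themselves, so two
mates sharing a node merge into a valid 2-node subpath, while two
singleton mates joined by a bare edge ($p+s+q = 2$) are rejected.
Connector enumeration is capped (64 paths, depth 32); hitting the cap is
treated as "more than one connector", which is all the uniqueness test
needs. We require global uniqueness of the connector before applying the
length rule — the stricter of the two possible readings.

Identical subpaths aggregate; their count is the subpath's **coverage**.
Every length-$k$ window of every paired subpath is a paired $k$-subpath
whose coverage is the sum over containing subpaths; windows with coverage
at least 2 are **reliable**. Windows are produced from $k = 2$ upward:
the canonical decomposition starts at 3, but the extension rule consults
2-subpath witnesses, so the same window/threshold scheme is applied one
length earlier (a documented divergence; `min_k` is configurable).

## Colored graphs and assembly subpaths

The pooled transcripts of all upstream assemblers are clustered by exonic
overlap per chromosome and strand. In each cluster a colored graph holds
one node per distinct exon interval (exact identity; `boundary_slack > 0`
optionally snaps boundaries within that distance to the majority
coordinate first, because different assemblers can disagree slightly on
exon ends) and one path per transcript, labeled by its assembler. Every
window of every path is an assembly subpath whose **depth** is the number
of *distinct* assemblers containing it — two transcripts of one assembler
count once — and depth at least 2 makes it reliable. Terminal exons
participate in node identity exactly; the slack flag is the only
relaxation.

## Mapping assembly subpaths onto splicing graphs

A hash index maps each junction key (chromosome, donor, acceptor) to its
splicing graph and edge. An assembly subpath maps when all of its
junctions hit the index, resolve to one graph, and the induced edge
sequence closes into a connected path (adjacency edges fill in where one
colored exon spans several read-defined segments; terminal ends extend
only through segments contained in the exon). Subpaths whose junctions
were never seen in the reads are dropped and counted — rescuing them would
mean editing the read-defined graph, which we deliberately avoid.
Mono-exon transcripts carry no junction and instead match isolated
segments by 50% reciprocal overlap. Read- and assembly-derived sets are
merged by node sequence; duplicates keep one copy tagged `merged` with
both scores retained. Coverage (read pairs) and depth (assemblers) are
incommensurable, so seeding never compares them directly: ordering is by
length, then assembly-derived before read-derived (they aggregate more
evidence), then raw score, then lexicographic node order.

## The weighted line graph and the connection program

Each splicing graph $G$ is transformed into its line graph $L(G)$: one
node per edge of $G$, weighted by that edge's coverage, and one edge per
incident pair. At every branching node of $G$ a small quadratic program
distributes flow between in-edges $i$ (weights $w_i$) and out-edges $j$:

$$\min_{f \ge 0}\; \sum_i \Big(\sum_j f_{ij} - w_i\Big)^2 +
  \sum_j \Big(\sum_i f_{ij} - w_j\Big)^2,$$

with a floor $f_{ij} \ge \epsilon\,\min(w_i, w_j)$ (default
$\epsilon = 0.05$) on every pair witnessed by a reliable 3-subpath through
the node. This concrete program is this package's own formulation of the
connection-weighting idea — its inputs (coverage differences and reliable
subpaths) and its output contract (a near-0/1 connection indicator) are
fixed, and the module isolates it behind one interface so an alternative
program can replace it. It is solved by non-negative least squares after
shifting out the floors; a ridge block of $10^{-4}$ on the design matrix
keeps the active-set solver away from the rank deficiency inherent in
row-sum/column-sum systems, and flows below $10^{-9}$ are treated as zero.
All-zero weights fall back to uniform flow over witnessed pairs.

Binarization sets an L-edge to 1 when its flow reaches `theta` (default
0.1) of the node's maximum flow, **or** it carries the largest non-zero
flow leaving its in-edge (every expressed edge continues through its best
pairing, which guarantees at least one weight-1 continuation per L-node
unless its flows vanish), **or** the pair is witnessed by any reliable
subpath. Non-branching incidences are always 1.

## Seeded path extension

Reliable $n$-subpaths project to unique $(n-1)$-paths of $L(G)$. Assembly
then loops:

1. **Seed**: the longest uncovered reliable subpath (ties: assembly before
   read, higher score, lexicographic); once all are covered, the unused
   L-node with the largest current weight — the natural choice where the
   rule leaves the node unspecified, and configurable in principle.
2. **Extend** right (and mirror left): candidates are weight-1 successors
   (all successors when none is — truncating instead would strand
   downstream nodes and break the cover guarantee; `strict_binary`
   restores the stricter behavior). Among several candidates, those
   supported by a reliable 2-subpath (path's last node, candidate)
   survive, then 3-subpath support on the current suffix, and so on while
   longer witnesses exist; then the largest current node weight; then the
   smallest node index, so output is bit-reproducible.
3. **Commit**: $c_{\min}$, the minimum current node weight along the path,
   is recorded as the path's abundance proxy and subtracted from every
   on-path node.

The loop ends when every reliable subpath is contained in a predicted path
and every L-node is used; each iteration covers at least one new subpath
or node, so termination is guaranteed (a cap of $10\,|L|$ iterations
guards against defects). Committed paths may traverse weight-0 nodes —
the cover condition requires it. Isolated covered segments, including
junction-free loci, are emitted as mono-exon transcripts with mean base
coverage as their proxy.

Finally, paths with $c_{\min}$ below `min_cov` (default 1.5) are dropped.
This post-assembly expression filter is the recall/precision trade-off
knob: because $c_{\min}$ subtraction zeroes shared junctions, a later true
isoform can legitimately carry $c_{\min} = 0$, and raising `min_cov`
trades such paths for precision. For this reason the package's
exact-recovery evaluation (in the acceptance tests and
`scripts/acceptance.R`) reports structural recovery with the filter
disabled (`min_cov = 0`) alongside the default operating point: the
question asked there is whether the path search finds exactly the true
intron chains, not where the abundance filter sits.

## The synthetic data generator

`fixture_spec()` fixes the study conditions: three multi-isoform genes
(an exon-skipping pair, a three-isoform gene with a skipped exon and an
alternative last exon, and a minus-strand mutually-exclusive-exon pair),
150 bp paired reads with fragment length $\mathcal N(300, 25^2)$ truncated
to the isoform, per-isoform fragment counts of 35–60, and three concordant
mock assemblers. Reads are placed uniformly along isoforms so CIGARs spell
exactly the true introns; assembler profiles can miss true isoforms
(`tp_rate`), add recombined spurious chains (`false_rate`), or jitter
internal boundaries (`jitter`). Each generator call draws from its own
stream keyed off `seed` (alignments: `seed`; GTFs: `seed + 1000003`) so
either artifact is reproducible regardless of call order.

The generator emulates the features the method consumes — shared exons,
uneven abundances, paired-end phasing, inter-assembler agreement and
disagreement — and deliberately omits base-level sequencing error,
mapping ambiguity, GC and positional bias, and genuinely novel junctions
absent from the reads. Passing tests therefore demonstrate the
correctness of the graph construction, the reliability calculus and the
path search under clean evidence; they do not measure robustness to
alignment noise at scale.

## Problem sizes and numerical choices

Property suites run on 100–200 random DAG fixtures of 4–12 nodes with
random reliable sets, sizes at which exhaustive oracles (path enumeration,
window tallies, rule replays) stay exact and the whole suite completes in
well under a minute per property. End-to-end runs use the default
three-gene conditions (650 fragments). Tolerances: flow-sanity checks at
$10^{-6}$, zero flow at $10^{-9}$, weight monotonicity at $10^{-9}$.
Ties everywhere break lexicographically by node index.

## Known limitations

Long reads, chimeric/fusion transcripts and de novo (FASTA) assemblies
are out of scope. Junctions reported by assemblers but unseen in the
reads are dropped rather than rescued. The depth calculus treats
assemblers as independent voters; correlated errors between assemblers
would defeat it. $c_{\min}$ is a bottleneck proxy, not an abundance
estimate.
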