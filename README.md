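# isopath

Genome-guided transcriptome assembly that borrows evidence from the
transcript sets of several upstream assemblers. `isopath` is aimed at
RNA-seq analysts who already run one or more reference-based assemblers
and want a consensus-driven reconstruction of isoforms per gene locus,
including lowly expressed ones that single tools tend to miss.

## Method

Per gene locus, spliced paired-end alignments define a **splicing graph**
*G*: nodes are exon segments, edges are splice junctions and intra-exon
adjacencies, edge weights are supporting-fragment counts. Two evidence
channels constrain the path search over *G*:

- **Paired subpaths** — a read pair with mate paths *P₁*, *P₂* is phased
  into *P₁ → P_in → P₂* when exactly one connecting path *P_in* exists and
  *p + s + q ≥ 3*; identical subpaths aggregate into a coverage, windows
  with coverage ≥ 2 are reliable.
- **Assembly subpaths** — transcripts from ≥ 2 assembler GTFs merge into a
  per-locus **colored graph** (one node per distinct exon, one colored
  path per transcript); windows whose **depth** (distinct assemblers
  containing them) is ≥ 2 are reliable, and are mapped back onto *G*
  through a junction hash index.

Each *G* is transformed into its weighted **line graph** *L(G)* (nodes =
edges of *G*, node weight = junction coverage). A per-node quadratic
program, solved by non-negative least squares, distributes flow between
incoming and outgoing edges and is binarized into 0/1 connection
indicators. Transcripts are then recovered as a **path cover**: the
longest uncovered reliable subpath seeds a path that is greedily extended
in both directions (weight-1 edges first, then reliable 2-, 3-, …-subpath
witnesses, then node weight), and each committed path subtracts its
minimum node weight *c_min* — its abundance proxy — from the graph. The
loop stops when every reliable subpath and every L-node is covered.
Transcripts with *c_min* below `--min-cov` (default 1.5) are filtered; the
threshold is the recall/precision trade-off knob.

## Worked example

The package ships a deterministic generator for a toy data set (three
multi-isoform genes, 650 read pairs, three concordant mock assemblers):

```r
library(isopath)
spec <- fixture_spec(seed = 1)
aln  <- generate_alignments(spec, "demo")       # SAM + truth table
asm  <- generate_assembler_gtfs(spec, "demo")   # one GTF per assembler
res  <- assemble_transcripts(aln$sam, asm$gtfs, asm$colors,
                             out = "demo/out.gtf", min_cov = 0)
res$transcripts[, c("transcript_id", "intron_chain", "cov")]
#>   transcript_id                        intron_chain cov
#> 1   ISOPATH.1.1                 1400-2000;2250-3000  18
#> 2   ISOPATH.1.2                           1400-3000  17
#> 3   ISOPATH.2.1 10500-11000;11300-12000;12400-13000  14
#> 4   ISOPATH.2.2 10500-11000;11300-12000;12400-14000   0
#> 5   ISOPATH.2.3             10500-12000;12400-13000   0
#> 6   ISOPATH.3.1                 5450-6000;6350-8000  17
#> 7   ISOPATH.3.2                 5450-7000;7300-8000   9
unlist(score_assembly(res$transcripts, aln$truth_df)[c("recall", "precision")])
#>    recall precision
#>         1         1
```

Each row is one assembled transcript: its ordered intron chain (the
structure used to decide correctness — a transcript is correct iff its
intron chain matches a true isoform exactly) and its `cov` abundance
proxy, the bottleneck junction coverage left for that path. The two
`cov = 0` rows are true isoforms whose junctions were fully consumed by
earlier paths; the default filter (`min_cov = 1.5`) would trade them for
precision.

The same pipeline runs from the shell:

```sh
inst/exec/isopath --bam demo/reads.sam \
  --assemblies demo/asmA.gtf,demo/asmB.gtf,demo/asmC.gtf \
  --out demo/out.gtf --min-cov 1.5
```

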