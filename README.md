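# lingedge

Conservation-prioritization toolkit for phylogenetic trees of languages
(or any taxa): fair-proportion **evolutionary distinctiveness (ED)**,
endangerment-weighted **EDGE scores**, taxonomy-based **grafting** of
missing tips into an incomplete backbone tree, and a pruning-based
**robustness analysis** of ED under incomplete sampling.

It is aimed at linguists and conservation scientists who have (a) a rooted
tree with branch lengths in Newick format — for languages, typically
lexical distance in expected cognate replacements; (b) an Ethnologue-style
hierarchical classification mapping each taxon to a nested lineage of
group names; and (c) an endangerment status per taxon on the EGIDS scale
(or any ordinal threat scale).  None of the three is required beyond the
tree plus statuses for basic scoring, and a synthetic generator builds all
three so everything runs with no external data.

## The metric

Fair proportion divides each branch equally among the tips descending from
it; a tip's ED is the sum of its shares along the root path, so tip scores
sum exactly to the tree's total branch length.  Because lexical branch
lengths have no absolute unit, scores are normalized to relative ED
(ED_R, mean 1 over the measured tips).  Endangerment statuses map to a GE
multiplier on a doubling scale (national = 1/32 … vigorous = 1,
threatened = 2, nearly extinct = 4), and the default (modified) EDGE score
balances the two ingredients:

    EDGE = ln(1 + ED_R) + (GE / 4) * ln 2

so that endangerment alone contributes at most ln 2.  The classic
`variant = "original"` form `ln(1 + ED) + GE * ln 2` is also available.
Taxa missing from the backbone are grafted in from the classification with
zero-length edges: this corrects the descendant counts that inflate the
sampled taxa's ED, without inventing distinctiveness for the unmeasured
ones (whose own scores are suppressed by default).

## A worked example

```r
library(lingedge)

# a synthetic study: 120 taxa, 72 of them on the measured backbone,
# classification derived from the truth tree, random EGIDS statuses
sc  <- make_scenario(120, sampling_fraction = 0.6, seed = 42)
res <- score_languages(sc$backbone, sc$statuses,
                       classification = sc$classification)
res
#> EDGE scores for 72 measured taxa (48 taxa grafted in); 25 threatened (GE >= 2)
#>  taxon      ED ED_R     GE   EDGE rank grafted
#>    t80 16.3236 3.27 2.0000 1.7979    1   FALSE
#>    t62 23.9540 4.80 0.0625 1.7682    2   FALSE
#>    t59 10.7475 2.15 3.5000 1.7546    3   FALSE
#>     t4 17.1939 3.44 1.0000 1.6647    4   FALSE
#>    t82 11.9682 2.40 2.0000 1.5694    5   FALSE
#>    t55 13.3897 2.68 1.0000 1.4766    6   FALSE
```

The top-ranked taxon t80 combines high distinctiveness (3.27 times the
average taxon's ED) with threatened status (GE = 2); t62 is the most
distinct taxon of all (ED_R = 4.8) and ranks second despite being almost
unendangered — exactly the trade-off the metric is designed to expose.
The 48 grafted taxa sharpen the 72 measured scores but get no rows of
their own.

How robust are those scores to incomplete sampling?

```r
pruning_experiment(sc$backbone, 0.5, reps = 200, seed = 42)
#> Pruning experiment (reduced arm): fraction 0.500 (36 tips), 200 replicates
#> mean R^2 = 0.8165, central 99% band [0.6374, 0.9504]
```

Half the tips removed, yet ED of the survivors still correlates with the
full-tree scores at a mean R² of 0.82 — heavy-tailed branch lengths make
fair-proportion ED initially resilient to missing taxa.

Is a region whose best member ranks only 83rd of 350 significantly
under-prioritized?  With 53 taxa in the region:

```r
group_best_rank_pvalue(350, 53, 83)
#> [1] 1.831822e-07
```

A command-line interface wraps the same functions
(`inst/cli/lingedge.R`, subcommands `score`, `graft`, `sensitivity`,
`ranktest`, `synth`); every stochastic subcommand requires `--seed`, and
all output files carry an audit header.

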