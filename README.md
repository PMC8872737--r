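# beadmap

Map single-cell images recorded by an imaging flow cytometer to the
physical positions of the same cells after a robotic dispenser has placed
them, first-in-first-out, on a porous membrane.

The link between the two instruments is a sequence code. Marker beads of
three sizes — 10, 20 and 30 µm, read as the symbols `A`, `T` and `C` — are
premixed with the cells at a 2:1 cell:marker ratio, so both readouts observe
the same marker string with, on average, two cells in each inter-marker gap.
`beadmap` aligns the two marker strings by global (Needleman–Wunsch)
dynamic programming (default scoring: match +5, mismatch −4, linear gap −8;
banded with automatic band verification for long runs), classifies every
disagreement as a **deletion** (object trapped in the fluidics), an
**insertion**, or a **misplacement** (FIFO violation), and localizes each
error on the template coordinate system. Cells are then mapped only inside
*verified segments*: gaps whose flanking markers align cleanly and whose
imaged and plate cell counts agree. Everything adjacent to an error is
dropped rather than guessed, which is what keeps wrong image-to-cell
assignments rare at the cost of some retention.

The package is a complete desk-scale laboratory for the method: simulators
for event streams and both error processes, the aligner and error
classifier, the segment-matching and mapping stage, Monte Carlo experiments
(detection probability and retention versus error rate), a synthetic plate
imager with pore background plus size-based detection/registration of beads
and cells to micron accuracy, 2D/3D morphological features, and a
from-scratch k-means with a fit/predict workflow. A command-line front end
(`inst/cli/beadmap.R`) exposes the pipeline as subcommands
(`simulate-stream`, `match`, `mc-curve`, `plate-detect`, `features`,
`cluster`).

## Worked example

Simulate a run of 1,000 markers and 2,000 cells, corrupt the plate-side
readout with 1% deletions and 1% local misplacements, and match the two
readouts:

```r
library(beadmap)

ifc <- generate_stream(1000, cell_marker_ratio = 2, seed = 42)
cpp <- apply_misplacement(apply_deletion(ifc, 0.01, seed = 1)$stream,
                          0.01, max_shift = 5, seed = 2)$stream

res <- run_matching(ifc, cpp, config = run_config(seed = 42))
table(res$segments$status)
#> dropped_count_mismatch       dropped_flanking   dropped_marker_error
#>                     60                      2                     27
#>                matched
#>                    912
str(res$stats)
#> List of 5
#>  $ retention_fraction: num 0.861
#>  $ misassignment_rate: num 0.00988
#>  $ usable_fraction   : num 1
#>  $ n_mapped          : int 1721
#>  $ n_interior        : int 1999
```

912 of the 999 interior gaps survive the drop rules, mapping 86% of the
cells; the `error_report` in `res$errors` lists each detected marker-level
error with its localized position (12 in this run, e.g. `deletion of T at
position 151`). Misassignment among retained cells (~1% here) comes almost
entirely from misplacements that reorder cells *within* one gap, which
per-gap count verification cannot see — see the methods vignette for the
analysis.

Detection probability of the sequence-level study, at the headline scale:

```r
detection_curve("deletion", rates = c(0.01, 0.05), n_symbols = 10000,
                replicates = 5, seed = 7)
#> <detection_curve> deletion, n_symbols=10000, 5 replicate(s)
#>  rate detection_probability       se n_errors
#>  0.01                0.9979 0.002083     95.4
#>  0.05                0.9885 0.004267    488.2
```

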