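# ppiscorekit

Pre- and post-processing for high-throughput protein–protein interaction
(PPI) screens built on AlphaFold-Multimer-class structure predictors.

Running an all-against-all PPI screen involves a lot of bookkeeping around
the predictor itself: sequences must be cleaned and signal peptides
trimmed, alignment depth checked (shallow MSAs weaken the co-evolutionary
signal the predictor relies on), job lists generated with complexes too
large for the accelerator excluded, and the predictor's per-model scores
condensed into something a bench scientist can rank and act on.
`ppiscorekit` automates all of that. It does **not** run the predictor:
structures, PAE matrices and the upstream confidence scores (pi-score,
ipTM_pTM, pDockQ) are its inputs.

## The composite scores

Each upstream metric alone misclassifies interactions near its own
threshold, so hetero interactions are ranked by a weighted composite of
the best model's scores (best = highest ipTM of the five models):

```
iQ  = ((pi-score + 2.63) / 5.26) * 40 + ipTM_pTM * 30 + pDockQ * 30
hiQ = ((mean interface pi-score + 2.63) / 5.26) * 60 + ipTM_pTM * 40
```

pi-score is normalized from its native [−2.63, 2.63] range, so both
composites live on a 0–100 scale. Evaluating them at the constituent
scores' published individual thresholds (pi = 0.05, ipTM_pTM = 0.5,
pDockQ = 0.5) gives **50.38** and **50.57**, which motivates the
operational retention rule: composite **> 50**, applied only to models
whose minimum inter-chain predicted aligned error (PAE) is ≤ 10 Å — a
complex with no confident inter-chain region is rejected before scoring.

Around the scores the package provides: signal-peptide trimming from a
SignalP-style table; per-position MSA depth with shallow flagging
(`shallow_MSA.txt`; flagged proteins are *annotated* as unreliable, never
dropped); all-against-all + homo-oligomer job planning with a
memory-capacity map (`OOM_int.txt`); interface distograms and contact
tables (8 Å Cβ convention); an iQ-score heatmap and an interaction network
with hiQ self-annotations, all with TSV/GraphML sidecars.

## Worked example

A deterministic toy-cohort generator emulates every input format at toy
scale, so the whole chain runs in seconds without a predictor:

```sh
Rscript inst/cli/ppiscorekit.R make-fixtures --out toy --seed 7
Rscript inst/cli/ppiscorekit.R run --fasta toy/proteins.fasta \
    --signalp toy/signalp.tsv --msa-dir toy/msas --models toy/models \
    --out toy_out
```

which prints

```
planned 28 jobs (7 excluded as OOM); flagged 2 shallow MSA(s)
retained 3 / 6 hetero interactions, 1 / 4 homo-oligomers
report written to toy_out/report
```

28 jobs are C(7,2) = 21 hetero pairs plus 7 homo-dimers; the 7 exclusions
all involve the deliberately oversized protein P05 (a 24 GB accelerator
fits ~3600 residues). The retained table (`retained_interactions.tsv`)
starts:

```
job_id   protein_a  protein_b  iq_score          retained  unreliable_msa
P01;P02  P01        P02        72.6045627376426  TRUE      FALSE
P04;P06  P04        P06        58.3022813688213  TRUE      TRUE
P02;P03  P02        P03        56.7813688212928  TRUE      FALSE
```

`P04;P06` is retained but flagged `unreliable_msa`: P06's alignment is
shallow, so the score should be treated with caution — exactly the
annotate-don't-drop behavior described above. The same run from R:

```r
library(ppiscorekit)
generate_cohort("toy", seed = 7)
res <- run_pipeline("toy/proteins.fasta", "toy_out",
                    signalp_table = "toy/signalp.tsv",
                    msa_dir = "toy/msas", models_dir = "toy/models")
res$scored$interactions    # all six pairs, constituent + composite scores
```

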