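# riboTails

Tools for two linked questions about translational control, written for
researchers analyzing ribosome profiling (Ribo-seq) and circularization-RACE
(cRACE) sequencing data:

1. **Which mRNAs change translation efficiency, and where do ribosomes
   sit on them?** Starting from transcript-space footprint alignments,
   the package filters ribosome-protected fragments (unique, 28–31 nt,
   A site in the zero frame of the CDS at a +15 nt offset), computes
   basal-normalized codon occupancy, builds 50-bin metagene profiles
   that expose 5′-CDS stalling (e.g. on signal-peptide-encoding,
   ER-targeted mRNAs), and calls differential translation efficiency
   (TE) at a 2-fold threshold, with Fisher's exact enrichment of
   signal-peptide/transmembrane annotation and codon-usage comparisons
   downstream.
2. **What exactly is on a small RNA's 3′ end?** From cRACE reads that
   span the 3′–5′ ligation junction, the package reconstructs exact 3′
   termini, separates templated nucleotides (including the Pol III 4-U
   terminator read-through) from non-templated tails with a greedy
   templated-first rule, calls uridylation (≥5 consecutive U in the
   non-templated tail), and fits a logistic model of uridylation
   probability against 3′ truncation.

## The core models

**Translation efficiency.** For gene *g* with footprint CPM *R* and
mRNA CPM *M* (pseudocount *c* = 0.5), per replicate TE = (*R*+*c*)/(*M*+*c*);
condition TE is the geometric mean over replicates, and genes are called
`down`/`up` when |log₂(TE_KO/TE_CTRL)| ≥ 1. Codon occupancy of an A-site
event is its positional footprint count divided by the mean count of the
+1,+2,+3 codons downstream (basal normalization); under uniform coverage
every codon's occupancy is exactly 1.

**Uridylation vs truncation.** With *x* the 3′ truncation in nt
(genomic extension = negative truncation), P(uridylated) =
logistic(β₀ + β₁·x), fitted by Newton–Raphson with observed-information
standard errors and explicit separation detection.

Synthetic-data generators (`ribo_sim_config()` / `crace_sim_config()`)
produce both data types with per-gene / per-read ground truth, so every
stage has parameter-recovery tests without any external data.

## Worked example

```r
library(riboTails)

# --- Ribo-seq: simulate a two-condition study and call differential TE ---
cfg   <- ribo_sim_config(n_genes = 500, depth = 5e5, seed = 1)
study <- simulate_ribo_study(cfg)
te    <- call_differential_te(compute_te(study$counts))
table(te$call)
#>      down unchanged
#>        19       481
planted <- study$truth$transcript_id[study$truth$is_planted_down]
sum(te$gene[te$call == "down"] %in% planted)  # 19 of the 20 planted genes
#> [1] 19

# --- cRACE: call 3' tails and fit the uridylation model ---
ref   <- synthetic_crace_reference(seed = 1)
sim   <- simulate_crace_reads(ref, crace_sim_config(n_reads = 1000, seed = 1))
calls <- call_tails(sim$reads, ref)
fit_uridylation_logistic(calls)
#> Logistic model of uridylation vs 3' truncation
#>   n = 1000, converged = TRUE
#>   intercept b0 = -3.3269 (SE 0.2054)
#>   slope     b1 = 0.2716 per nt truncation (SE 0.0177)
#>   Wald z = 15.389, two-sided p = 1.94e-53
#>   logLik = -326.6702 (null -655.6850)
```

The TE table says 19 of 500 genes dropped at least 2-fold in translation
efficiency — 19 of the 20 genes the simulator planted (the twentieth sat
too close to the threshold at this depth). The logistic fit recovers the
simulator's uridylation model (true β₀ = −3, β₁ = 0.25/nt): each extra
nucleotide of 3′ truncation raises the log-odds of carrying a U-tail by
≈0.27, and the association is decisive.

On-disk pipelines with the same semantics are `run_simulation()`,
`run_ribo_pipeline()` and `run_crace_pipeline()`, also reachable as
subcommands of the thin CLI at `inst/scripts/ribotails.R`
(`simulate` / `ribo` / `crace`). Every run writes a JSON manifest with its
configuration and seed; reruns are byte-identical.

See `vignettes/methods.Rmd` for the full account of the models,
parameter defaults, numerical conventions, what the simulators do and do
not emulate, and known limitations.

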