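# rpmotif — de novo motif discovery with repulsive parallel MCMC

`rpmotif` finds short recurring patterns (transcription-factor binding
motifs, typically 8–15 bp) in sets of DNA sequences such as ChIP-seq peak
regions or promoters.  It is aimed at analysts who want *many distinct*
motifs from one run — primary motif plus cofactors — rather than the single
strongest pattern.

The posterior of a motif model over real sequence sets is highly multimodal:
a single Gibbs motif sampler is absorbed by one locally high-probability
motif and stays there.  `rpmotif` runs M complete ZOOPS samplers
("replicas") as one interacting chain with the augmented target

    pi_A(x_1, ..., x_M | beta)  ∝  prod_i pi(x_i) * psi(Theta_1, ..., Theta_M)^beta
    log psi = sum_i min_{j<i} D(Theta_i, Theta_j)

where `D` is a width-aware Frobenius dissimilarity between position
probability matrices (PPMs) with a gap penalty for width differences.  The
repulsive factor `psi^beta` penalises replicas whose motif matrices approach
each other, so different replicas explore different motifs; `beta = 0`
recovers M independent chains.  Each replica is updated by Gibbs sweeps over
sites and background, a slice-sampled PPM update under the repulsion, and a
reversible-jump move on the motif width.  Because repulsion biases the draws,
each kept joint sample carries an importance weight (the inverse repulsive
factor) that restores unbiased posterior estimates.  The M × N sampled motif
states are greedily clustered by PPM dissimilarity into a ranked list of
representative motifs, filtered by sequence-level enrichment (≥ 5% of
sequences by default), and can be scored against known site annotations by
nucleotide-level sensitivity/precision (SN/PPV) and log-likelihood-ratio
(LLR) statistics.

## Worked example

Simulate promoter-like sequences with a GC-box planted in 80% of them, run a
reduced sampler, and inspect the ranked motifs:

```r
library(rpmotif)

dat <- simulate_motif_data(n = 60, length_mode = "fixed", fixed_length = 200,
                           background = c(0.3, 0.2, 0.2, 0.3),
                           ppms = list(gc_box = example_ppm("GGGCGGGG", strength = 0.97)),
                           mean_motifs = 0.8, count_model = "bernoulli", seed = 5)

ctl <- rpmcmc_control(replicas = 5, iterations = 120, burnin = 20)
fit <- rpmcmc(dat$sequences, ctl, seed = 5)
fit
#> Repulsive parallel MCMC motif sampler fit
#>   sequences : 60 (lengths 200-200 bp)
#>   replicas  : 5, iterations 120 (burn-in 20, 100 kept)
#>   widths    : 8-15, beta policy 'dynamic10', weight mode 'exponent'
#>   max sampled log-likelihood: -32449.52

cl <- cluster_motifs(fit)
cl
#> 4 motif clusters from 500 samples (lambda = 0.3, 4 enriched >= 5% of sequences)
#>  rank width   weight n_members sum_z enrichment enriched loglik  consensus
#>     1     8 0.600000       300    46      0.767     TRUE -32460   GGGCGGGG
#>     2     8 0.200004       107    46      0.767     TRUE -32450   CCCCGCCC
#>     3     8 0.199724        68    12      0.200     TRUE -32928   GAtgtaGA
#>     4    10 0.000272        25     8      0.133     TRUE -32934 CTTGtCTtcT

ev <- sn_ppv(dat$truth, predicted_sites(cl))
sprintf("SN = %.3f  PPV = %.3f", ev$SN, ev$PPV)
#> "SN = 0.939  PPV = 1.000"
```

The rank-1 motif is the planted GC-box (consensus `GGGCGGGG`, occupying
46/60 sequences); rank 2 is the same motif read on the opposite strand —
the dissimilarity deliberately does not fold reverse complements together,
so such pairs are expected.  `predicted_sites()` returns 1-based
forward-strand coordinates with a strand column; `write_motif_report()`
serialises PPMs (MEME minimal format), sites (TSV) and a summary table.

A thin command-line wrapper (`inst/scripts/rpmotif`) exposes the same
pipeline as `rpmotif discover | simulate | evaluate` with flag defaults
matching `rpmcmc_control()`.

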