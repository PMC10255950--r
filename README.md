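# tbseq

Analysis of terbium(III) cleavage sequencing (Tb-seq) experiments:
a high-throughput probe for **compact RNA tertiary structure** and
RNP interfaces in long RNAs.

## The science

Folded RNAs compress their phosphate backbones at tertiary modules,
creating pockets of intense negative electrostatic potential that
recruit multivalent cations. Tb³⁺ binds these Mg²⁺-like sites and —
where the backbone adopts an in-line geometry — catalyses strand
scission. Read out by reverse transcription with a gene-specific
primer, each scission becomes a cDNA truncation, so a sequencing
library maps cleavage propensity at single-nucleotide resolution
across a transcript of any length.

The per-nucleotide estimator is the conditional termination
probability

    P(stop) = n_stop / (n_stop + n_readthrough)

computed only at positions with more than 10,000 read-throughs.
Reactivity is the treated-minus-untreated difference of these
probabilities, normalized per profile to the mean of its top decile
and scaled to an upper bound of 8. "Strong Tb signal" sites must pass
three criteria: normalized reactivity > 0.5 in every replicate at the
reference concentration (0.5 mM in vitro, 1 mM in lysate),
reproducibility in ≥ 2 replicates, and dependence of the signal on
the Tb³⁺ concentration series. Probing native versus
Proteinase-K-deproteinized lysate gives the protein-dependence
profile

    ΔTb = Reactivity(lysate + ProtK) − Reactivity(lysate)

classified at a stringent ±0.5 cutoff. Finally, called sites can be
related to backbone compression in 3-D structures through the
phosphate distance d(Pₙ → Pₙ₊₂): sharp tertiary turns sit in a
5.5–9.1 Å band, far below the 9.6–12.5 Å of plain A-form helix.

The package covers the full path — SAM/BAM → stop counts →
reactivities → site calls → ΔTb → backbone geometry — plus a
ground-truth read simulator of RT-truncation libraries, so every
stage is testable without external data.

## Worked example

Simulate a 300-nt transcript with three cleavage sites (κ = 0.15 at
positions 60, 120, 180) over a concentration series, then run the
calling criteria:

```r
library(tbseq)

cfg <- simulation_config(
  sequence = strrep("ACGT", 75), name = "demo_rna",
  cleavage_sites = c("60" = 0.15, "120" = 0.15, "180" = 0.15),
  background_stop = 0.01, n_reads = 2e6, min_read_length = 20)

ex <- simulate_probing_experiment(cfg, concentrations = c(0.1, 0.5, 2),
                                  replicates = c("r1", "r2"),
                                  context = "in_vitro", seed = 1)
ex$profiles[["r1_0.5mM"]]
#> <reactivity_profile> demo_rna | in_vitro rep r1, 0.5 mM Tb | 299/300 usable, F = 0.007866

sites <- call_strong_sites(ex$profiles, threshold = 0.5)
sites
#> <strong_site_set> demo_rna (in_vitro): 3/299 evaluated positions called at 0.5 mM

as.data.frame(sites[sites$called, ])
#>  position mean_norm_reactivity pass_threshold pass_replicates pass_concentration called
#>        60                    8           TRUE            TRUE               TRUE   TRUE
#>       120                    8           TRUE            TRUE               TRUE   TRUE
#>       180                    8           TRUE            TRUE               TRUE   TRUE
```

Of 299 positions with usable coverage, exactly the three seeded sites
pass all three criteria: their normalized reactivity saturates the
8-point scale (they dominate their own profiles' normalization
factor, here F ≈ 0.0079 on the raw probability scale), they reproduce
in both replicates, and their raw signal rises monotonically across
0.1 → 0.5 → 2 mM.

On the structural side, the analytic A-form reference helix gives the
expected helical backbone spacing:

```r
helix <- pn_pn2_distances(ideal_aform_helix(20))
round(helix$d_n_n2[1], 2)
#> [1] 11.42
```

11.42 Å sits inside the 9.6–12.5 Å helix band; compressed tertiary
turns in real structures fall several ångströms below it
(`compare_site_distances()` quantifies the contrast for a called site
set against a reference run).

Real data enter through `read_alignments()` (SAM/BAM against a
single-transcript FASTA) or, end-to-end, through a YAML manifest and
`run_pipeline()`; `inst/cli/tbseq.R` wraps the same functions as a
command-line tool with `count`, `reactivity`, `call`, `delta`,
`geometry`, `simulate`, and `run` subcommands.

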