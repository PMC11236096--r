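# rendor — reverse network diffusion for denoising weighted networks

Inferred biological networks, gene regulatory networks in particular, carry
**transitive noise**: spurious or inflated edges between nodes that are only
connected through intermediaries. `rendor` removes this noise by modelling
it explicitly. The observed network's random walk `P = D⁻¹W` is treated as
the *diffused* image of an unknown direct walk,

    f_m(P) = (m − 1) · P · (mI − P)⁻¹        (forward diffusion)

which accumulates the probability of all connecting paths of length k with
weight 1/mᵏ, each step normalized by the intermediate node's degree. The
denoiser applies the exact functional inverse,

    f_m⁻¹(P) = m · ((m − 1)I + P)⁻¹ · P      (reverse diffusion)

stripping indirect contributions of **all** path lengths at once, then maps
the corrected walk back to a graph through its stationary distribution
(`h(P) = α·diag(π)·P`). Around this core the package provides:

* the full denoising pipeline `rendorDenoise()` (preprocessing
  `W + ε₁J + ε₂I`, negative-row repair, graph reconstruction) and the
  forward model `nrDiffuse()`;
* four comparator denoisers: network deconvolution (`ndDenoise()`), network
  enhancement (`neDenoise()`), the silencer (`silencerDenoise()`) and
  partial correlation (`icmDenoise()`);
* a synthetic-network generator (`makeTrueGraph()`, `injectIndirectNoise()`,
  `noiseSweep()`) producing circular / Erdős–Rényi / Barabási–Albert ground
  truths with labelled indirect-noise edges;
* ranking evaluation (`aurocScore()`, `auprScore()`, `confusionAtK()`,
  `tpCurve()`, `benchmarkDenoisers()`) and TSV/YAML I/O with a command-line
  interface (`cliMain()`, `inst/scripts/rendor-cli.R`).

## Worked example

Build the classic illustration — a 20-node cycle with 15 injected indirect
edges (a 35-edge noisy network) — denoise it, and keep the top 20 edges:

```r
library(rendor)

sp  <- simSpec("circular", n = 20, noiseProportion = 15/35, seed = 3)
net <- injectIndirectNoise(makeTrueGraph(sp), sp)
W   <- noisyWeights(net)

r0    <- edgeRanking(W)                 # the noisy input's own ranking
truth <- truthVector(net, r0)           # 1 = true cycle edge
den   <- rendorDenoise(W, denoiseConfig(m = 4))
r1    <- edgeRanking(den)

rbind(input  = confusionAtK(r0$score, truth, 20),
      rendor = confusionAtK(r1$score, truth, 20))
#>        TP FP  TN FN   f1
#> input  11  9 161  9 0.55
#> rendor 13  7 163  7 0.65
aurocScore(r1$score, truth)   # 0.970, up from 0.956 for the input
auprScore(r1$score, truth)    # 0.744, up from 0.571 for the input
```

Of the 20 top-ranked pairs, denoising turns two false positives back into
true cycle edges, and the full-ranking AUPR rises from 0.571 to 0.744: the
reverse diffusion pushes triangle-closing chords below the true edges they
shortcut. The same pipeline is available from the shell:

```sh
Rscript inst/scripts/rendor-cli.R simulate --topology circular --n 20 \
    --noise-prop 0.4286 --seed 3 --out-dir sim/
Rscript inst/scripts/rendor-cli.R denoise --method rendor --m 4 \
    --in sim/network_001.tsv --out sim/denoised.tsv
Rscript inst/scripts/rendor-cli.R evaluate --scores sim/denoised.tsv \
    --truth sim/labels_001.tsv --k 20
```

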