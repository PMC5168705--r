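## Shared in-code fixtures. Everything is generated at test time; nothing is
## read from disk.

## Feature table with designed signal: `signalVars` shifted upward in BC by
## `shift` (in sd units), remaining `noiseVars` pure noise. Used for model
## tests that do not need the droplet layer.
makeFeatureSim <- function(n = 60, signalVars = c("RASGRF1", "CPXM1", "IC"),
                           noiseVars = c("HOXA10", "DACH1", "Mean12"),
                           shift = 1.2, seed = 1) {
    set.seed(seed)
    labels <- rep(c("HV", "BC"), each = n / 2)
    vars <- c(signalVars, noiseVars)
    x <- matrix(rnorm(n * length(vars)), n, length(vars),
                dimnames = list(NULL, vars))
    x[labels == "BC", signalVars] <- x[labels == "BC", signalVars] + shift
    list(features = as.data.frame(x), labels = labels)
}

## Hand-built droplet wells: `nPosPerWell[i]` positive droplets (amplitude
## ~8000) out of `nDroplets`, negatives ~1000; labels alongside.
makeWellSim <- function(nPosPerWell, labels, nDroplets = 3000,
                        seed = 1, negMean = 1000, negSd = 60,
                        posMean = 8000, posSd = 200) {
    set.seed(seed)
    stopifnot(length(nPosPerWell) == length(labels))
    ids <- sprintf("W%03d", seq_along(nPosPerWell))
    tabs <- lapply(seq_along(ids), function(i) {
        np <- nPosPerWell[i]
        data.frame(sample_id = ids[i], marker = "M1", well = "A01",
                   channel = "FAM",
                   amplitude = c(rnorm(np, posMean, posSd),
                                 rnorm(nDroplets - np, negMean, negSd)))
    })
    list(droplets = DropletData(do.call(rbind, tabs)),
         labels = stats::setNames(labels, ids))
}

## A tiny complete MarkerQuant table (all 16 panel markers x samples) from
## given per-marker concentrations; positivity = concentration > 0.
makeQuantFixture <- function(conc_by_sample) {
    panel <- MarkerPanel()
    mks <- c(methylationMarkers(panel), internalControls(panel))
    do.call(rbind, lapply(names(conc_by_sample), function(s) {
        conc <- conc_by_sample[[s]]
        stopifnot(length(conc) == 16)
        data.frame(sample_id = s, marker = mks, n_pos = NA, n_total = NA,
                   lambda = NA, concentration = conc,
                   log10_concentration = log10(conc),
                   cutoff_used = 0, positive_call = conc > 0)
    }))
}
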