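# Shared fixtures, built once per test run and cached.

.fixcache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixcache[[name]]))
    assign(name, force(expr), envir = .fixcache)
  get(name, envir = .fixcache)
}

fxPanel <- function() fixture("panel", referencePanel())
fxCutoffs <- function() fixture("cutoffs", defaultCutoffs())
fxPbmcLineages <- function() fixture("pbmc_lt", lineageTable("pbmc_core"))
fxBmtLineages <- function() fixture("bmt_lt", lineageTable("bmt_subsets"))
fxPbmcTemplates <- function() fixture("pbmc_tmpl",
                                      populationTemplates("pbmc_default"))
fxTree <- function() fixture("pbmc_tree", gatingTree(fxPbmcLineages()))

# the bundled 50,000-event PBMC simulation used by the coverage and gating
# acceptance checks and several unit tests
fxPbmcSim <- function() fixture("pbmc_sim", {
  cfg <- simConfig(50000, seed = 2024, templates = fxPbmcTemplates(),
                   beadFraction = 0.05, doubletRate = 0.02,
                   deadFraction = 0.03)
  simulateSample(cfg)
})

# arcsinh-transformed, bead-normalized, pre-gated view of fxPbmcSim
fxPbmcGated <- function() fixture("pbmc_gated", {
  sim <- fxPbmcSim()
  tr <- arcsinhTransform(beadNormalize(sim$matrix)$matrix)
  pg <- pregate(tr, fxCutoffs())
  res <- suppressWarnings(
    applyGating(tr[pg$mask], fxTree(), fxCutoffs(), sampleId = "pbmc50k"))
  list(tr = tr, mask = pg$mask, attrition = pg$attrition,
       pregated = tr[pg$mask], result = res,
       truth = sim$truth[pg$mask, , drop = FALSE])
})

# a small EventMatrix with given antibody values on the reference panel
# (aux channels filled with plausible live-singlet values)
makeMatrix <- function(values, antigens = colnames(values), seed = 1) {
  set.seed(seed)
  panel <- fxPanel()
  meta <- CytoMonitor:::.panelChannelMeta(panel)
  n <- nrow(values)
  y <- matrix(0.2, n, nrow(meta), dimnames = list(NULL, meta$name))
  ab <- meta$name[match(antigens, meta$antigen)]
  y[, ab] <- values
  y[, meta$name[meta$class == "dna"]] <- 6
  y[, meta$name[meta$class == "length"]] <- 2.5
  y[, meta$name[meta$class == "viability"]] <- 0.5
  tm <- sort(runif(n, 0, 100))
  y[, meta$name[meta$class == "time"]] <- tm
  new("EventMatrix", exprs = y, channelMeta = meta, time = tm,
      scale = "arcsinh", scaleFactors = numeric(0))
}

# binomial tolerance: 4 standard errors of a proportion
tol4se <- function(p, n) 4 * sqrt(p * (1 - p) / n)
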