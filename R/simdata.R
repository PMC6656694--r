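# Synthetic mass-cytometry data with ground truth.
#
# Marker intensities are generated as Gaussians on the arcsinh scale
# (censored at zero, i.e. non-negative raw counts), one mode per population
# template, then inverse-transformed to raw dual counts and multiplied by
# the acquisition-time sensitivity drift.  The four expression levels used
# by the templates sit at fixed arcsinh locations matched to the default
# cutoff table.

.LEVELS <- c(neg = 0.5, low = 2.6, pos = 4.2, high = 5.8)
.SPREAD <- 0.4
# auxiliary-channel generation parameters (arcsinh scale)
.AUX <- list(
  dna = c(loc = 6.0, sd = 0.15), dna_bead = c(loc = 0.2, sd = 0.15),
  length = c(loc = 2.5, sd = 0.10), viab_live = c(loc = 0.8, sd = 0.40),
  viab_dead = c(loc = 4.5, sd = 0.40), bead = c(loc = 5.5, sd = 0.30),
  bead_bg = c(loc = 0.2, sd = 0.15), bc_on = c(loc = 5.5, sd = 0.30),
  bc_off = c(loc = 0.3, sd = 0.20))
.COFACTOR <- 5

# population-typical markers beyond the defining clauses, so that every
# template carries at least four positively identifying antigens (synthetic
# calibration; per-population intensity distributions are this package's
# choice, not measured data)
.TEMPLATE_EXTRAS <- list(
  "CD4 T naive" = c(CD127 = "pos", CD27 = "pos"),
  "CD4 T central memory" = c(CD127 = "pos", CD27 = "pos", CD45RO = "pos"),
  "CD4 T effector memory" = c(CD45RO = "pos", "PD-1" = "pos"),
  "CD4 T effector" = c(Tbet = "pos"),
  "Treg" = c(CD45RO = "pos"),
  "Treg naive" = c(CD38 = "pos"),
  "Treg memory" = c(CD45RO = "pos"),
  "CD8 T naive" = c(CD127 = "pos", CD27 = "pos"),
  "CD8 T central memory" = c(CD45RO = "pos", CD27 = "pos"),
  "CD8 T effector memory" = c(CD45RO = "pos"),
  "CD8 T effector" = c(Tbet = "pos"),
  "gd T cells" = c(CD45RA = "pos", CD27 = "pos"),
  "gd T CD45RA+" = c(CD27 = "pos"),
  "gd T CD45RA-" = c(CD45RO = "pos", CD27 = "pos"),
  "NKT cells" = c(CD45RO = "pos", CD56 = "pos"),
  "DP T cells" = c(CD45RA = "pos", CCR7 = "pos"),
  "DN T cells" = c(CD45RO = "pos", CD38 = "pos"),
  "CD27- B cells" = c(CD45RA = "pos"),
  "CD27+ B cells" = c(CD45RA = "pos"),
  "Plasmablasts" = c("Ki-67" = "pos"),
  "Transitional B cells" = c(CD45RA = "pos"),
  "CD56high CD16- NK cells" = c(CCR7 = "pos", Tbet = "pos"),
  "CD56high CD16+ NK cells" = c(Tbet = "pos"),
  "CD56low CD16+ NK cells" = c(Tbet = "pos", CD45RA = "pos"),
  "Classical monocytes" = c("HLA-DR" = "pos", CD11c = "pos", CD38 = "pos"),
  "Intermediate monocytes" = c("HLA-DR" = "pos", CD11c = "pos"),
  "Non-classical monocytes" = c("HLA-DR" = "pos", CD11c = "pos"),
  "cDC" = c(CD11b = "pos", CD33 = "pos"),
  "pDC" = c(CD45RA = "pos", CD38 = "pos"),
  "Basophils" = c(CD38 = "pos", CD11b = "pos"),
  "HLA-DR-CD16+ cells" = c(CD38 = "pos"),
  "CD117+ progenitors" = c(CD45RA = "pos"))

.PBMC_FREQ <- c(
  "CD4 T naive" = 0.11, "CD4 T central memory" = 0.10,
  "CD4 T effector memory" = 0.06, "CD4 T effector" = 0.02, "Treg" = 0.02,
  "CD8 T naive" = 0.07, "CD8 T central memory" = 0.04,
  "CD8 T effector memory" = 0.05, "CD8 T effector" = 0.04,
  "gd T cells" = 0.03, "NKT cells" = 0.01,
  "CD27- B cells" = 0.06, "CD27+ B cells" = 0.03, "Plasmablasts" = 0.005,
  "CD56low CD16+ NK cells" = 0.10, "CD56high CD16- NK cells" = 0.01,
  "Classical monocytes" = 0.15, "Intermediate monocytes" = 0.03,
  "Non-classical monocytes" = 0.04,
  "cDC" = 0.01, "pDC" = 0.005, "Basophils" = 0.01)

# bmt profile: leaf medians in percent; "HLA-DR-CD16+ cells" is the filler
# population that absorbs the remainder of each sample
.BMT_MEDIAN_PCT <- c(
  "gd T CD45RA+" = 0.4, "gd T CD45RA-" = 0.3, "NKT cells" = 0.3,
  "Treg naive" = 0.2, "Treg memory" = 1.3,
  "CD4 T naive" = 0.3, "CD4 T central memory" = 7.0,
  "CD4 T effector memory" = 5.0, "CD4 T effector" = 2.0,
  "CD8 T naive" = 0.5, "CD8 T central memory" = 3.0,
  "CD8 T effector memory" = 4.0, "CD8 T effector" = 3.5,
  "DP T cells" = 0.3, "DN T cells" = 0.9,
  "Plasmablasts" = 0.1, "Transitional B cells" = 0.15,
  "CD27+ B cells" = 0.35, "CD27- B cells" = 3.33,
  "CD56high CD16- NK cells" = 0.6, "CD56high CD16+ NK cells" = 0.5,
  "CD56low CD16+ NK cells" = 6.0,
  "Classical monocytes" = 20.0, "Intermediate monocytes" = 3.0,
  "Non-classical monocytes" = 4.0,
  "pDC" = 0.3, "cDC" = 0.8, "Basophils" = 0.3, "CD117+ progenitors" = 0.5)
.BMT_FILLER <- "HLA-DR-CD16+ cells"

# accumulate marker levels along the path root -> leaf, then extras
.templateLevels <- function(leaf, lineages, idx) {
  d <- lineages@definitions
  path <- rev(c(leaf, .ancestors(leaf, idx$parent)))
  lev <- character(0)
  for (nm in path) {
    i <- match(nm, d$name)
    lev[names(d$positive[[i]])] <- d$positive[[i]]
    lev[names(d$negative[[i]])] <- d$negative[[i]]
  }
  ex <- .TEMPLATE_EXTRAS[[leaf]]
  lev[setdiff(names(ex), names(lev))] <- ex[setdiff(names(ex), names(lev))]
  lev
}

#' Population templates for the bundled simulation profiles
#'
#' Builds the per-population intensity templates (arcsinh-scale location
#' and spread per antigen) used by the generator.  Locations come from the
#' marker-sign definitions of the matching lineage table, accumulated from
#' root to leaf, at the four fixed expression levels (neg 0.5, low 2.6,
#' pos 4.2, high 5.8); unlisted antigens sit at the negative baseline.
#'
#' @param profile \code{"pbmc_default"} (healthy PBMC composition) or
#'   \code{"bmt"} (post-transplant composition; the HLA-DR-CD16+ filler
#'   population absorbs the frequency remainder).
#' @param panel an \linkS4class{AntibodyPanel}.
#' @return list of templates; each has \code{name}, \code{frequency},
#'   \code{location} and \code{spread} (named by antigen).
#' @export
populationTemplates <- function(profile = c("pbmc_default", "bmt"),
                                panel = referencePanel()) {
  profile <- match.arg(profile)
  lineages <- lineageTable(if (profile == "pbmc_default") "pbmc_core"
                           else "bmt_subsets")
  freq <- if (profile == "pbmc_default") .PBMC_FREQ else {
    f <- .BMT_MEDIAN_PCT / 100
    f[.BMT_FILLER] <- 1 - sum(f)
    f
  }
  idx <- .lineageIndex(lineages)
  antigens <- panelAntigens(panel)
  lapply(names(freq), function(leaf) {
    lev <- .templateLevels(leaf, lineages, idx)
    loc <- setNames(rep(.LEVELS[["neg"]], length(antigens)), antigens)
    loc[names(lev)] <- .LEVELS[lev]
    list(name = leaf, frequency = unname(freq[[leaf]]), location = loc,
         spread = setNames(rep(.SPREAD, length(antigens)), antigens))
  })
}

#' Simulation configuration
#'
#' @param nEvents number of events to generate (> 0).
#' @param seed integer RNG seed; generation is bitwise-reproducible given
#'   the seed (R's default Mersenne-Twister generator).
#' @param templates list of population templates
#'   (\code{\link{populationTemplates}}); frequencies must sum to 1.
#' @param beadFraction fraction of events that are EQ calibration beads.
#' @param doubletRate fraction of cell events that are cell-cell doublets.
#' @param deadFraction fraction of cell events that are cisplatin-high
#'   dead cells.
#' @param drift \code{NULL} (no drift) or a function of acquisition time
#'   returning a positive multiplicative sensitivity factor (applied to all
#'   mass channels).
#' @param barcode optional character vector of barcode metals to set high
#'   for every event of this sample (used by the pooling generator).
#' @param duration acquisition duration in seconds.
#' @param name sample identifier.
#' @return a validated \code{simConfig} list.
#' @export
simConfig <- function(nEvents, seed, templates,
                      beadFraction = 0, doubletRate = 0, deadFraction = 0,
                      drift = NULL, barcode = NULL, duration = 600,
                      name = "sample1") {
  cfg <- list(nEvents = as.integer(nEvents), seed = as.integer(seed),
              templates = templates, beadFraction = beadFraction,
              doubletRate = doubletRate, deadFraction = deadFraction,
              drift = drift, barcode = barcode, duration = duration,
              name = name)
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  if (!is.finite(cfg$nEvents) || cfg$nEvents <= 0L)
    stop("nEvents must be positive", call. = FALSE)
  fr <- c(cfg$beadFraction, cfg$doubletRate, cfg$deadFraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("beadFraction, doubletRate and deadFraction must lie in [0, 1]",
         call. = FALSE)
  f <- vapply(cfg$templates, `[[`, numeric(1), "frequency")
  if (abs(sum(f) - 1) > 1e-9)
    stop("template frequencies must sum to 1 (got ", sum(f), ")",
         call. = FALSE)
  if (!is.null(cfg$drift)) {
    if (!is.function(cfg$drift))
      stop("drift must be NULL or a function of time", call. = FALSE)
    if (any(cfg$drift(seq(0, cfg$duration, length.out = 11)) <= 0))
      stop("drift values must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

# one block of arcsinh-scale antibody values for rows of a template matrix
.drawTemplateBlock <- function(n, template, antigens, locShift = NULL) {
  loc <- template$location[antigens]
  if (!is.null(locShift)) loc <- pmax(loc + locShift[antigens], 0)
  sp <- template$spread[antigens]
  m <- matrix(rnorm(n * length(antigens), mean = rep(loc, each = n),
                    sd = rep(sp, each = n)), nrow = n)
  pmax(m, 0)
}

#' Simulate one mass-cytometry sample with ground truth
#'
#' Generates \code{nEvents} events: live cells drawn as a multinomial over
#' the population templates, plus (optionally) EQ calibration beads (high
#' in all five bead metals, DNA-negative), cisplatin-high dead cells, and
#' cell-cell doublets (raw intensity sums of two live cells with doubled
#' DNA and elevated event length).  Values are Gaussian per template on the
#' arcsinh scale, censored at zero, inverse-transformed to raw dual counts
#' and multiplied by the sensitivity drift at the event's acquisition time.
#'
#' @param config a \code{\link{simConfig}}.
#' @param panel an \linkS4class{AntibodyPanel}.
#' @param locShift optional named per-antigen arcsinh location shift
#'   (technical staining variation; see
#'   \code{\link{simulateReplicatePair}}).
#' @return list with \code{matrix} (raw-scale \linkS4class{EventMatrix}),
#'   \code{truth} (data.frame: per-event \code{label}, \code{bead},
#'   \code{doublet}, \code{dead} and \code{sample}), and \code{trueFreq}
#'   (the template frequency vector used).
#' @export
simulateSample <- function(config, panel = referencePanel(),
                           locShift = NULL) {
  .validateSimConfig(config)
  set.seed(config$seed)
  .simulateSampleNoSeed(config, panel, locShift)
}

.simulateSampleNoSeed <- function(config, panel, locShift = NULL) {
  n <- config$nEvents
  meta <- .panelChannelMeta(panel, barcodeMetals = attr(config, "bcMetals"))
  antigens <- meta$antigen[meta$class == "antibody"]
  tnames <- vapply(config$templates, `[[`, character(1), "name")
  tfreq <- vapply(config$templates, `[[`, numeric(1), "frequency")

  nBead <- rbinom(1, n, config$beadFraction)
  nCell <- n - nBead
  nDoublet <- rbinom(1, nCell, config$doubletRate)
  nSingle <- nCell - nDoublet
  nDead <- rbinom(1, nSingle, config$deadFraction)

  # population of each singlet cell (dead cells are also template draws)
  popIdx <- sample.int(length(tnames), nSingle, replace = TRUE, prob = tfreq)
  y <- matrix(0, nrow = n, ncol = nrow(meta),
              dimnames = list(NULL, meta$name))
  rowsCell <- seq_len(nSingle)
  abCols <- meta$name[meta$class == "antibody"]
  for (k in seq_along(tnames)) {
    rows <- rowsCell[popIdx == k]
    if (!length(rows)) next
    y[rows, abCols] <- .drawTemplateBlock(length(rows), config$templates[[k]],
                                          antigens, locShift)
  }

  dnaCols <- meta$name[meta$class == "dna"]
  viabCols <- meta$name[meta$class == "viability"]
  beadCol <- meta$name[meta$class == "bead"]
  lenCol <- meta$name[meta$class == "length"]
  timeCol <- meta$name[meta$class == "time"]
  draw <- function(rows, cols, par)
    pmax(matrix(rnorm(length(rows) * length(cols), par[["loc"]], par[["sd"]]),
                nrow = length(rows)), 0)
  y[rowsCell, dnaCols] <- draw(rowsCell, dnaCols, .AUX$dna)
  y[rowsCell, lenCol] <- draw(rowsCell, lenCol, .AUX$length)
  dead <- rep(FALSE, n)
  dead[sample(rowsCell, nDead)] <- TRUE
  y[rowsCell, viabCols] <- draw(rowsCell, viabCols, .AUX$viab_live)
  if (nDead) y[dead, viabCols] <- draw(which(dead), viabCols, .AUX$viab_dead)
  y[rowsCell, beadCol] <- draw(rowsCell, beadCol, .AUX$bead_bg)

  # convert cells to raw now so doublets can be built as raw sums
  massCols <- setdiff(meta$name, c(timeCol, lenCol))
  raw <- y
  raw[, massCols] <- .COFACTOR * sinh(y[, massCols, drop = FALSE])
  raw[, lenCol] <- .COFACTOR * sinh(y[, lenCol, drop = FALSE])

  lab <- rep(NA_character_, n)
  lab[rowsCell] <- tnames[popIdx]
  doublet <- rep(FALSE, n)
  if (nDoublet) {
    rowsD <- nSingle + seq_len(nDoublet)
    i1 <- sample(rowsCell, nDoublet, replace = TRUE)
    i2 <- sample(rowsCell, nDoublet, replace = TRUE)
    raw[rowsD, massCols] <- raw[i1, massCols, drop = FALSE] +
      raw[i2, massCols, drop = FALSE]
    # ion-cloud length of a coincident event: ~1.6x a singlet, not 2x
    raw[rowsD, lenCol] <- 0.8 * (raw[i1, lenCol] + raw[i2, lenCol])
    doublet[rowsD] <- TRUE
    lab[rowsD] <- "debris"
  }
  bead <- rep(FALSE, n)
  if (nBead) {
    rowsB <- nSingle + nDoublet + seq_len(nBead)
    beadChan <- meta$name[!is.na(meta$metal) &
                          meta$metal %in% .EQ_BEAD_METALS]
    yb <- matrix(0, nBead, length(massCols), dimnames = list(NULL, massCols))
    yb[] <- pmax(matrix(rnorm(length(yb), .AUX$bead_bg[["loc"]],
                              .AUX$bead_bg[["sd"]]), nBead), 0)
    yb[, beadChan] <- draw(seq_len(nBead), beadChan, .AUX$bead)
    yb[, dnaCols] <- draw(seq_len(nBead), dnaCols, .AUX$dna_bead)
    raw[rowsB, massCols] <- .COFACTOR * sinh(yb)
    raw[rowsB, lenCol] <- .COFACTOR *
      sinh(draw(seq_len(nBead), lenCol, .AUX$length))
    bead[rowsB] <- TRUE
    lab[rowsB] <- "bead"
  }
  if (!is.null(config$barcode)) {
    bcCols <- meta$name[meta$class == "barcode"]
    onCols <- meta$name[!is.na(meta$metal) & meta$metal %in% config$barcode]
    yc <- matrix(pmax(rnorm(n * length(bcCols), .AUX$bc_off[["loc"]],
                            .AUX$bc_off[["sd"]]), 0), n,
                 dimnames = list(NULL, bcCols))
    yc[, onCols] <- pmax(matrix(rnorm(n * length(onCols),
                                      .AUX$bc_on[["loc"]],
                                      .AUX$bc_on[["sd"]]), n), 0)
    raw[, bcCols] <- .COFACTOR * sinh(yc)
  }

  # acquisition order and time, then sensitivity drift
  ord <- sample.int(n)
  raw <- raw[ord, , drop = FALSE]
  lab <- lab[ord]; bead <- bead[ord]; doublet <- doublet[ord]
  dead <- dead[ord]
  tm <- sort(runif(n, 0, config$duration))
  raw[, timeCol] <- tm
  if (!is.null(config$drift)) {
    g <- config$drift(tm)
    raw[, massCols] <- raw[, massCols, drop = FALSE] * g
  }
  truth <- data.frame(label = lab, bead = bead, doublet = doublet,
                      dead = dead, sample = config$name,
                      stringsAsFactors = FALSE)
  em <- new("EventMatrix", exprs = raw, channelMeta = meta, time = tm,
            scale = "raw", scaleFactors = numeric(0))
  list(matrix = em, truth = truth, trueFreq = setNames(tfreq, tnames))
}

#' Simulate a pair of technical replicates
#'
#' Emulates aliquots of the same donor stained and acquired at two sites:
#' both replicates share the same true population frequency vector, while
#' per-channel staining variation is modeled as a per-replicate arcsinh
#' location shift drawn with the given standard deviation.
#'
#' @param config a \code{\link{simConfig}} (seed seeds both draws).
#' @param technicalNoiseSd standard deviation (arcsinh units) of the
#'   per-channel location shift; must be >= 0.
#' @param panel an \linkS4class{AntibodyPanel}.
#' @return list of two \code{simulateSample} results (\code{a}, \code{b}).
#' @export
simulateReplicatePair <- function(config, technicalNoiseSd = 0.05,
                                  panel = referencePanel()) {
  if (!is.numeric(technicalNoiseSd) || technicalNoiseSd < 0)
    stop("technicalNoiseSd must be >= 0", call. = FALSE)
  .validateSimConfig(config)
  set.seed(config$seed)
  antigens <- panelAntigens(panel)
  shiftA <- setNames(rnorm(length(antigens), 0, technicalNoiseSd), antigens)
  shiftB <- setNames(rnorm(length(antigens), 0, technicalNoiseSd), antigens)
  cfgA <- config; cfgA$name <- paste0(config$name, "_siteA")
  cfgB <- config; cfgB$name <- paste0(config$name, "_siteB")
  a <- .simulateSampleNoSeed(cfgA, panel, locShift = shiftA)
  b <- .simulateSampleNoSeed(cfgB, panel, locShift = shiftB)
  list(a = a, b = b)
}

#' Bundled GvHD effect table for the bmt cohort profile
#'
#' Group-specific median frequencies (percent of live leukocytes) for the
#' populations whose abundance differs between patients with and without
#' GvHD: CD27- B cells (0.44 vs 3.33) and naive CD4 T cells (0.09 vs 0.3).
#'
#' @return data.frame with columns \code{population}, \code{group},
#'   \code{median_pct}.
#' @export
gvhdEffectTable <- function() {
  data.frame(
    population = c("CD27- B cells", "CD4 T naive"),
    group = c("GvHD", "GvHD"),
    median_pct = c(0.44, 0.09),
    stringsAsFactors = FALSE)
}

#' Simulate a BMT monitoring cohort
#'
#' Emulates the bundled bone-marrow-transplant cohort: 15 donors (3 with
#' GvHD) sampled at up to two time points for 28 samples total.  Per-sample
#' true frequencies are drawn around the group medians with logit-normal
#' dispersion; the HLA-DR-CD16+ filler population absorbs the remainder so
#' that the named population medians are exact generator parameters.
#'
#' @param profile cohort profile; only \code{"bmt"} is bundled.
#' @param nSamples number of samples (default 28).
#' @param groupAssignment optional data.frame with columns
#'   \code{sample_id}, \code{donor}, \code{time_point}, \code{group};
#'   defaults to the bundled cohort shape.
#' @param effectTable data.frame of group-specific medians
#'   (\code{\link{gvhdEffectTable}}); \code{NULL} disables group effects
#'   (both groups exchangeable).
#' @param seed integer seed.
#' @param nEvents events per sample.
#' @param frequencyNoise logit-normal standard deviation of the per-sample
#'   frequency perturbation (default 0.7, reflecting the large
#'   between-patient dispersion of post-transplant immune composition).
#' @param eventData if \code{FALSE}, only true frequencies and metadata are
#'   generated (fast path for count-level simulation studies).
#' @param beadFraction,doubletRate,deadFraction passed to each sample's
#'   \code{\link{simConfig}}.
#' @return list with \code{samples} (list of \code{simulateSample} results,
#'   or \code{NULL}s when \code{eventData = FALSE}), \code{metadata}
#'   (sample_id, donor, time_point, group), and \code{trueFreq}
#'   (populations x samples matrix of true frequencies).
#' @export
simulateCohort <- function(profile = "bmt", nSamples = 28,
                           groupAssignment = NULL,
                           effectTable = gvhdEffectTable(), seed = 1,
                           nEvents = 20000, frequencyNoise = 0.7,
                           eventData = TRUE, beadFraction = 0.03,
                           doubletRate = 0.02, deadFraction = 0.03) {
  if (!identical(profile, "bmt"))
    stop("unknown cohort profile '", profile, "'; available: bmt",
         call. = FALSE)
  if (is.null(groupAssignment))
    groupAssignment <- .defaultBmtCohort(nSamples)
  if (nrow(groupAssignment) != nSamples)
    stop("groupAssignment must cover all samples", call. = FALSE)
  med <- .BMT_MEDIAN_PCT / 100
  if (!is.null(effectTable) && nrow(effectTable)) {
    bad <- setdiff(effectTable$population, names(med))
    if (length(bad))
      stop("unknown population in effect table: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  templates <- populationTemplates("bmt")
  tnames <- vapply(templates, `[[`, character(1), "name")
  freqs <- matrix(NA_real_, nrow = length(tnames), ncol = nSamples,
                  dimnames = list(tnames, groupAssignment$sample_id))
  for (s in seq_len(nSamples)) {
    m <- med
    g <- groupAssignment$group[s]
    if (!is.null(effectTable) && nrow(effectTable)) {
      hit <- effectTable$group == g
      m[effectTable$population[hit]] <- effectTable$median_pct[hit] / 100
    }
    f <- stats::plogis(stats::qlogis(m) + rnorm(length(m), 0, frequencyNoise))
    if (sum(f) > 0.98) f <- f * 0.98 / sum(f)
    f[.BMT_FILLER] <- 1 - sum(f)
    freqs[, s] <- f[tnames]
  }
  sampleSeeds <- sample.int(.Machine$integer.max, nSamples)
  samples <- vector("list", nSamples)
  if (eventData) {
    for (s in seq_len(nSamples)) {
      tmpl <- templates
      for (k in seq_along(tmpl)) tmpl[[k]]$frequency <- freqs[tnames[k], s]
      cfg <- simConfig(nEvents = nEvents, seed = sampleSeeds[s],
                       templates = tmpl, beadFraction = beadFraction,
                       doubletRate = doubletRate,
                       deadFraction = deadFraction,
                       name = groupAssignment$sample_id[s])
      samples[[s]] <- simulateSample(cfg)
    }
  }
  list(samples = samples, metadata = groupAssignment, trueFreq = freqs)
}

# 15 donors, 3 with GvHD (two time points each); 28 samples by default.
# GvHD donors are interleaved so truncated cohorts keep both groups.
.defaultBmtCohort <- function(nSamples = 28) {
  donors <- sprintf("D%02d", c(1, 4, 5, 2, 6, 7, 3, 8:15))
  group <- ifelse(donors %in% c("D01", "D02", "D03"), "GvHD", "noGvHD")
  rows <- data.frame(donor = rep(donors, each = 2),
                     time_point = rep(c("t1", "t2"), 15),
                     group = rep(group, each = 2), stringsAsFactors = FALSE)
  if (nSamples == 28) # drop the later time point of two non-GvHD donors
    rows <- rows[-c(28, 30), , drop = FALSE]
  else
    rows <- rows[seq_len(min(nSamples, nrow(rows))), , drop = FALSE]
  rows$sample_id <- paste0(rows$donor, "_", rows$time_point)
  rownames(rows) <- NULL
  rows[, c("sample_id", "donor", "time_point", "group")]
}

#' Simulate a barcoded pool of samples
#'
#' Each sample's events carry its k-of-n palladium barcode pattern (code
#' channels high, the rest low); a configurable fraction of cross-sample
#' doublets carries the union pattern of two random samples.
#'
#' @param configs list of \code{\link{simConfig}} objects (one per sample;
#'   names become sample labels).
#' @param scheme named list: sample name -> character vector of barcode
#'   metals (the "on" channels); all codes must use the same number of
#'   channels and be pairwise distinct with Hamming distance >= 2.
#' @param metals the full set of barcode channel metals (default six Pd
#'   isotopes).
#' @param doubletFraction fraction of pooled events replaced by
#'   cross-sample doublets.
#' @param seed integer seed for pooling.
#' @param panel an \linkS4class{AntibodyPanel}.
#' @return as \code{\link{simulateSample}}; \code{truth$sample} holds the
#'   originating sample (or \code{"doublet"}).
#' @export
simulateBarcodedPool <- function(configs, scheme,
                                 metals = c("102Pd", "104Pd", "105Pd",
                                            "106Pd", "108Pd", "110Pd"),
                                 doubletFraction = 0, seed = 1,
                                 panel = referencePanel()) {
  if (is.null(names(scheme)) || anyDuplicated(names(scheme)))
    stop("scheme must be a uniquely named list of codes", call. = FALSE)
  k <- unique(lengths(scheme))
  if (length(k) != 1L)
    stop("all codes must use the same number of channels", call. = FALSE)
  codes <- lapply(scheme, sort)
  for (i in seq_along(codes)) {
    bad <- setdiff(codes[[i]], metals)
    if (length(bad))
      stop("code channel not in barcode metals: ", bad[1], call. = FALSE)
    for (j in seq_len(i - 1L)) {
      hd <- length(setdiff(codes[[i]], codes[[j]])) +
        length(setdiff(codes[[j]], codes[[i]]))
      if (hd == 0L)
        stop("duplicate barcode codes: ", names(codes)[i], " and ",
             names(codes)[j], call. = FALSE)
      if (hd < 2L)
        stop("codes must be pairwise Hamming distance >= 2", call. = FALSE)
    }
  }
  if (length(configs) != length(scheme))
    stop("one config per scheme entry is required", call. = FALSE)
  parts <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cfg$name <- names(scheme)[i]
    cfg$barcode <- scheme[[i]]
    attr(cfg, "bcMetals") <- metals
    parts[[i]] <- simulateSample(cfg, panel)
  }
  set.seed(seed)
  raw <- do.call(rbind, lapply(parts, function(p) p$matrix@exprs))
  truth <- do.call(rbind, lapply(parts, function(p) p$truth))
  n <- nrow(raw)
  meta <- parts[[1]]$matrix@channelMeta
  timeCol <- meta$name[meta$class == "time"]
  lenCol <- meta$name[meta$class == "length"]
  massCols <- setdiff(meta$name, c(timeCol, lenCol))
  nD <- rbinom(1, n, doubletFraction)
  if (nD && length(parts) >= 2) {
    sampleOf <- truth$sample
    tgt <- sample.int(n, nD)
    for (r in tgt) {
      other <- sample(which(sampleOf != sampleOf[r]), 1)
      raw[r, massCols] <- raw[r, massCols] + raw[other, massCols]
      raw[r, lenCol] <- 0.8 * (raw[r, lenCol] + raw[other, lenCol])
      truth$sample[r] <- "doublet"
      truth$doublet[r] <- TRUE
    }
  }
  ord <- sample.int(n)
  raw <- raw[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  tm <- sort(runif(n, 0, max(vapply(configs, `[[`, numeric(1), "duration"))))
  raw[, timeCol] <- tm
  em <- new("EventMatrix", exprs = raw, channelMeta = meta, time = tm,
            scale = "raw", scaleFactors = numeric(0))
  list(matrix = em, truth = truth,
       trueFreq = NULL, scheme = scheme)
}
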