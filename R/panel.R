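# Packaged reference panel and lineage-definition tables.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "CytoMonitor")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged data file '", file, "' is missing or corrupted; ",
         "reinstall the package", call. = FALSE)
  path
}

# "89Y" -> list(mass = 89, symbol = "Y"); used for FCS channel naming
.parseMetal <- function(metal) {
  m <- regmatches(metal, regexec("^([0-9]+)([A-Za-z]+)$", metal))
  lapply(m, function(x) {
    if (length(x) != 3L) stop("malformed metal label: ", metal, call. = FALSE)
    list(mass = as.integer(x[2]), symbol = x[3])
  })
}

#' FCS short channel name for a metal label
#'
#' Converts a metal label such as \code{"89Y"} to the vendor-style FCS
#' \code{$PnN} name \code{"Y89Di"}.
#'
#' @param metal character vector of metal labels (mass + element symbol).
#' @return character vector of channel names.
#' @export
metalChannelName <- function(metal) {
  vapply(.parseMetal(metal), function(p)
    sprintf("%s%dDi", p$symbol, p$mass), character(1))
}

#' Load the packaged 33-antibody reference panel
#'
#' Returns the reference immune-monitoring panel: 33 antibody channels
#' covering the major immune lineages, established subsets, activation and
#' checkpoint molecules, plus the auxiliary non-antibody channels (DNA
#' intercalators on 191Ir/193Ir, cisplatin viability on 194Pt/195Pt, event
#' length, acquisition time, and the bead-exclusive 140Ce calibration
#' channel).
#'
#' @return an \linkS4class{AntibodyPanel}.
#' @examples
#' p <- referencePanel()
#' nrow(panelChannels(p))  # 33
#' @export
referencePanel <- function() {
  ch <- read.delim(.extdata("reference_panel.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  aux <- read.delim(.extdata("auxiliary_channels.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  aux$metal <- as.character(aux$metal)
  aux$metal[aux$metal %in% c("NA", "")] <- NA_character_
  if (nrow(ch) != 33L)
    stop("corrupted reference panel: expected 33 antibody channels, found ",
         nrow(ch), call. = FALSE)
  p <- new("AntibodyPanel", name = "reference_33",
           channels = ch[, c("metal", "antigen", "clone", "category",
                             "compartment")],
           auxiliary = aux)
  validObject(p)
  p
}

#' Load a packaged lineage-definition profile
#'
#' @param profile one of \code{"pbmc_core"} (major PBMC lineages and
#'   subsets) or \code{"bmt_subsets"} (extended post-transplant set with
#'   at least 30 leaf subsets, including HLA-DR-CD16+ cells).
#' @return a \linkS4class{LineageTable}.
#' @export
lineageTable <- function(profile = c("pbmc_core", "bmt_subsets")) {
  available <- c("pbmc_core", "bmt_subsets")
  if (!is.character(profile) || !profile[1] %in% available)
    stop("unknown lineage profile '", profile[1], "'; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  profile <- profile[1]
  readLineageTable(.extdata(sprintf("lineages_%s.yaml", profile)))
}

#' Read / write lineage tables as YAML
#'
#' Lineage tables round-trip through a human-editable YAML dialect: a
#' \code{profile} name and a \code{populations} list with \code{name},
#' \code{parent} and named \code{positive}/\code{negative} level maps.
#'
#' @param path file path.
#' @return \code{readLineageTable}: a \linkS4class{LineageTable}.
#' @export
readLineageTable <- function(path) {
  y <- yaml::read_yaml(path)
  pops <- y$populations
  defs <- data.frame(
    name = vapply(pops, `[[`, character(1), "name"),
    parent = vapply(pops, function(p)
      if (is.null(p$parent)) NA_character_ else p$parent, character(1)),
    stringsAsFactors = FALSE)
  lev <- function(p, key, ok) {
    x <- p[[key]]
    if (is.null(x)) return(character(0))
    x <- unlist(x)
    bad <- setdiff(x, ok)
    if (length(bad))
      stop("invalid level '", bad[1], "' in definition of ", p$name,
           call. = FALSE)
    x
  }
  defs$positive <- lapply(pops, lev, "positive", c("pos", "high"))
  defs$negative <- lapply(pops, lev, "negative", c("neg", "low"))
  defs$ignored <- lapply(pops, function(p)
    if (is.null(p$ignored)) character(0) else unlist(p$ignored))
  lt <- new("LineageTable", profile = as.character(y$profile),
            definitions = defs)
  validObject(lt)
  lt
}

#' @rdname readLineageTable
#' @param lineages a \linkS4class{LineageTable} to serialize.
#' @export
writeLineageTable <- function(lineages, path) {
  d <- lineages@definitions
  pops <- lapply(seq_len(nrow(d)), function(i) {
    p <- list(name = d$name[i],
              parent = if (is.na(d$parent[i])) NULL else d$parent[i])
    if (length(d$positive[[i]])) p$positive <- as.list(d$positive[[i]])
    if (length(d$negative[[i]])) p$negative <- as.list(d$negative[[i]])
    if (length(d$ignored[[i]])) p$ignored <- as.list(d$ignored[[i]])
    p
  })
  yaml::write_yaml(list(profile = lineages@profile, populations = pops), path)
  invisible(path)
}

#' Read / write a panel as YAML
#'
#' @param panel an \linkS4class{AntibodyPanel}.
#' @param path file path.
#' @export
writePanel <- function(panel, path) {
  yaml::write_yaml(list(
    name = panel@name,
    channels = lapply(seq_len(nrow(panel@channels)), function(i)
      as.list(panel@channels[i, ])),
    auxiliary = lapply(seq_len(nrow(panel@auxiliary)), function(i) {
      a <- as.list(panel@auxiliary[i, ])
      if (is.na(a$metal)) a$metal <- NULL
      a
    })), path)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  y <- yaml::read_yaml(path)
  ch <- do.call(rbind, lapply(y$channels, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  aux <- do.call(rbind, lapply(y$auxiliary, function(x) {
    if (is.null(x$metal)) x$metal <- NA_character_
    data.frame(x[c("metal", "name", "role")], stringsAsFactors = FALSE)
  }))
  p <- new("AntibodyPanel", name = y$name, channels = ch, auxiliary = aux)
  validObject(p)
  p
}

# depth of each definition in the tree (root = 0) and children in order
.lineageIndex <- function(lineages) {
  d <- lineages@definitions
  depth <- setNames(rep(NA_integer_, nrow(d)), d$name)
  depth[is.na(d$parent)] <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    prog <- FALSE
    for (i in todo) {
      pd <- depth[d$parent[i]]
      if (!is.na(pd)) { depth[d$name[i]] <- pd + 1L; prog <- TRUE }
    }
    if (!prog) stop("lineage table contains a cycle", call. = FALSE)
  }
  children <- lapply(setNames(d$name, d$name), function(nm)
    d$name[!is.na(d$parent) & d$parent == nm])
  list(depth = depth, children = children,
       parent = setNames(d$parent, d$name))
}

# all ancestors of a node, closest first (excluding the node itself)
.ancestors <- function(name, parent) {
  out <- character(0)
  p <- parent[[name]]
  while (!is.na(p)) { out <- c(out, p); p <- parent[[p]] }
  out
}

#' Validate a panel against a set of lineage definitions
#'
#' Checks the structural invariants of panel and lineage table and the
#' mutual consistency of the two: unique metals and antigens, known
#' categories, every referenced antigen present in the panel, tree-shaped
#' definitions, and separability of every pair of siblings by at least one
#' (antigen, sign) clause.  Violations are returned as data, not raised.
#'
#' @param panel an \linkS4class{AntibodyPanel}.
#' @param lineages a \linkS4class{LineageTable} (optional).
#' @return data.frame of violations with columns \code{rule},
#'   \code{subject}, \code{message}; zero rows when everything holds.
#' @export
validatePanel <- function(panel, lineages = NULL) {
  v <- list()
  add <- function(rule, subject, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, subject = subject,
                                       message = message)
  ch <- panel@channels
  dup <- ch$metal[duplicated(ch$metal)]
  for (m in unique(dup))
    add("metal_unique", m, paste("metal", m, "used by multiple antibodies"))
  dup <- ch$antigen[duplicated(ch$antigen)]
  for (a in unique(dup))
    add("antigen_unique", a, paste("antigen", a, "duplicated in panel"))
  bad <- which(!ch$category %in%
               c("lineage", "subset", "activation", "checkpoint", "exclusion") |
               !nzchar(ch$category))
  for (i in bad) add("category", ch$antigen[i], "invalid or empty category")
  overlap <- intersect(stats::na.omit(panel@auxiliary$metal), ch$metal)
  for (m in overlap)
    add("aux_disjoint", m, "auxiliary channel collides with antibody metal")
  if (!is.null(lineages)) {
    d <- lineages@definitions
    refd <- unique(unlist(c(lapply(d$positive, names),
                            lapply(d$negative, names))))
    for (a in setdiff(refd, ch$antigen))
      add("unknown_antigen", a, paste("lineage references antigen", a,
                                      "not in panel"))
    idx <- tryCatch(.lineageIndex(lineages), error = function(e) NULL)
    if (is.null(idx)) {
      add("tree", lineages@profile, "definitions do not form a tree")
    } else {
      sig <- function(i) {
        pos <- d$positive[[i]]; neg <- d$negative[[i]]
        c(paste0(names(pos), "+", pos), paste0(names(neg), "-", neg))
      }
      for (nm in names(idx$children)) {
        kids <- idx$children[[nm]]
        if (length(kids) < 2) next
        for (a in seq_along(kids)) for (b in seq_len(a - 1L)) {
          ia <- match(kids[a], d$name); ib <- match(kids[b], d$name)
          if (!length(setdiff(sig(ia), sig(ib))) &&
              !length(setdiff(sig(ib), sig(ia))))
            add("sibling_separability", paste(kids[a], "/", kids[b]),
                "sibling definitions do not differ in any (antigen, sign) pair")
        }
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(0), subject = character(0),
               message = character(0))
}

# channel metadata data.frame for a panel (the EventMatrix channelMeta);
# barcodeMetals adds palladium barcode columns when pooling samples
.panelChannelMeta <- function(panel, barcodeMetals = NULL) {
  ch <- panel@channels
  aux <- panel@auxiliary
  auxNames <- aux$name
  auxNames[!is.na(aux$metal)] <- metalChannelName(aux$metal[!is.na(aux$metal)])
  meta <- rbind(
    data.frame(name = auxNames,
               desc = aux$name, metal = aux$metal,
               antigen = NA_character_, class = aux$role,
               stringsAsFactors = FALSE),
    data.frame(name = metalChannelName(ch$metal),
               desc = paste0(ch$metal, "_", ch$antigen),
               metal = ch$metal, antigen = ch$antigen, class = "antibody",
               stringsAsFactors = FALSE))
  if (!is.null(barcodeMetals))
    meta <- rbind(meta, data.frame(
      name = metalChannelName(barcodeMetals),
      desc = paste0("BC_", barcodeMetals), metal = barcodeMetals,
      antigen = NA_character_, class = "barcode", stringsAsFactors = FALSE))
  rownames(meta) <- NULL
  meta
}

# column indices helpers
.chanIdx <- function(meta, class) which(meta$class %in% class)
.antigenCols <- function(object) {
  meta <- object@channelMeta
  setNames(which(meta$class == "antibody"),
           meta$antigen[meta$class == "antibody"])
}
# metals that light up on EQ calibration beads (Ce140 + the four shared
# lanthanide channels)
.EQ_BEAD_METALS <- c("140Ce", "151Eu", "153Eu", "165Ho", "175Lu")
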