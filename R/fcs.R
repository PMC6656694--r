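# Minimal FCS 3.0/3.1 reader and FCS 3.1 writer.
#
# Dialect: list mode, a single DATA segment, little-endian float32 on
# write; on read, float32/float64 in either byte order are accepted.
# Delimiter escaping inside TEXT values is not supported (none of the
# keywords written here need it).

.fcsChannelClass <- function(name, desc) {
  lower <- tolower(name)
  if (lower == "time") return("time")
  if (grepl("length", lower)) return("length")
  m <- regmatches(name, regexec("^([A-Za-z]+)([0-9]+)Di$", name))[[1]]
  if (length(m) == 3L) {
    sym <- m[2]
    if (sym == "Ir") return("dna")
    if (sym == "Pt") return("viability")
    if (sym == "Ce") return("bead")
    if (sym == "Pd") return("barcode")
    return("antibody")
  }
  "antibody"
}

.fcsMetal <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z]+)([0-9]+)Di$", name))[[1]]
  if (length(m) == 3L) paste0(m[3], m[2]) else NA_character_
}

#' Read an FCS file
#'
#' Reads an FCS 3.0/3.1 list-mode file into an \linkS4class{EventMatrix}
#' on the raw scale.  Metal and antigen assignments are parsed from
#' \code{$PnN}/\code{$PnS} where they follow the vendor
#' \code{<Symbol><mass>Di} / \code{<mass><Symbol>_<antigen>} convention.
#' A Time channel, if present, populates the acquisition-time slot
#' (events are ordered by it); otherwise time is the 0-based event index.
#'
#' @param path path to an FCS file.
#' @return an \linkS4class{EventMatrix} with \code{scale = "raw"}.
#' @export
readFCS <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", trimws(substr(header, 1, 10)),
         "' in ", path, call. = FALSE)
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  textBeg <- off(11, 18); textEnd <- off(19, 26)
  dataBeg <- off(27, 34); dataEnd <- off(35, 42)
  seek(con, textBeg)
  txt <- rawToChar(readBin(con, "raw", textEnd - textBeg + 1))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- setNames(as.list(parts[c(FALSE, TRUE)]), trimws(parts[c(TRUE, FALSE)]))
  par <- as.integer(kw[["$PAR"]])
  tot <- as.integer(kw[["$TOT"]])
  if (is.na(par) || is.na(tot))
    stop("FCS file lacks $PAR/$TOT keywords", call. = FALSE)
  names_ <- vapply(seq_len(par), function(i) {
    v <- kw[[sprintf("$P%dN", i)]]
    if (is.null(v)) stop("$PAR mismatch: missing $P", i, "N", call. = FALSE)
    v
  }, character(1))
  descs <- vapply(seq_len(par), function(i) {
    v <- kw[[sprintf("$P%dS", i)]]
    if (is.null(v)) names_[i] else v
  }, character(1))
  dtype <- kw[["$DATATYPE"]]
  if (!dtype %in% c("F", "D"))
    stop("unsupported $DATATYPE '", dtype, "' (need F or D)", call. = FALSE)
  byteord <- kw[["$BYTEORD"]]
  endian <- if (identical(byteord, "4,3,2,1") ||
                identical(byteord, "8,7,6,5,4,3,2,1")) "big" else "little"
  size <- if (dtype == "F") 4L else 8L
  if (dataBeg == 0) { dataBeg <- as.numeric(kw[["$BEGINDATA"]]);
                      dataEnd <- as.numeric(kw[["$ENDDATA"]]) }
  vals <- numeric(0)
  if (tot > 0L) {
    seek(con, dataBeg)
    nvals <- par * tot
    expect <- nvals * size
    if (dataEnd - dataBeg + 1 < expect)
      stop("truncated DATA segment: expected ", expect, " bytes, segment has ",
           dataEnd - dataBeg + 1, call. = FALSE)
    vals <- readBin(con, "numeric", n = nvals, size = size, endian = endian)
    if (length(vals) < nvals)
      stop("truncated DATA segment in ", path, call. = FALSE)
  }
  x <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE,
              dimnames = list(NULL, names_))
  meta <- data.frame(
    name = names_, desc = descs,
    metal = vapply(names_, .fcsMetal, character(1)),
    antigen = NA_character_,
    class = vapply(names_, .fcsChannelClass, character(1)),
    stringsAsFactors = FALSE)
  ab <- meta$class == "antibody"
  meta$antigen[ab] <- ifelse(
    grepl("^[0-9]+[A-Za-z]+_", meta$desc[ab]),
    sub("^[0-9]+[A-Za-z]+_", "", meta$desc[ab]), meta$desc[ab])
  rownames(meta) <- NULL
  ti <- which(meta$class == "time")
  if (length(ti) == 1L && tot > 0L) {
    tm <- x[, ti]
    if (is.unsorted(tm)) {
      o <- order(tm)
      x <- x[o, , drop = FALSE]
      tm <- tm[o]
    }
  } else tm <- if (tot > 0L) as.numeric(seq_len(tot) - 1L) else numeric(0)
  new("EventMatrix", exprs = x, channelMeta = meta, time = tm,
      scale = "raw", scaleFactors = numeric(0))
}

#' Write an FCS 3.1 file
#'
#' Writes a raw-scale \linkS4class{EventMatrix} as FCS 3.1 (list mode,
#' single DATA segment, little-endian float32, \code{$PnN}/\code{$PnS}
#' from the channel metadata).  Transformed matrices are refused so that
#' arcsinh-scale values never masquerade as instrument output.
#'
#' @param matrix an \linkS4class{EventMatrix} with \code{scale = "raw"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFCS <- function(matrix, path) {
  stopifnot(is(matrix, "EventMatrix"))
  if (matrix@scale != "raw")
    stop("writeFCS only writes raw-scale matrices (got scale '",
         matrix@scale, "'); transformed data must not masquerade as ",
         "instrument output", call. = FALSE)
  x <- matrix@exprs
  meta <- matrix@channelMeta
  par <- ncol(x); tot <- nrow(x)
  d <- "/"
  kwPairs <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
    "$NEXTDATA", "0", "$MODE", "L", "$DATATYPE", "F",
    "$BYTEORD", "1,2,3,4",
    "$TOT", as.character(tot), "$PAR", as.character(par))
  for (i in seq_len(par)) {
    rng <- max(1, 2^ceiling(log2(max(1, max(x[, i], 0)))))
    kwPairs <- c(kwPairs,
                 sprintf("$P%dN", i), meta$name[i],
                 sprintf("$P%dS", i), meta$desc[i],
                 sprintf("$P%dB", i), "32",
                 sprintf("$P%dE", i), "0,0",
                 sprintf("$P%dR", i), format(rng, scientific = FALSE))
  }
  mkText <- function(bd, ed) {
    p <- kwPairs
    p[p == "%BD%"] <- sprintf("%012.0f", bd)
    p[p == "%ED%"] <- sprintf("%012.0f", ed)
    paste0(d, paste0(p, collapse = d), d)
  }
  headerLen <- 58
  textLen <- nchar(mkText(0, 0))  # fixed width: offsets are zero-padded
  dataBeg <- headerLen + textLen
  dataLen <- 4 * par * tot
  dataEnd <- if (dataLen > 0) dataBeg + dataLen - 1 else 0
  if (dataLen == 0) dataBeg0 <- 0 else dataBeg0 <- dataBeg
  txt <- mkText(dataBeg0, dataEnd)
  textBeg <- headerLen
  textEnd <- textBeg + nchar(txt) - 1
  fits <- function(v) v <= 99999999
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                 textBeg, textEnd,
                 if (dataLen > 0 && fits(dataEnd)) dataBeg else 0,
                 if (dataLen > 0 && fits(dataEnd)) dataEnd else 0,
                 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(txt), con)
  if (tot > 0)
    writeBin(as.vector(t(x)), con, size = 4L, endian = "little")
  invisible(path)
}
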