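#' @include chromatogram-class.R
NULL

# ---- ABIF (AB1) binary container -------------------------------------------
#
# Minimal reader/writer for the ABIF directory format used by capillary
# sequencers. Only the tags the pipeline needs are handled:
#   DATA 9-12  analyzed trace arrays (int16), in filter-wheel dye order
#   FWO_ 1     filter-wheel order: which base each DATA channel carries
#   PLOC 1     0-based sample index of each called base's peak (int16)
#   PBAS 1     called bases (char)
# All integers are big-endian. Directory entries are 28 bytes; payloads of
# 4 bytes or fewer are stored inline in the entry's offset field.

ABIF_HEADER_LEN <- 128L

abifReadEntry <- function(raw, at) {
    # at: 0-based byte offset of a 28-byte directory entry
    nm <- rawToChar(raw[(at + 1L):(at + 4L)])
    con <- rawConnection(raw[(at + 5L):(at + 28L)])
    on.exit(close(con))
    list(name = nm,
         number = readBin(con, "integer", 1, 4, endian = "big"),
         type = readBin(con, "integer", 1, 2, endian = "big"),
         elemsize = readBin(con, "integer", 1, 2, endian = "big"),
         nelem = readBin(con, "integer", 1, 4, endian = "big"),
         datasize = readBin(con, "integer", 1, 4, endian = "big"),
         offsetraw = {
             x <- readBin(con, "raw", 8)
             x[1:4]
         })
}

abifPayload <- function(raw, entry) {
    if (entry$datasize <= 4L) {
        entry$offsetraw[seq_len(entry$datasize)]
    } else {
        con <- rawConnection(entry$offsetraw)
        off <- readBin(con, "integer", 1, 4, endian = "big")
        close(con)
        raw[(off + 1L):(off + entry$datasize)]
    }
}

abifDecode <- function(bytes, type, nelem) {
    if (type == 4L) {          # int16
        readBin(bytes, "integer", nelem, 2, signed = TRUE, endian = "big")
    } else if (type == 2L) {   # char
        rawToChar(bytes)
    } else if (type == 1L) {   # uint8
        as.integer(bytes)
    } else if (type == 5L) {   # int32
        readBin(bytes, "integer", nelem, 4, endian = "big")
    } else {
        stop("unsupported ABIF element type: ", type)
    }
}

#' Read an AB1/ABIF chromatogram
#'
#' Parses the analyzed trace arrays, the base-call peak locations and the
#' called sequence from an ABIF container. The four trace channels are
#' assigned to bases through the filter-wheel-order tag (`FWO_`), never by
#' position, so files differing only in dye order parse identically.
#'
#' @param path path to an AB1/ABIF file.
#' @return a [Chromatogram]. Peak times are converted to 1-based sample
#'   indices.
#' @seealso [writeTrace()] for the round-trip writer, [readTrace()] for
#'   format sniffing.
#' @export
readABIF <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- readBin(path, "raw", file.size(path))
    if (length(raw) < ABIF_HEADER_LEN || rawToChar(raw[1:4]) != "ABIF")
        stop("not an ABIF file (bad magic): ", path)
    tdir <- abifReadEntry(raw, 6L)
    con <- rawConnection(tdir$offsetraw)
    dirOff <- readBin(con, "integer", 1, 4, endian = "big")
    close(con)
    if (dirOff + 28L * tdir$nelem > length(raw))
        stop("truncated ABIF file: directory extends past end of file")
    entries <- lapply(seq_len(tdir$nelem) - 1L,
                      function(i) abifReadEntry(raw, dirOff + 28L * i))
    names(entries) <- vapply(entries, function(e)
        paste0(e$name, ".", e$number), "")

    need <- function(tag) {
        e <- entries[[tag]]
        if (is.null(e))
            stop("malformed ABIF: missing required tag ", tag)
        abifDecode(abifPayload(raw, e), e$type, e$nelem)
    }
    fwo <- strsplit(need("FWO_.1"), "")[[1]]
    if (length(fwo) != 4L || !setequal(fwo, BASES))
        stop("malformed ABIF: FWO_ tag is not a permutation of GATC")
    traces <- lapply(9:12, function(k) need(paste0("DATA.", k)))
    if (length(unique(lengths(traces))) != 1L)
        stop("malformed ABIF: trace channels differ in length")
    ch <- matrix(0, nrow = length(traces[[1]]), ncol = 4,
                 dimnames = list(NULL, BASES))
    for (k in 1:4) ch[, fwo[k]] <- traces[[k]]
    if (is.null(entries[["PLOC.1"]]))
        stop("missing peak-location tag PLOC: ",
             "peak calling from raw traces is not supported")
    ploc <- need("PLOC.1")
    bas <- if (!is.null(entries[["PBAS.1"]])) need("PBAS.1") else ""
    Chromatogram(ch, peakTimes = ploc + 1L, basecalls = bas,
                 sampleId = sub("\\.ab1$", "", basename(path)))
}

abifEntryBytes <- function(name, number, type, elemsize, nelem, payload,
                           blockOffset) {
    # returns list(entry = 28 raw bytes, block = raw payload or NULL)
    datasize <- length(payload)
    con <- rawConnection(raw(0), "r+")
    writeBin(charToRaw(name), con)
    writeBin(as.integer(c(number)), con, size = 4, endian = "big")
    writeBin(as.integer(c(type, elemsize)), con, size = 2, endian = "big")
    writeBin(as.integer(c(nelem, datasize)), con, size = 4, endian = "big")
    if (datasize <= 4L) {
        writeBin(c(payload, raw(4L - datasize)), con)
        block <- NULL
    } else {
        writeBin(as.integer(blockOffset), con, size = 4, endian = "big")
        block <- payload
    }
    writeBin(as.integer(0), con, size = 4, endian = "big")  # datahandle
    out <- rawConnectionValue(con)
    close(con)
    list(entry = out, block = block)
}

int16Bytes <- function(x) {
    if (any(x < -32768 | x > 32767))
        stop("amplitude exceeds ABIF int16 range")
    writeBin(as.integer(x), raw(), size = 2, endian = "big")
}

writeABIF <- function(cg, path, dyeOrder = "GATC") {
    fwo <- strsplit(dyeOrder, "")[[1]]
    stopifnot(setequal(fwo, BASES))
    ch <- round(channels(cg))
    pt <- peakTimes(cg)
    specs <- list()
    for (k in 1:4)
        specs[[length(specs) + 1L]] <- list(
            name = "DATA", number = 8L + k, type = 4L, elemsize = 2L,
            nelem = nrow(ch), payload = int16Bytes(ch[, fwo[k]]))
    specs[[length(specs) + 1L]] <- list(
        name = "FWO_", number = 1L, type = 2L, elemsize = 1L, nelem = 4L,
        payload = charToRaw(dyeOrder))
    specs[[length(specs) + 1L]] <- list(
        name = "PLOC", number = 1L, type = 4L, elemsize = 2L,
        nelem = length(pt), payload = int16Bytes(pt - 1L))
    if (nzchar(basecalls(cg)))
        specs[[length(specs) + 1L]] <- list(
            name = "PBAS", number = 1L, type = 2L, elemsize = 1L,
            nelem = nchar(basecalls(cg)), payload = charToRaw(basecalls(cg)))

    offset <- ABIF_HEADER_LEN
    blocks <- raw(0)
    entryBytes <- raw(0)
    for (s in specs) {
        e <- abifEntryBytes(s$name, s$number, s$type, s$elemsize, s$nelem,
                            s$payload, offset)
        entryBytes <- c(entryBytes, e$entry)
        if (!is.null(e$block)) {
            blocks <- c(blocks, e$block)
            offset <- offset + length(e$block)
        }
    }
    dirOffset <- offset
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("ABIF"), con)
    writeBin(101L, con, size = 2, endian = "big")
    writeBin(charToRaw("tdir"), con)
    writeBin(1L, con, size = 4, endian = "big")
    writeBin(c(1023L, 28L), con, size = 2, endian = "big")
    writeBin(c(length(specs), 28L * length(specs), dirOffset, 0L), con,
             size = 4, endian = "big")
    writeBin(raw(ABIF_HEADER_LEN - 6L - 28L), con)   # pad header to 128
    writeBin(blocks, con)
    writeBin(entryBytes, con)
    invisible(path)
}

# ---- JSON trace dialect ----------------------------------------------------
#
# The simulator's native, lossless plain-text format (schema version 1):
# {"format": "qsanger-trace", "version": 1, "sample_id": ..., "basecalls":
#  ..., "base_offset": ..., "peak_times": [...], "channels": {"G": [...],
#  "A": ..., "T": ..., "C": ...}}. Peak times are 1-based sample indices.

writeTraceJSON <- function(cg, path) {
    obj <- list(format = "qsanger-trace", version = 1L,
                sample_id = sampleId(cg), basecalls = basecalls(cg),
                base_offset = cg@baseOffset,
                peak_times = peakTimes(cg),
                channels = lapply(as.list(BASES), function(b)
                    unname(channels(cg)[, b])))
    names(obj$channels) <- BASES
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

readTraceJSON <- function(path) {
    obj <- jsonlite::fromJSON(path)
    if (!identical(obj$format, "qsanger-trace"))
        stop("not a qsanger trace file: ", path)
    if (!identical(as.integer(obj$version), 1L))
        stop("unsupported trace schema version: ", obj$version)
    ch <- do.call(cbind, obj$channels[BASES])
    colnames(ch) <- BASES
    Chromatogram(ch, peakTimes = obj$peak_times,
                 basecalls = if (is.null(obj$basecalls)) "" else obj$basecalls,
                 sampleId = if (is.null(obj$sample_id)) "" else obj$sample_id,
                 baseOffset = if (is.null(obj$base_offset)) 0L
                              else as.integer(obj$base_offset))
}

#' Write a chromatogram to disk
#'
#' `"json"` writes the package's lossless plain-text trace dialect;
#' `"abif"` writes a minimal ABIF container (trace amplitudes rounded to
#' 16-bit integers, as the format requires).
#'
#' @param cg a [Chromatogram].
#' @param path output path.
#' @param format `"json"` or `"abif"`.
#' @param dyeOrder filter-wheel order string for ABIF output.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(cg, path, format = c("json", "abif"),
                       dyeOrder = "GATC") {
    stopifnot(is(cg, "Chromatogram"))
    validObject(cg)
    switch(match.arg(format),
           json = writeTraceJSON(cg, path),
           abif = writeABIF(cg, path, dyeOrder))
}

#' Read a chromatogram from disk, sniffing the format
#'
#' Dispatches on the file's magic bytes: `ABIF` goes to [readABIF()],
#' anything else is parsed as the JSON trace dialect.
#'
#' @param path input path.
#' @return a [Chromatogram].
#' @export
readTrace <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    magic <- readBin(path, "raw", 4)
    if (length(magic) == 4 && rawToChar(magic) == "ABIF") readABIF(path)
    else readTraceJSON(path)
}

# ---- trimming --------------------------------------------------------------

#' Trim a read to its quality window
#'
#' Discards the first `firstBase` called bases (the leading region is
#' typically low quality and, for the validation constructs, identical
#' between variants) and every call beyond `lastBase` (trace quality decays
#' late in the run). Counting is in called bases of the *original* read:
#' the object records how many leading calls have already been discarded, so
#' trimming is idempotent. Channel samples outside the retained span (plus
#' half a peak spacing of margin) are dropped and peak times re-offset.
#'
#' @param cg a [Chromatogram] with called peaks.
#' @param firstBase,lastBase 0-based base-call index window `[firstBase,
#'   lastBase)` to retain.
#' @return the trimmed [Chromatogram].
#' @examples
#' sp <- simSpec(seed = 1)
#' cg <- simulateTrace(paste(rep("GATC", 30), collapse = ""), sp)
#' length(trimRead(cg, 20, 1000))   # 120 calls -> 100
#' @export
trimRead <- function(cg, firstBase = 20, lastBase = 1000) {
    stopifnot(is(cg, "Chromatogram"))
    if (firstBase >= lastBase) stop("firstBase must be below lastBase")
    pt <- peakTimes(cg)
    n <- length(pt)
    # window in current (already-offset) coordinates
    lo0 <- as.integer(firstBase) - cg@baseOffset    # 0-based, inclusive
    hi0 <- as.integer(lastBase) - cg@baseOffset     # 0-based, exclusive
    lo0 <- max(lo0, 0L)
    hi0 <- min(hi0, n)
    if (hi0 - lo0 < 1L || n <= lo0)
        stop("read too short: fewer than ", firstBase, " called bases")
    keep <- (lo0 + 1L):hi0
    spacing <- if (n > 1L) stats::median(diff(pt)) else 12
    margin <- ceiling(spacing / 2)
    start <- max(1L, as.integer(pt[keep[1]] - margin))
    end <- min(nrow(channels(cg)), as.integer(pt[keep[length(keep)]] + margin))
    bc <- basecalls(cg)
    Chromatogram(channels(cg)[start:end, , drop = FALSE],
                 peakTimes = pt[keep] - start + 1L,
                 basecalls = if (nzchar(bc))
                     substr(bc, keep[1], keep[length(keep)]) else "",
                 sampleId = sampleId(cg),
                 baseOffset = cg@baseOffset + lo0)
}

# ---- FASTA export ----------------------------------------------------------

#' Export called sequences as FASTA
#'
#' With `alphabet = "plain"` the stored base calls are written as-is. With
#' `alphabet = "extended"` peaks are re-called ([callPeaks()]) and two-peak
#' positions encoded as IUPAC two-base ambiguity letters
#' ([encodeExtended()]); the header carries an `alphabet=extended` flag.
#'
#' @param cg a [Chromatogram].
#' @param path output FASTA path.
#' @param alphabet `"plain"` or `"extended"`.
#' @param config a [qsangerConfig()] supplying the secondary-peak thresholds
#'   for extended re-calling.
#' @return `path`, invisibly.
#' @export
exportFasta <- function(cg, path, alphabet = c("plain", "extended"),
                        config = qsangerConfig()) {
    alphabet <- match.arg(alphabet)
    if (alphabet == "plain") {
        s <- basecalls(cg)
        if (!nzchar(s)) stop("chromatogram has no base calls")
        hdr <- sampleId(cg)
    } else {
        calls <- callPeaks(cg, relThreshold = config$relThreshold,
                           absThreshold = config$absThreshold)
        s <- encodeExtended(calls)
        hdr <- paste0(sampleId(cg), " alphabet=extended")
    }
    xs <- Biostrings::DNAStringSet(s)
    names(xs) <- hdr
    Biostrings::writeXStringSet(xs, path)
    invisible(path)
}
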