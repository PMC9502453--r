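## Readers and writers for MSP-style spectral libraries and for the sparse
## binned-intensity matrix. The MSP dialect is deliberately permissive:
## repository exports mix "key: value" and "KEY=value" metadata lines, and
## collision-energy fields are free text ("35", "35 V", "HCD 35%", ...).

.metaKeyMap <- c(
    "db#" = "record_id", "id" = "record_id", "spectrumid" = "record_id",
    "name" = "name", "compoundname" = "name",
    "compoundid" = "compound_id",
    "smiles" = "smiles",
    "inchikey" = "inchikey",
    "instrumenttype" = "instrument_type",
    "ionmode" = "ionisation_mode", "ionizationmode" = "ionisation_mode",
    "ionisationmode" = "ionisation_mode",
    "precursortype" = "precursor_type", "adduct" = "precursor_type",
    "precursormz" = "precursor_mz", "precursormz." = "precursor_mz",
    "mw" = "molecular_weight", "molecularweight" = "molecular_weight",
    "collisionenergy" = "collision_energy", "ce" = "collision_energy")

.normKey <- function(key) gsub("[^a-z#.]", "", tolower(key))

#' Parse a free-text collision-energy field
#'
#' Extracts the numeric value and its unit from strings like \code{"35"},
#' \code{"35 V"}, \code{"35eV"} or \code{"HCD 35\%"}. Percent values are
#' normalised collision energies of HCD-class instruments; plain numbers get
#' unit \code{NA}.
#'
#' @param text character vector of collision-energy strings.
#' @return data.frame with numeric \code{value} and character \code{unit}
#'   (one of \code{"V"}, \code{"eV"}, \code{"\%"} or \code{NA}).
#' @export
parseCollisionEnergy <- function(text) {
    value <- rep(NA_real_, length(text))
    unit <- rep(NA_character_, length(text))
    for (i in seq_along(text)) {
        s <- trimws(text[i])
        if (!nzchar(s) || is.na(text[i])) next
        m <- regmatches(s, regexpr("-?[0-9]+(\\.[0-9]+)?", s))
        if (!length(m)) next
        value[i] <- as.numeric(m)
        rest <- sub("-?[0-9]+(\\.[0-9]+)?", "", s)
        if (grepl("%", rest, fixed = TRUE)) unit[i] <- "%"
        else if (grepl("ev", rest, ignore.case = TRUE)) unit[i] <- "eV"
        else if (grepl("v", rest, ignore.case = TRUE)) unit[i] <- "V"
    }
    data.frame(value = value, unit = unit, stringsAsFactors = FALSE)
}

.normalizeAdduct <- function(x) {
    x <- gsub("[[:space:]]|\\^", "", x)
    x <- gsub("−", "-", x)   # unicode minus
    x
}

.normalizeIonMode <- function(x) {
    x <- tolower(trimws(x))
    out <- rep("unknown", length(x))
    out[x %in% c("p", "positive", "pos", "+")] <- "positive"
    out[x %in% c("n", "negative", "neg", "-")] <- "negative"
    out
}

.emptyMeta <- function(n = 0L) {
    data.frame(
        record_id = character(n), compound_id = rep(NA_character_, n),
        name = rep(NA_character_, n), smiles = rep(NA_character_, n),
        inchikey = rep(NA_character_, n),
        instrument_type = rep(NA_character_, n),
        ionisation_mode = rep("unknown", n),
        precursor_type = rep(NA_character_, n),
        precursor_mz = rep(NA_real_, n),
        molecular_weight = rep(NA_real_, n),
        collision_energy_value = rep(NA_real_, n),
        collision_energy_unit = rep(NA_character_, n),
        stringsAsFactors = FALSE)
}

.recordFromFields <- function(fields, peaks, idx) {
    meta <- .emptyMeta(1L)
    meta$record_id <- if (!is.null(fields$record_id)) fields$record_id else
        sprintf("record_%05d", idx)
    for (col in c("name", "compound_id", "smiles", "inchikey",
                  "instrument_type"))
        if (!is.null(fields[[col]])) meta[[col]] <- fields[[col]]
    if (!is.null(fields$ionisation_mode))
        meta$ionisation_mode <- .normalizeIonMode(fields$ionisation_mode)
    if (!is.null(fields$precursor_type))
        meta$precursor_type <- .normalizeAdduct(fields$precursor_type)
    for (col in c("precursor_mz", "molecular_weight")) {
        if (!is.null(fields[[col]])) {
            v <- suppressWarnings(as.numeric(fields[[col]]))
            if (is.finite(v)) meta[[col]] <- v
        }
    }
    if (!is.null(fields$collision_energy)) {
        ce <- parseCollisionEnergy(fields$collision_energy)
        meta$collision_energy_value <- ce$value
        meta$collision_energy_unit <- ce$unit
    }
    o <- order(peaks[, 1L])
    peaks <- peaks[o, , drop = FALSE]
    colnames(peaks) <- c("mz", "intensity")
    list(meta = meta, peaks = peaks)
}

#' Derive stable compound identifiers
#'
#' Spectra of the same molecule must share one identifier so that grouped
#' splitting can keep them in a single set. The identifier is the InChIKey
#' when present, else the (optionally canonicalised) SMILES, else the
#' compound name lower-cased, else the record id itself.
#'
#' @param meta metadata data.frame with \code{inchikey}, \code{smiles},
#'   \code{name}, \code{record_id} columns.
#' @param canonicalize canonicalise SMILES via OpenBabel before use? Slower
#'   but merges equivalent SMILES spellings.
#' @return character vector of compound ids.
#' @export
deriveCompoundId <- function(meta, canonicalize = TRUE) {
    id <- meta$inchikey
    smi <- meta$smiles
    need <- is.na(id) & !is.na(smi)
    if (any(need) && canonicalize) {
        usmi <- unique(smi[need])
        can <- vapply(usmi, function(s) {
            out <- tryCatch(
                suppressWarnings(ChemmineOB::convertFormat(
                    "SMI", "CAN", paste0(s, "\tx\n"))),
                error = function(e) "")
            out <- sub("\t.*$", "", sub("\n.*$", "", out))
            if (nzchar(out)) out else s
        }, character(1))
        id[need] <- can[match(smi[need], usmi)]
    } else if (any(need)) {
        id[need] <- smi[need]
    }
    need <- is.na(id) & !is.na(meta$name)
    id[need] <- tolower(trimws(meta$name[need]))
    id[is.na(id)] <- meta$record_id[is.na(id)]
    id
}

#' Assemble a SpectrumSet from parts
#'
#' @param meta metadata data.frame (missing standard columns are added as NA).
#' @param peaks list of two-column mz/intensity matrices; rows are sorted by
#'   m/z if needed.
#' @return a \linkS4class{SpectrumSet}.
#' @export
SpectrumSet <- function(meta, peaks) {
    full <- .emptyMeta(nrow(meta))
    for (col in intersect(colnames(meta), .SPECTRUM_META_COLS))
        full[[col]] <- meta[[col]]
    for (col in c("record_id", "compound_id", "name", "smiles", "inchikey",
                  "instrument_type", "precursor_type"))
        full[[col]] <- trimws(as.character(full[[col]]))
    full$ionisation_mode <- ifelse(
        full$ionisation_mode %in% c("positive", "negative"),
        full$ionisation_mode, .normalizeIonMode(full$ionisation_mode))
    peaks <- lapply(peaks, function(p) {
        p <- as.matrix(p)
        storage.mode(p) <- "double"
        colnames(p) <- c("mz", "intensity")
        p[order(p[, 1L]), , drop = FALSE]
    })
    rownames(full) <- NULL
    new("SpectrumSet", meta = full, peaks = peaks)
}

#' Read a spectral library
#'
#' Parses an MSP-style library (\code{dialect = "msp"}: blank-line separated
#' entries, metadata as \code{key: value} or \code{KEY=value}, peak lines as
#' whitespace-separated mz/intensity pairs) or a one-row-per-record tabular
#' file (\code{dialect = "tabular"}, as written by \code{\link{writeSpectra}}).
#' Unparseable fields are stored as missing, never guessed; a malformed entry
#' is skipped with a message rather than aborting the batch. A parse report
#' (record/skip counts and per-field missingness) is attached and retrievable
#' with \code{\link{parseReport}}.
#'
#' @param path file to read.
#' @param dialect \code{"msp"} or \code{"tabular"}.
#' @param canonicalize canonicalise SMILES when deriving compound ids.
#' @return a \linkS4class{SpectrumSet}, in file order.
#' @export
readSpectra <- function(path, dialect = c("msp", "tabular"),
                        canonicalize = TRUE) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("cannot read spectral library: ", path)
    if (dialect == "msp") .readMsp(path, canonicalize)
    else .readTabular(path, canonicalize)
}

.readMsp <- function(path, canonicalize) {
    lines <- readLines(path, warn = FALSE)
    entries <- list()
    skipped <- 0L
    blocks <- list()
    cur <- integer(0)
    for (ln in seq_along(lines)) {
        if (nzchar(trimws(lines[ln]))) cur <- c(cur, ln)
        else if (length(cur)) { blocks[[length(blocks) + 1L]] <- cur; cur <- integer(0) }
    }
    if (length(cur)) blocks[[length(blocks) + 1L]] <- cur

    for (bi in seq_along(blocks)) {
        block <- lines[blocks[[bi]]]
        fields <- list()
        pk <- list()
        bad <- FALSE
        for (line in block) {
            line <- trimws(line)
            if (grepl("^[A-Za-z][^=:]*[:=]", line)) {
                sep <- regexpr("[:=]", line)
                key <- .normKey(substr(line, 1L, sep - 1L))
                val <- trimws(substr(line, sep + 1L, nchar(line)))
                if (key %in% c("numpeaks", "numpeaks.")) next
                std <- .metaKeyMap[key]
                if (!is.na(std) && nzchar(val)) fields[[std]] <- val
            } else {
                parts <- strsplit(line, "[[:space:];]+")[[1]]
                parts <- parts[nzchar(parts)]
                mz <- suppressWarnings(as.numeric(parts[1]))
                it <- suppressWarnings(as.numeric(parts[2]))
                if (length(parts) < 2L || !is.finite(mz) || !is.finite(it)) {
                    bad <- TRUE
                    break
                }
                pk[[length(pk) + 1L]] <- c(mz, it)
            }
        }
        if (bad) {
            skipped <- skipped + 1L
            message(sprintf("skipping malformed entry %d in %s", bi, path))
            next
        }
        peaks <- if (length(pk)) do.call(rbind, pk) else
            matrix(numeric(0), 0L, 2L)
        entries[[length(entries) + 1L]] <-
            .recordFromFields(fields, peaks, length(entries) + 1L)
    }
    .finishRead(entries, skipped, canonicalize)
}

.readTabular <- function(path, canonicalize) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    skipped <- 0L
    entries <- list()
    for (i in seq_len(nrow(df))) {
        ptxt <- df$peaks[i]
        ok <- TRUE
        peaks <- matrix(numeric(0), 0L, 2L)
        if (!is.na(ptxt) && nzchar(ptxt)) {
            pairs <- strsplit(strsplit(ptxt, ";", fixed = TRUE)[[1]], ":",
                              fixed = TRUE)
            vals <- suppressWarnings(lapply(pairs, as.numeric))
            if (any(vapply(vals, function(v)
                length(v) != 2L || any(!is.finite(v)), logical(1)))) ok <- FALSE
            else peaks <- do.call(rbind, vals)
        }
        if (!ok) {
            skipped <- skipped + 1L
            message(sprintf("skipping malformed entry %d in %s", i, path))
            next
        }
        fields <- as.list(df[i, setdiff(colnames(df), "peaks"), drop = FALSE])
        fields <- fields[!vapply(fields, function(v) is.na(v) ||
                                     !nzchar(as.character(v)), logical(1))]
        fields <- lapply(fields, as.character)
        names(fields) <- vapply(names(fields), function(k) {
            std <- .metaKeyMap[.normKey(k)]
            if (is.na(std)) k else std
        }, character(1))
        entries[[length(entries) + 1L]] <-
            .recordFromFields(fields, peaks, length(entries) + 1L)
    }
    .finishRead(entries, skipped, canonicalize)
}

.finishRead <- function(entries, skipped, canonicalize) {
    if (!length(entries)) {
        out <- SpectrumSet(.emptyMeta(0L), list())
    } else {
        meta <- do.call(rbind, lapply(entries, `[[`, "meta"))
        ## derive ids only where the file does not carry them already
        need <- is.na(meta$compound_id)
        if (any(need))
            meta$compound_id[need] <-
                deriveCompoundId(meta[need, , drop = FALSE], canonicalize)
        out <- SpectrumSet(meta, lapply(entries, `[[`, "peaks"))
    }
    missing_tally <- vapply(spectrumMeta(out), function(col)
        sum(is.na(col)), integer(1))
    attr(out, "parseReport") <- list(
        n_records = nSpectra(out), n_skipped = skipped,
        missing_fields = missing_tally)
    out
}

#' Parse report of a read operation
#'
#' @param x a \linkS4class{SpectrumSet} returned by \code{\link{readSpectra}}.
#' @return list with \code{n_records}, \code{n_skipped} and per-field
#'   missing-value tallies, or NULL when the object was built in memory.
#' @export
parseReport <- function(x) attr(x, "parseReport")

#' Write a spectral library
#'
#' \code{dialect = "msp"} writes blank-line separated entries with
#' \code{key: value} metadata and \code{mz intensity} peak lines;
#' \code{"tabular"} writes one row per record with peaks encoded as
#' \code{mz:intensity;...}. Both round-trip through \code{\link{readSpectra}}.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param path output file.
#' @param dialect \code{"msp"} or \code{"tabular"}.
#' @export
writeSpectra <- function(x, path, dialect = c("msp", "tabular")) {
    dialect <- match.arg(dialect)
    meta <- spectrumMeta(x)
    peaks <- peakLists(x)
    if (dialect == "msp") {
        con <- file(path, "w")
        on.exit(close(con))
        for (i in seq_len(nSpectra(x))) {
            m <- meta[i, ]
            wl <- function(key, val) {
                if (length(val) == 1L && !is.na(val) && nzchar(as.character(val)))
                    writeLines(paste0(key, ": ", val), con)
            }
            wl("Name", m$name)
            wl("DB#", m$record_id)
            wl("Compound_id", m$compound_id)
            wl("InChIKey", m$inchikey)
            wl("SMILES", m$smiles)
            wl("Instrument_type", m$instrument_type)
            wl("Ion_mode",
               c(positive = "P", negative = "N")[m$ionisation_mode])
            wl("Precursor_type", m$precursor_type)
            wl("PrecursorMZ", .fmtNum(m$precursor_mz))
            wl("MW", .fmtNum(m$molecular_weight))
            if (!is.na(m$collision_energy_value))
                wl("Collision_energy",
                   paste0(.fmtNum(m$collision_energy_value),
                          if (!is.na(m$collision_energy_unit))
                              paste0(" ", m$collision_energy_unit) else ""))
            writeLines(sprintf("Num Peaks: %d", nrow(peaks[[i]])), con)
            if (nrow(peaks[[i]]))
                writeLines(sprintf("%s %s", .fmtNum(peaks[[i]][, 1L]),
                                   .fmtNum(peaks[[i]][, 2L])), con)
            writeLines("", con)
        }
    } else {
        ptxt <- vapply(peaks, function(p)
            paste(sprintf("%s:%s", .fmtNum(p[, 1L]), .fmtNum(p[, 2L])),
                  collapse = ";"), character(1))
        df <- cbind(meta, peaks = ptxt)
        df$collision_energy <- ifelse(
            is.na(meta$collision_energy_value), NA,
            paste0(.fmtNum(meta$collision_energy_value),
                   ifelse(is.na(meta$collision_energy_unit), "",
                          paste0(" ", meta$collision_energy_unit))))
        df$collision_energy_value <- NULL
        df$collision_energy_unit <- NULL
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

.fmtNum <- function(x) sprintf("%.17g", x)

## ------------------------------------------------- instrument standardisation

.instrumentEnv <- new.env(parent = emptyenv())

.instrumentTable <- function() {
    if (is.null(.instrumentEnv$tab)) {
        f <- system.file("extdata", "instrument_synonyms.tsv",
                         package = "ms2fp", mustWork = TRUE)
        .instrumentEnv$tab <- read.delim(f, stringsAsFactors = FALSE)
    }
    .instrumentEnv$tab
}

#' Standardise instrument-type labels
#'
#' Spectral repositories mix vendor spellings of the same platform (for
#' example \code{"ESI-QFT"} and \code{"LC-ESI-QFT"}). Labels found in the
#' shipped synonym table are replaced by their canonical form; unknown labels
#' pass through unchanged and are flagged in the \code{"flagged"} attribute.
#' The mapping is idempotent: canonical labels map to themselves.
#'
#' @param label character vector of instrument-type labels.
#' @return character vector of canonical labels, with a logical
#'   \code{"flagged"} attribute marking labels absent from the table.
#' @export
standardizeInstrument <- function(label) {
    tab <- .instrumentTable()
    key <- toupper(trimws(label))
    hit <- match(key, toupper(tab$synonym))
    out <- ifelse(is.na(hit), trimws(label), tab$canonical[hit])
    attr(out, "flagged") <- is.na(hit) & !(key %in% toupper(tab$canonical))
    out
}

## ------------------------------------------------------- sparse matrix files

#' Write a sparse matrix to a plain-text triplet file
#'
#' Self-describing tab-separated format: a header, the dimensions, optional
#' bin-grid parameters, row ids, column labels, then one \code{i j value}
#' triplet per stored element printed with 17 significant digits so that
#' \code{readSparseMatrix(writeSparseMatrix(M))} reproduces \code{M}
#' bit-exactly.
#'
#' @param m a \linkS4class{SpectralMatrix}, sparse \code{Matrix} or base
#'   matrix. Values must be finite.
#' @param path output file.
#' @export
writeSparseMatrix <- function(m, path) {
    grid <- NULL
    if (is(m, "SpectralMatrix")) {
        grid <- m@grid
        m <- m@values
    }
    m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                 "generalMatrix"), "TsparseMatrix")
    if (length(m@x) && any(!is.finite(m@x)))
        stop("matrix contains non-finite values")
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write: ", path))
    on.exit(close(con))
    writeLines("%%ms2fp-sparse-matrix 1.0", con)
    writeLines(sprintf("dims\t%d\t%d\t%d", nrow(m), ncol(m), length(m@x)), con)
    if (!is.null(grid))
        writeLines(sprintf("grid\t%s\t%s\t%s", .fmtNum(grid@mzMin),
                           .fmtNum(grid@mzMax), .fmtNum(grid@step)), con)
    rn <- rownames(m)
    if (is.null(rn)) rn <- as.character(seq_len(nrow(m)))
    cn <- colnames(m)
    if (is.null(cn)) cn <- as.character(seq_len(ncol(m)))
    if (nrow(m)) writeLines(paste0("row\t", rn), con)
    if (ncol(m)) writeLines(paste0("col\t", cn), con)
    if (length(m@x))
        writeLines(sprintf("x\t%d\t%d\t%s", m@i + 1L, m@j + 1L,
                           .fmtNum(m@x)), con)
    invisible(path)
}

#' Read a sparse matrix written by \code{\link{writeSparseMatrix}}
#'
#' @param path file to read.
#' @return a \linkS4class{SpectralMatrix} when the file records a bin grid,
#'   otherwise a sparse \code{dgCMatrix}.
#' @export
readSparseMatrix <- function(path) {
    if (!file.exists(path)) stop("cannot read: ", path)
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !startsWith(lines[1], "%%ms2fp-sparse-matrix"))
        stop("not an ms2fp sparse matrix file: ", path)
    tag <- sub("\t.*$", "", lines)
    dims <- as.integer(strsplit(lines[tag == "dims"], "\t")[[1]][-1])
    grid <- NULL
    if (any(tag == "grid")) {
        g <- as.numeric(strsplit(lines[tag == "grid"][1], "\t")[[1]][-1])
        grid <- new("BinGrid", mzMin = g[1], mzMax = g[2], step = g[3])
    }
    rn <- sub("^row\t", "", lines[tag == "row"])
    cn <- sub("^col\t", "", lines[tag == "col"])
    xs <- lines[tag == "x"]
    if (length(xs)) {
        parts <- strsplit(xs, "\t")
        i <- vapply(parts, function(p) as.integer(p[2]), integer(1))
        j <- vapply(parts, function(p) as.integer(p[3]), integer(1))
        v <- vapply(parts, function(p) as.numeric(p[4]), numeric(1))
    } else {
        i <- j <- integer(0)
        v <- numeric(0)
    }
    m <- Matrix::sparseMatrix(i = i, j = j, x = v,
                              dims = c(dims[1], dims[2]),
                              dimnames = list(
                                  if (dims[1]) rn else NULL,
                                  if (dims[2]) cn else NULL))
    m <- methods::as(m, "CsparseMatrix")
    if (!is.null(grid))
        new("SpectralMatrix", values = m, grid = grid)
    else m
}

#' Read a structure table
#'
#' Tab-separated file with columns \code{compound_id} and \code{smiles}.
#'
#' @param path file to read.
#' @return data.frame with \code{compound_id} and \code{smiles}.
#' @export
readStructures <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("compound_id", "smiles") %in% colnames(df)))
        stop("structure table needs compound_id and smiles columns")
    df
}
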