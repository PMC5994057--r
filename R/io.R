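## File formats: TSV matrices (features x samples), annotation tables,
## category sets, tensor assembly.  TSV throughout (genomics convention);
## gzip is handled transparently by R's connection machinery.

#' Read a labelled feature x sample matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' the body must be fully numeric with no missing values (tensor methods
#' require complete data — no imputation is performed).
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return numeric matrix with feature-id rownames and sample-id colnames.
#' @export
readMatrixTSV <- function(path) {
    df <- tryCatch(
        utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE),
        error = function(e) stop("parse error in '", path, "': ",
                                 conditionMessage(e)))
    if (ncol(df) < 2L)
        stop("'", path, "' needs a feature-id column plus >= 1 sample column")
    ids <- as.character(df[[1L]])
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate feature ids in '", path, "': ",
             paste(utils::head(unique(dup), 5), collapse = ", "))
    body <- df[, -1L, drop = FALSE]
    for (j in seq_along(body)) {
        col <- body[[j]]
        if (!is.numeric(col)) {
            bad <- which(is.na(suppressWarnings(as.numeric(col))) &
                         !is.na(col))[1L]
            stop(sprintf("non-numeric cell in '%s': row %d (feature '%s'), column '%s'",
                         path, if (is.na(bad)) NA_integer_ else bad,
                         if (is.na(bad)) "?" else ids[bad],
                         colnames(body)[j]))
        }
        if (anyNA(col)) {
            bad <- which(is.na(col))[1L]
            stop(sprintf("missing value in '%s': row %d (feature '%s'), column '%s'; complete data required",
                         path, bad, ids[bad], colnames(body)[j]))
        }
    }
    M <- as.matrix(body)
    rownames(M) <- ids
    M
}

#' Write a labelled matrix as TSV
#'
#' Numeric values are written with 17 significant digits, so a write/read
#' round trip is bit-exact.
#'
#' @param M numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param path output path (".gz" suffix writes gzip).
#' @param idColumn header of the feature-id column (default "feature_id").
#' @return invisibly, \code{path}.
#' @export
writeMatrixTSV <- function(M, path, idColumn = "feature_id") {
    stopifnot(is.matrix(M))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    rn <- rownames(M) %||% paste0("f", seq_len(nrow(M)))
    cn <- colnames(M) %||% paste0("s", seq_len(ncol(M)))
    writeLines(paste(c(idColumn, cn), collapse = "\t"), con)
    body <- apply(format(M, digits = 17, trim = TRUE, scientific = FALSE),
                  1L, paste, collapse = "\t")
    writeLines(paste(rn, body, sep = "\t"), con)
    invisible(path)
}

#' Assemble an OmicsTensor from per-data-type matrices
#'
#' Stacks >= 2 feature x sample matrices (identical feature-id and
#' sample-id sets) into a (type x sample x feature) tensor.  Unless
#' \code{strictOrder}, rows and columns are reordered to the first
#' matrix's order; with \code{strictOrder} the orders must already match.
#'
#' @param matrices named list of labelled matrices (names become the
#'   mode-1 labels).
#' @param strictOrder require identical id orderings instead of reordering.
#' @return an \linkS4class{OmicsTensor}.
#' @export
assembleTensor <- function(matrices, strictOrder = FALSE) {
    stopifnot(is.list(matrices), length(matrices) >= 2L)
    nms <- names(matrices) %||% paste0("type", seq_along(matrices))
    ref <- matrices[[1L]]
    feats <- rownames(ref)
    samps <- colnames(ref)
    if (is.null(feats) || is.null(samps))
        stop("matrices must carry feature rownames and sample colnames")
    for (t in seq_along(matrices)) {
        M <- matrices[[t]]
        mf <- setdiff(union(rownames(M), feats), intersect(rownames(M), feats))
        ms <- setdiff(union(colnames(M), samps), intersect(colnames(M), samps))
        if (length(mf) || length(ms))
            stop("id sets differ between matrices ('", nms[t], "'): ",
                 paste(utils::head(c(mf, ms), 10), collapse = ", "))
        if (strictOrder &&
            (!identical(rownames(M), feats) || !identical(colnames(M), samps)))
            stop("strictOrder: matrix '", nms[t],
                 "' has a different row/column ordering")
    }
    v <- array(0, c(length(matrices), length(samps), length(feats)))
    for (t in seq_along(matrices))
        v[t, , ] <- t(matrices[[t]][feats, samps, drop = FALSE])
    OmicsTensor(v, nms, samps, feats)
}

#' Read a feature annotation table (TSV or BED)
#'
#' TSV: columns \code{feature_id} and optionally \code{chromosome}.  BED
#' (detected by a \code{.bed} suffix or by \code{format}): standard
#' 0-based half-open \code{chrom start end name}; coordinates are carried
#' through as metadata but unused by the statistics.
#'
#' @param path annotation file.
#' @param format \code{"auto"}, \code{"tsv"} or \code{"bed"}.
#' @return data.frame with columns feature_id, chromosome (and start/end
#'   for BED).
#' @export
readAnnotation <- function(path, format = c("auto", "tsv", "bed")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "tsv"
    if (format == "bed") {
        df <- utils::read.delim(path, header = FALSE,
                                stringsAsFactors = FALSE)
        if (ncol(df) < 4L)
            stop("BED annotation needs >= 4 columns (chrom start end name)")
        data.frame(feature_id = as.character(df[[4L]]),
                   chromosome = as.character(df[[1L]]),
                   start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
                   stringsAsFactors = FALSE)
    } else {
        df <- utils::read.delim(path, header = TRUE,
                                stringsAsFactors = FALSE)
        if (!"feature_id" %in% colnames(df))
            stop("TSV annotation needs a 'feature_id' column")
        df$feature_id <- as.character(df$feature_id)
        df
    }
}

#' Read a category set (one feature id per line)
#' @param path text file, one id per line (blank lines ignored).
#' @return character vector of unique ids.
#' @export
readCategorySet <- function(path) {
    ids <- readLines(path)
    unique(ids[nzchar(trimws(ids))])
}
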