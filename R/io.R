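# File formats: TSV gene tables and presence matrices, BED + JSON
# segmentation reports, two-column profile TSVs, trajectory CSVs.

#' Read an ordered gene table
#'
#' Tab-separated with a header. Required columns: `partition_id`,
#' `gene_order_index` and at least one of `tag` / `cluster_id`. Optional:
#' `gene_id`, `start_bp`, `end_bp`, `strand`. Within each partition the order
#' index must be dense `0..N-1`; when coordinates are present,
#' `start_bp < end_bp` is enforced. A `tag` column is coerced to 0/1.
#'
#' @param path file path.
#'
#' @return a data.frame of class `gene_table`, sorted by partition and order
#'   index.
#' @export
readGeneTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("partition_id", "gene_order_index")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("gene table is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (!any(c("tag", "cluster_id") %in% names(tab)))
        stop("gene table must carry a 'tag' or a 'cluster_id' column")
    tab$gene_order_index <- as.integer(tab$gene_order_index)
    for (p in unique(tab$partition_id)) {
        idx <- sort(tab$gene_order_index[tab$partition_id == p])
        if (anyDuplicated(idx))
            stop("duplicate gene_order_index in partition '", p, "'")
        if (!identical(idx, seq_along(idx) - 1L))
            stop("gene_order_index must be dense 0..N-1 in partition '", p, "'")
    }
    if ("tag" %in% names(tab)) {
        tg <- as.integer(tab$tag)
        if (anyNA(tg) || !all(tg %in% c(0L, 1L)))
            stop("'tag' column must be binary 0/1")
        tab$tag <- tg
    }
    if (all(c("start_bp", "end_bp") %in% names(tab))) {
        tab$start_bp <- as.numeric(tab$start_bp)
        tab$end_bp <- as.numeric(tab$end_bp)
        if (any(!is.na(tab$start_bp) & !is.na(tab$end_bp) &
                tab$start_bp >= tab$end_bp))
            stop("malformed coordinates: start_bp must be < end_bp")
    }
    tab <- tab[order(tab$partition_id, tab$gene_order_index), , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- c("gene_table", "data.frame")
    tab
}

#' Write a gene table
#'
#' @param tab a data.frame as produced by [readGeneTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(tab, path) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Extract one partition's tags as a TaggedChromosome
#'
#' @param tab a gene table with a `tag` column.
#' @param partition partition identifier; defaults to the first.
#' @return a [TaggedChromosome-class].
#' @export
geneTableChromosome <- function(tab, partition = NULL) {
    if (is.null(partition)) partition <- tab$partition_id[1L]
    sub <- tab[tab$partition_id == partition, , drop = FALSE]
    if (nrow(sub) == 0L) stop("partition '", partition, "' not found")
    if (!"tag" %in% names(sub)) stop("gene table has no 'tag' column")
    taggedChromosome(sub$tag[order(sub$gene_order_index)])
}

#' Read a presence matrix
#'
#' Two layouts: `"wide"` — header row of cluster IDs, one row per assembly
#' (first column assembly ID), 0/1 cells; `"long"` — two columns
#' `assembly_id`, `cluster_id`, one row per presence entry. With
#' `format = "auto"` the long layout is detected from the header.
#'
#' @param path file path.
#' @param format `"auto"`, `"wide"` or `"long"`.
#'
#' @return a [PresenceMatrix-class].
#' @export
readPresenceMatrix <- function(path, format = c("auto", "wide", "long")) {
    format <- match.arg(format)
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (format == "auto")
        format <- if (identical(header, c("assembly_id", "cluster_id")))
            "long" else "wide"
    if (format == "long") {
        tab <- utils::read.delim(path, stringsAsFactors = FALSE)
        mat <- table(tab$assembly_id, tab$cluster_id) > 0L
        mat <- matrix(as.logical(mat), nrow = nrow(mat), dimnames = dimnames(mat))
    } else {
        tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                                 check.names = FALSE, row.names = 1L)
        mat <- as.matrix(tab) > 0
    }
    presenceMatrix(mat)
}

#' Write a presence matrix (wide TSV)
#'
#' @param pm a [PresenceMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePresenceMatrix <- function(pm, path) {
    stopifnot(is(pm, "PresenceMatrix"))
    m <- pm@presence * 1L
    out <- data.frame(assembly_id = rownames(m), m, check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write gene-age labels as TSV
#'
#' Columns: gene_id, cluster_id, commonality_fraction, label.
#'
#' @param labels data.frame from [classifyGeneAges()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneAgeLabels <- function(labels, path) {
    utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a segmentation as BED and JSON
#'
#' The JSON report carries `k`, the log-likelihood, BIC, the chi-square
#' uniformity test (when `k >= 2`), the enrichment summary and the segment
#' table (gene-index coordinates). When the gene table supplies bp
#' coordinates, a BED file of segments is written as 0-based half-open bp
#' intervals; a segment wrapping the origin is split into two BED records
#' sharing a name. Without coordinates the BED file is skipped with a
#' warning.
#'
#' @param seg a [Segmentation-class].
#' @param genes optional gene table (one partition) with `start_bp`/`end_bp`.
#' @param bed_path,json_path output paths; `NULL` skips the file.
#' @param partition partition identifier used as the BED chromosome name.
#'
#' @return invisibly, a list with the report and the BED data.frame (or NULL).
#' @export
writeSegments <- function(seg, genes = NULL, bed_path = NULL,
                          json_path = NULL, partition = NULL) {
    stopifnot(is(seg, "Segmentation"))
    st <- segTable(seg)
    report <- list(
        k = nSegments(seg), N = seg@N, M = seg@M,
        logLik = seg@logLik, bic = seg@bic,
        segments = st)
    if (nSegments(seg) >= 2L) {
        ut <- chisqUniformity(seg)
        report$chisq <- list(statistic = ut$statistic, df = ut$df,
                             p_value = ut$p_value)
        report$enrichment <- enrichmentSummary(seg)
    }
    bed <- NULL
    hasCoord <- !is.null(genes) && all(c("start_bp", "end_bp") %in% names(genes))
    if (hasCoord) {
        if (is.null(partition)) partition <- as.character(genes$partition_id[1L])
        genes <- genes[genes$partition_id == partition, , drop = FALSE]
        genes <- genes[order(genes$gene_order_index), , drop = FALSE]
        if (nrow(genes) != seg@N)
            stop("gene table partition and segmentation disagree on gene count")
        rows <- list()
        for (i in seq_len(nrow(st))) {
            g0 <- st$start[i]
            gl <- st$length[i]
            name <- paste0("seg", i, "_", st$class[i])
            score <- max(0L, min(1000L, as.integer(round(1000 * st$density[i]))))
            pieces <- if (g0 + gl <= seg@N) list(c(g0, g0 + gl - 1L))
                      else list(c(g0, seg@N - 1L), c(0L, g0 + gl - seg@N - 1L))
            for (pc in pieces) {
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = partition,
                    start = genes$start_bp[pc[1L] + 1L],
                    end = genes$end_bp[pc[2L] + 1L],
                    name = name, score = score, strand = ".",
                    stringsAsFactors = FALSE)
            }
        }
        bed <- do.call(rbind, rows)
        if (!is.null(bed_path))
            utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE)
    } else if (!is.null(bed_path)) {
        warning("gene table lacks bp coordinates; BED output skipped, ",
                "JSON report uses gene indices")
    }
    if (!is.null(json_path))
        jsonlite::write_json(report, json_path, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    invisible(list(report = report, bed = bed))
}

#' Write / read a two-column profile TSV
#'
#' Used for complexity profiles (`scale`, `value`) and autocorrelation series
#' (`lag`, `r`); the round trip preserves values and, for profiles, the
#' chromosome length needed for distance computations.
#'
#' @param x an `msc_profile` or `autocorrelation_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileTSV <- function(x, path) {
    if (inherits(x, "msc_profile")) {
        out <- data.frame(scale = x$scale, value = x$value)
        attrLine <- paste0("# n=", x$n, " type=msc")
    } else if (inherits(x, "autocorrelation_series")) {
        out <- data.frame(lag = x$lag, r = x$r)
        attrLine <- paste0("# n=", x$n, " type=autocorrelation")
    } else stop("unsupported profile object")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(attrLine, con)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProfileTSV
#' @export
readProfileTSV <- function(path) {
    first <- readLines(path, n = 1L)
    n <- as.integer(sub(".*n=([0-9]+).*", "\\1", first))
    type <- sub(".*type=([a-z]+).*", "\\1", first)
    tab <- utils::read.delim(path, skip = 1L)
    if (type == "msc") {
        structure(list(scale = tab$scale, value = tab$value, n = n),
                  class = "msc_profile")
    } else {
        r <- tab$r
        zl <- which(r[-1L] <= 0)
        structure(list(lag = tab$lag, r = r,
                       zero_lag = if (length(zl)) zl[1L] else NA_integer_,
                       n = n),
                  class = "autocorrelation_series")
    }
}

#' Write a disruption trajectory as CSV
#'
#' `step,block_count` rows; optionally the snapshot matrix (rows = snapshots,
#' columns = genes, 0/1) to a second file for heat-map style rendering.
#'
#' @param traj a `disruption_trajectory`.
#' @param path output CSV path.
#' @param snapshots_path optional path for the snapshot matrix CSV.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path, snapshots_path = NULL) {
    utils::write.csv(data.frame(step = traj$step,
                                block_count = traj$block_count),
                     path, row.names = FALSE, quote = FALSE)
    if (!is.null(snapshots_path))
        utils::write.table(traj$snapshots, snapshots_path, sep = ",",
                           row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write mobility-model epoch snapshots as CSV
#'
#' Rows = epochs, columns = genes, 0/1 high-mobility indicators.
#'
#' @param record a `mobility_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSnapshotsCSV <- function(record, path) {
    utils::write.table(record$snapshots, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
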