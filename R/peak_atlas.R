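#' Read peak calls from narrowPeak or BED files
#'
#' Reads one or more per-sample peak files into a single peak table. Coordinates
#' follow the BED convention: 0-based, half-open \code{[start, end)}. For ENCODE
#' narrowPeak (BED6+4) the peak score is taken from column 9, the MACS2
#' \eqn{-\log_{10}(q)} value; for plain BED the column holding that score is
#' chosen with \code{score_col} (default 5, the BED score column).
#'
#' @param paths character vector of peak files. If the vector is named, names
#'   become sample ids; otherwise ids are file basenames without extension.
#' @param format \code{"narrowPeak"} or \code{"bed"}.
#' @param score_col 1-based column index of the \eqn{-\log_{10}(q)} score when
#'   \code{format = "bed"}; ignored for narrowPeak.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{score}, \code{sample_id}.
#' @seealso [filter_peaks()], [merge_nonredundant()]
#' @export
read_peak_files <- function(paths, format = c("narrowPeak", "bed"),
                            score_col = 5L) {
  format <- match.arg(format)
  if (length(paths) < 1L) stop("no peak files supplied")
  ids <- names(paths)
  if (is.null(ids)) {
    ids <- sub("\\.(narrowPeak|bed)$", "", basename(paths), ignore.case = TRUE)
  }
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    out[[i]] <- read_one_peak_file(paths[[i]], format, score_col, ids[[i]])
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

empty_peak_df <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), sample_id = character(),
             stringsAsFactors = FALSE)
}

read_one_peak_file <- function(path, format, score_col, sample_id) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(empty_peak_df())
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  need <- if (format == "narrowPeak") 10L else max(4L, score_col)
  scol <- if (format == "narrowPeak") 9L else score_col

  bad_line <- function(i, why) {
    stop(sprintf("%s line %d: %s", path, idx[i], why), call. = FALSE)
  }
  n <- length(fields)
  chrom <- character(n); start <- integer(n); end <- integer(n)
  name <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < need) {
      bad_line(i, sprintf("expected >= %d columns, found %d", need, length(f)))
    }
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e)) bad_line(i, "unparseable start/end coordinate")
    if (s < 0L) bad_line(i, "negative start coordinate")
    if (e <= s) bad_line(i, "end <= start (zero or negative peak length)")
    q <- suppressWarnings(as.numeric(f[scol]))
    if (is.na(q)) bad_line(i, sprintf("unparseable score in column %d", scol))
    if (q < 0) bad_line(i, "negative -log10(q) score")
    chrom[i] <- f[1L]; start[i] <- s; end[i] <- e
    name[i] <- f[4L]; score[i] <- q
  }
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, sample_id = sample_id, stringsAsFactors = FALSE)
}

# GRanges view of a BED-convention peak table (1-based closed internally, so
# half-open BED intervals that merely touch do not overlap).
peaks_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Drop weak peaks and peaks overlapping blacklisted regions
#'
#' Retains peaks whose \eqn{-\log_{10}(q)} score is strictly greater than
#' \code{min_neg_log_q} (the default 2 removes peaks with q >= 0.01, i.e.
#' \eqn{-\log_{10} q \le 2}) and that share no base pair with any blacklist
#' interval. Overlap means at least one shared bp under 0-based half-open
#' coordinates, so a peak ending where a blacklist region starts is retained.
#'
#' @param peaks data.frame as returned by [read_peak_files()].
#' @param min_neg_log_q significance cutoff; peaks with score \code{<=} this
#'   value are removed.
#' @param blacklist optional data.frame with \code{chrom}, \code{start},
#'   \code{end} (see [read_blacklist()]), or NULL.
#' @return filtered peak data.frame (possibly empty).
#' @export
filter_peaks <- function(peaks, min_neg_log_q = 2, blacklist = NULL) {
  stopifnot(min_neg_log_q >= 0)
  peaks <- peaks[peaks$score > min_neg_log_q, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist) > 0L && nrow(peaks) > 0L) {
    # suppressed warning: disjoint seqlevels (a blacklist confined to other
    # chromosomes) is a legitimate no-overlap case, not a user error
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(peaks_gr(peaks), peaks_gr(blacklist),
                                  minoverlap = 1L))
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop) > 0L) peaks <- peaks[-drop, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  peaks
}

#' Merge per-sample peaks into a non-redundant peak atlas
#'
#' Greedy score-ranked selection: all peaks are ranked by score descending
#' (ties broken by chromosome then start, for determinism); the top peak is
#' kept and every remaining peak overlapping it (>= 1 bp) is discarded;
#' the process repeats until no peaks remain. The result is a set of
#' pairwise non-overlapping intervals sorted by coordinate, shared by all
#' reference samples.
#'
#' @param peaks filtered peak data.frame from one or more samples.
#' @return a \code{peak_atlas}: data.frame with \code{chrom}, \code{start},
#'   \code{end}, \code{peak_id} (formatted \code{chrom_start_end}) and
#'   \code{score}, with contributing sample ids in
#'   \code{attr(, "provenance")}.
#' @export
merge_nonredundant <- function(peaks) {
  if (nrow(peaks) == 0L) {
    atlas <- data.frame(chrom = character(), start = integer(),
                        end = integer(), peak_id = character(),
                        score = numeric(), stringsAsFactors = FALSE)
    attr(atlas, "provenance") <- character()
    class(atlas) <- c("peak_atlas", "data.frame")
    return(atlas)
  }
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  gr <- peaks_gr(peaks)
  fo <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  adj <- split(S4Vectors::subjectHits(fo), S4Vectors::queryHits(fo))
  n <- nrow(peaks)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[adj[[as.character(i)]]] <- FALSE  # includes i itself
  }
  atlas <- peaks[keep, c("chrom", "start", "end", "score"), drop = FALSE]
  atlas <- atlas[order(atlas$chrom, atlas$start), , drop = FALSE]
  atlas$peak_id <- sprintf("%s_%d_%d", atlas$chrom, atlas$start, atlas$end)
  atlas <- atlas[, c("chrom", "start", "end", "peak_id", "score")]
  rownames(atlas) <- NULL
  attr(atlas, "provenance") <-
    if ("sample_id" %in% names(peaks)) unique(peaks$sample_id) else character()
  class(atlas) <- c("peak_atlas", "data.frame")
  atlas
}

#' Read a blacklist BED file (regions to exclude from peak analysis)
#'
#' @param path BED file with at least chrom/start/end columns.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) stop("blacklist file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    stringsAsFactors = FALSE)
}

#' Write a peak atlas as BED4
#'
#' Columns: chrom, start, end, peak_id (\code{chrom_start_end}).
#'
#' @param atlas a \code{peak_atlas} from [merge_nonredundant()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas[, c("chrom", "start", "end", "peak_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
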