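#' Read a fragment-analysis peak table
#'
#' Delimited text (tab or comma, auto-detected from the header line) with
#' columns \code{sample_id}, \code{run_id}, \code{size}, \code{height} --
#' the sized, height-quantified FAM peaks exported by fragment-analysis
#' software, one row per peak.
#'
#' @param path file path.
#' @return data frame with the four columns above, sizes fractional bases,
#'   heights RFU.
#' @export
read_peak_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample_id", "run_id", "size", "height")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("peak table %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$run_id <- as.character(df$run_id)
  df$size <- as.numeric(df$size)
  df$height <- as.numeric(df$height)
  if (any(is.na(df$size)) || any(df$size <= 0, na.rm = TRUE))
    stop("peak sizes must be positive numbers", call. = FALSE)
  if (any(is.na(df$height)) || any(df$height < 0))
    stop("peak heights must be non-negative", call. = FALSE)
  df[, need]
}

#' Build one peak profile per sample/run
#'
#' @param peaks data frame as returned by [read_peak_table()].
#' @return list of \code{peak_profile} objects (sample_id, run_id, peaks
#'   sorted by size, empty qc_flags), one per unique sample/run pair, ordered
#'   by sample then run id.
#' @export
peak_profiles <- function(peaks) {
  key <- paste(peaks$sample_id, peaks$run_id, sep = "\r")
  lapply(split(seq_len(nrow(peaks)), key),   # split() orders by key
         function(i) {
           p <- peaks[i, , drop = FALSE]
           new_peak_profile(p$sample_id[1], p$run_id[1],
                            p[order(p$size), c("size", "height")])
         })
}

new_peak_profile <- function(sample_id, run_id, peaks,
                             qc_flags = character(0)) {
  peaks <- as.data.frame(peaks)
  rownames(peaks) <- NULL
  structure(list(sample_id = sample_id, run_id = run_id,
                 peaks = peaks, qc_flags = qc_flags),
            class = "peak_profile")
}

#' @export
print.peak_profile <- function(x, ...) {
  cat(sprintf("Peak profile %s/%s: %d peaks%s\n", x$sample_id, x$run_id,
              nrow(x$peaks),
              if (length(x$qc_flags))
                paste0(" [", paste(x$qc_flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Restrict a profile to the sizing window
#'
#' Retains peaks with \code{low <= size <= high} (both ends inclusive).
#' A profile left with no peaks is flagged \code{EMPTY}.
#'
#' @param profile a \code{peak_profile}.
#' @param low,high window bounds in bases (defaults 320 and 420).
#' @return the filtered \code{peak_profile}.
#' @export
filter_window <- function(profile, low = 320, high = 420) {
  stopifnot(inherits(profile, "peak_profile"), low < high)
  keep <- profile$peaks$size >= low & profile$peaks$size <= high
  profile$peaks <- profile$peaks[keep, , drop = FALSE]
  rownames(profile$peaks) <- NULL
  if (nrow(profile$peaks) == 0L)
    profile$qc_flags <- union(profile$qc_flags, "EMPTY")
  profile
}

#' Advisory quality flags for a peak profile
#'
#' \code{OFFSCALE} when any peak reaches the saturation threshold (in the lab
#' such products are re-run diluted 1:2 or 1:10); \code{LOW_SIGNAL} when a
#' strict majority of peaks fall below the low-signal threshold and nothing is
#' off-scale (in the lab such products are re-run with 2-4x more template).
#' Flags are advisory: processing continues.
#'
#' @param profile a \code{peak_profile}.
#' @param offscale_height saturation threshold, RFU (default 32000).
#' @param low_height low-signal threshold, RFU (default 1000).
#' @return the profile with updated \code{qc_flags}.
#' @export
qc_flag <- function(profile, offscale_height = 32000, low_height = 1000) {
  stopifnot(inherits(profile, "peak_profile"),
            offscale_height > 0, low_height > 0)
  h <- profile$peaks$height
  if (length(h) && any(h >= offscale_height)) {
    profile$qc_flags <- union(profile$qc_flags, "OFFSCALE")
  } else if (length(h) && sum(h < low_height) > length(h) / 2) {
    profile$qc_flags <- union(profile$qc_flags, "LOW_SIGNAL")
  }
  profile
}

#' Bin the peaks of a profile and sum their heights
#'
#' Each peak is assigned via [assign_bin()]; heights of co-binned peaks are
#' summed. Unassigned peak mass is reported separately and excluded from the
#' bin sums.
#'
#' @param profile a window-filtered \code{peak_profile}.
#' @param table a \code{bin_table}.
#' @param tolerance,offset passed to [assign_bin()].
#' @return named numeric vector of summed heights (names = bin_id), with the
#'   summed unassigned height in attribute \code{"unassigned"}.
#' @export
bin_peaks <- function(profile, table, tolerance = 0, offset = 0) {
  stopifnot(inherits(profile, "peak_profile"))
  ids <- assign_bin(profile$peaks$size, table, tolerance, offset)
  hit <- !is.na(ids)
  sums <- tapply(profile$peaks$height[hit], ids[hit], sum)
  out <- as.numeric(sums)
  names(out) <- names(sums) %||% character(0)
  attr(out, "unassigned") <- sum(profile$peaks$height[!hit])
  out
}

#' Normalize binned heights to relative abundances
#'
#' @param binned named numeric vector of non-negative summed heights.
#' @return named vector summing to 1.
#' @export
normalize_abundance <- function(binned) {
  total <- sum(binned)
  if (length(binned) == 0L || total <= 0)
    stop("EMPTY_PROFILE: no positive peak height to normalize", call. = FALSE)
  out <- binned / total
  attr(out, "unassigned") <- NULL
  out
}

#' Average replicate runs of one sample
#'
#' Unweighted arithmetic mean of normalized bin abundances across replicate
#' runs (duplicate PCRs and/or duplicate fragment-analysis runs); a bin absent
#' from a replicate contributes 0 for that replicate.
#'
#' @param replicates list of normalized named vectors for one sample.
#' @return named vector over the union of bins, summing to 1.
#' @export
average_replicates <- function(replicates) {
  stopifnot(length(replicates) >= 1L)
  bins <- sort(unique(unlist(lapply(replicates, names))))
  acc <- setNames(numeric(length(bins)), bins)
  for (r in replicates) acc[names(r)] <- acc[names(r)] + r
  acc / length(replicates)
}

#' Assemble the samples x bins relative-abundance matrix
#'
#' Columns are the union of bins detected in at least one sample, ordered by
#' bin low bound; bins never detected (e.g. a reference bin absent from every
#' sample) get no column. Missing bins within a sample are exact zeros and
#' every row sums to 1.
#'
#' @param samples named list: sample_id -> averaged normalized named vector.
#' @param table the \code{bin_table} used for binning (fixes column order).
#' @return an \code{abundance_matrix} (numeric matrix, samples in rows,
#'   bin ids as column names).
#' @export
build_matrix <- function(samples, table) {
  ids <- names(samples)
  if (is.null(ids) || anyDuplicated(ids))
    stop("samples must be a uniquely named list", call. = FALSE)
  detected <- sort(unique(unlist(lapply(samples, names))))
  ord <- order(table$low[match(as.integer(detected), table$bin_id)])
  detected <- detected[ord]
  m <- matrix(0, nrow = length(samples), ncol = length(detected),
              dimnames = list(ids, detected))
  for (s in ids) m[s, names(samples[[s]])] <- samples[[s]]
  as_abundance_matrix(m)
}

#' Validate and class an abundance matrix
#' @param m numeric matrix, samples in rows, bins in columns; every row must
#'   sum to 1 within 1e-9 and values lie in [0, 1].
#' @return the matrix with class \code{abundance_matrix}.
#' @export
as_abundance_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0) || any(m > 1))
    stop("abundances must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("every abundance row must sum to 1", call. = FALSE)
  class(m) <- c("abundance_matrix", class(m))
  m
}

#' Full peak-table -> abundance-matrix pipeline
#'
#' Window-filters, QC-flags, bins, normalizes and replicate-averages every
#' sample of a peak table. Samples whose runs all have zero in-window binned
#' height are dropped with a warning.
#'
#' @param peaks data frame from [read_peak_table()] (or path to one).
#' @param table a \code{bin_table}.
#' @param window inclusive sizing window, bases.
#' @param tolerance,offset passed to [assign_bin()].
#' @param offscale_height,low_height passed to [qc_flag()].
#' @return an \code{abundance_matrix}; QC flags per run in attribute
#'   \code{"qc"}, total unassigned height per run in attribute
#'   \code{"unassigned"}.
#' @export
peaks_to_matrix <- function(peaks, table, window = c(320, 420),
                            tolerance = 0, offset = 0,
                            offscale_height = 32000, low_height = 1000) {
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  profs <- peak_profiles(peaks)
  qc <- list(); unass <- c(); norm <- list()
  for (p in profs) {
    p <- qc_flag(filter_window(p, window[1], window[2]),
                 offscale_height, low_height)
    key <- paste0(p$sample_id, "/", p$run_id)
    qc[[key]] <- p$qc_flags
    b <- bin_peaks(p, table, tolerance, offset)
    unass[key] <- attr(b, "unassigned")
    if (length(b) && sum(b) > 0) {
      norm[[p$sample_id]] <- c(norm[[p$sample_id]],
                               list(normalize_abundance(b)))
    } else {
      warning(sprintf("run %s has no binned signal; excluded", key))
    }
  }
  if (!length(norm)) stop("no sample with binned signal", call. = FALSE)
  averaged <- lapply(norm, average_replicates)
  m <- build_matrix(averaged, table)
  attr(m, "qc") <- qc
  attr(m, "unassigned") <- unass
  m
}

#' Read / write an abundance matrix as TSV
#'
#' Samples in rows (first column \code{sample_id}), bin ids as the remaining
#' column headers (prefixed \code{bin_} on disk so headers stay syntactic),
#' full precision, fixed ordering.
#' @param m an \code{abundance_matrix}.
#' @param path file path.
#' @export
write_abundance_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- paste0("bin_", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_matrix
#' @export
read_abundance_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- as.character(df$sample_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rn
  colnames(m) <- sub("^bin_", "", colnames(m))
  as_abundance_matrix(m)
}
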