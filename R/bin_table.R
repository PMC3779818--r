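#' Construct a fragment-length bin table
#'
#' Groups predicted amplicon lengths into diagnostic fragment bins: lengths
#' differing by at most \code{merge_radius} bases (default 1, giving the
#' 2-base ranges of the reference assay) are merged into one bin and their
#' taxon labels unioned.
#'
#' @param predictions data frame with columns \code{taxon_label} and
#'   \code{length_bases} (one row per reference amplicon), or the output of
#'   [predict_amplicons()].
#' @param window integer length-2: the sizing window; lengths outside it are
#'   dropped with a warning.
#' @param merge_radius merge lengths differing by <= this many bases.
#' @return a \code{bin_table}: data frame with columns \code{bin_id},
#'   \code{low}, \code{high}, \code{taxon_labels}, \code{branch_labels} and
#'   attributes \code{window_low}, \code{window_high}.
#' @export
build_bin_table <- function(predictions, window = c(320L, 420L),
                            merge_radius = 1L) {
  stopifnot(all(c("taxon_label", "length_bases") %in% names(predictions)))
  len <- as.integer(predictions$length_bases)
  lab <- as.character(predictions$taxon_label)
  out <- len >= window[1] & len <= window[2]
  if (any(!out & !is.na(len)))
    warning(sprintf("%d length(s) outside [%d, %d] dropped",
                    sum(!out), window[1], window[2]))
  len <- len[out]; lab <- lab[out]
  if (!length(len)) stop("no lengths inside the sizing window", call. = FALSE)
  o <- order(len)
  len <- len[o]; lab <- lab[o]
  # chain-merge: a new bin starts where the gap to the previous length
  # exceeds the merge radius
  grp <- cumsum(c(1L, diff(len) > merge_radius))
  lows <- tapply(len, grp, min)
  highs <- tapply(len, grp, max)
  taxa <- tapply(lab, grp, function(x)
    paste(sort(unique(x[!is.na(x) & nzchar(x)])), collapse = ";"))
  tab <- data.frame(bin_id = seq_along(lows), low = as.integer(lows),
                    high = as.integer(highs),
                    taxon_labels = as.character(taxa),
                    branch_labels = "", stringsAsFactors = FALSE)
  as_bin_table(tab, window_low = window[1], window_high = window[2])
}

#' Validate and class a bin table
#'
#' @param tab data frame with columns \code{bin_id}, \code{low}, \code{high}
#'   and optionally \code{taxon_labels}, \code{branch_labels}.
#' @param window_low,window_high sizing-window bounds (bases).
#' @return the validated \code{bin_table}.
#' @export
as_bin_table <- function(tab, window_low = 320L, window_high = 420L) {
  stopifnot(all(c("bin_id", "low", "high") %in% names(tab)))
  if (is.null(tab$taxon_labels)) tab$taxon_labels <- ""
  if (is.null(tab$branch_labels)) tab$branch_labels <- ""
  tab$taxon_labels[is.na(tab$taxon_labels)] <- ""
  tab$branch_labels[is.na(tab$branch_labels)] <- ""
  tab <- tab[order(tab$low), , drop = FALSE]
  rownames(tab) <- NULL
  if (any(tab$low > tab$high))
    stop("bin with low > high", call. = FALSE)
  if (any(tab$low < window_low | tab$high > window_high))
    stop("bin outside the sizing window", call. = FALSE)
  if (nrow(tab) > 1 && any(tab$low[-1] <= tab$high[-nrow(tab)]))
    stop("overlapping bins", call. = FALSE)
  if (anyDuplicated(tab$bin_id))
    stop("duplicate bin_id", call. = FALSE)
  attr(tab, "window_low") <- as.integer(window_low)
  attr(tab, "window_high") <- as.integer(window_high)
  class(tab) <- c("bin_table", "data.frame")
  tab
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("Fragment bin table: %d bins in window [%d, %d] bases\n",
              nrow(x), attr(x, "window_low"), attr(x, "window_high")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Assign a sized fragment to a bin
#'
#' Applies the global calibration \code{offset}, rounds the fractional
#' instrument size half-up to the nearest integer base, and returns the bin
#' whose range (widened by \code{tolerance} bases on each side) contains it.
#' Ambiguous containment (possible when \code{tolerance > 0}) is broken to the
#' nearest bin centre, exact ties to the lower \code{bin_id}. Sizes outside
#' the sizing window, or in no bin, are unassigned (\code{NA}).
#'
#' @param length fractional fragment size(s) in bases (vectorized).
#' @param table a \code{bin_table}.
#' @param tolerance non-negative widening of each bin range, bases.
#' @param offset global size calibration offset added before rounding.
#' @return integer vector of \code{bin_id}s, \code{NA} where unassigned.
#' @examples
#' tab <- arisa_fixtures()$table1_bins
#' assign_bin(348.4, tab)   # group 1
#' assign_bin(500, tab)     # NA: outside the window
#' @export
assign_bin <- function(length, table, tolerance = 0, offset = 0) {
  stopifnot(inherits(table, "bin_table"), tolerance >= 0)
  wlo <- attr(table, "window_low"); whi <- attr(table, "window_high")
  L <- round_half_up(length + offset)
  centers <- (table$low + table$high) / 2
  vapply(L, function(l) {
    if (is.na(l) || l < wlo || l > whi) return(NA_integer_)
    hit <- which(l >= table$low - tolerance & l <= table$high + tolerance)
    if (!length(hit)) return(NA_integer_)
    if (length(hit) > 1L) {
      d <- abs(centers[hit] - l)
      hit <- hit[d == min(d)]            # nearest centre, then lower bin_id
      hit <- hit[which.min(table$bin_id[hit])]
    }
    as.integer(table$bin_id[hit])
  }, integer(1))
}

#' Read / write a bin table as TSV
#'
#' Columns: \code{bin_id}, \code{low}, \code{high}, \code{taxon_labels}
#' (semicolon-joined), \code{branch_labels}. The reference 16-bin table ships
#' in this format (see [arisa_fixtures()]).
#'
#' @param path file path.
#' @param window_low,window_high sizing-window bounds.
#' @return \code{read_bin_table}: a \code{bin_table}.
#' @export
read_bin_table <- function(path, window_low = 320L, window_high = 420L) {
  tab <- read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
  for (col in c("bin_id", "low", "high"))
    tab[[col]] <- as.integer(tab[[col]])
  for (col in c("taxon_labels", "branch_labels")) {
    if (is.null(tab[[col]])) tab[[col]] <- ""
    tab[[col]] <- as.character(tab[[col]])
  }
  as_bin_table(tab, window_low, window_high)
}

#' @param table a \code{bin_table} to serialize.
#' @rdname read_bin_table
#' @export
write_bin_table <- function(table, path) {
  stopifnot(inherits(table, "bin_table"))
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Summarize the spread of amplicon lengths in a bin table
#'
#' The spread is reported both as the inclusive span of the extreme bin
#' bounds and as the difference of the extreme bin low edges, since an
#' endpoint-inclusive "varied by N bases" statement is ambiguous.
#' @param table a \code{bin_table}.
#' @return list with \code{min_length}, \code{max_length}, \code{span_bounds}
#'   (max high - min low) and \code{span_lows} (max low - min low).
#' @export
bin_table_span <- function(table) {
  stopifnot(inherits(table, "bin_table"))
  list(min_length = min(table$low), max_length = max(table$high),
       span_bounds = max(table$high) - min(table$low),
       span_lows = max(table$low) - min(table$low))
}
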