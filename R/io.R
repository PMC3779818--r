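#' Read reference sequences from FASTA
#'
#' The record id is the description-line token before the first whitespace;
#' the taxon label is everything after it. Sequences are uppercased and
#' \code{U} converted to \code{T}.
#'
#' @param path FASTA file path.
#' @return list of \code{reference_sequence} objects, each a list with
#'   \code{id}, \code{taxon_label}, \code{sequence}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file", call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  labels <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate sequence id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  seqs <- unname(chartr("U", "T", toupper(as.character(set))))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    if (!nzchar(seqs[i]))
      stop(sprintf("empty sequence for record '%s'", ids[i]), call. = FALSE)
    .check_iupac(seqs[i], sprintf("record '%s'", ids[i]))
    out[[i]] <- structure(list(id = ids[i], taxon_label = labels[i],
                               sequence = seqs[i]),
                          class = "reference_sequence")
  }
  out
}

#' Predict the bin table for a whole reference set
#'
#' Runs [predict_amplicons()] over every reference sequence and merges the
#' resulting lengths into a \code{bin_table} via [build_bin_table()].
#'
#' @param refs list of \code{reference_sequence} (from [read_fasta()]).
#' @param primers,max_mismatch,length_window passed to [predict_amplicons()].
#' @param merge_radius passed to [build_bin_table()].
#' @return list with \code{predictions} (per-reference amplicon data frame,
#'   with an \code{assigned_bin} column) and \code{bin_table}.
#' @export
reference_bin_table <- function(refs, primers = arisa_primers(),
                                max_mismatch = 0L,
                                length_window = c(320L, 420L),
                                merge_radius = 1L) {
  preds <- do.call(rbind, lapply(refs, predict_amplicons, primers = primers,
                                 max_mismatch = max_mismatch,
                                 length_window = length_window))
  if (is.null(preds) || nrow(preds) == 0L)
    stop("no amplicon predicted from the reference set", call. = FALSE)
  bt <- build_bin_table(preds, window = length_window,
                        merge_radius = merge_radius)
  preds$assigned_bin <- assign_bin(preds$length_bases, bt)
  list(predictions = preds, bin_table = bt)
}
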