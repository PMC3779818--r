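#' IUPAC nucleotide degeneracy sets
#'
#' Mapping from the 15 IUPAC nucleotide codes to the set of concrete bases
#' each one stands for (e.g. \code{R} = A/G, \code{Y} = C/T, \code{N} = any).
#' Used to honour the degenerate positions of the ITS2 ARISA primers.
#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

.check_iupac <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "")[[1]]), names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC character(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Does an IUPAC primer character match a concrete base?
#'
#' @param primer_char single IUPAC nucleotide code (possibly degenerate).
#' @param base concrete base, one of A, C, G, T.
#' @return \code{TRUE} iff \code{base} lies in the degeneracy set of
#'   \code{primer_char}.
#' @examples
#' iupac_match("R", "A")  # TRUE: R = A/G
#' iupac_match("Y", "G")  # FALSE: Y = C/T
#' @export
iupac_match <- function(primer_char, base) {
  primer_char <- toupper(primer_char)
  base <- toupper(base)
  if (!primer_char %in% names(IUPAC_SETS))
    stop(sprintf("invalid IUPAC code '%s'", primer_char), call. = FALSE)
  if (!base %in% c("A", "C", "G", "T"))
    stop(sprintf("'%s' is not a concrete base", base), call. = FALSE)
  base %in% IUPAC_SETS[[primer_char]]
}

#' Reverse complement of an IUPAC string
#' @param seq nucleotide string, possibly degenerate.
#' @return reverse-complemented string, degeneracies mapped through their
#'   complements (R <-> Y, etc.).
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  .check_iupac(seq)
  paste(rev(IUPAC_COMPLEMENT[strsplit(seq, "")[[1]]]), collapse = "")
}

#' Find degenerate-primer binding sites on a template
#'
#' Slides the primer along the plus strand of \code{seq} and reports every
#' window matching with at most \code{max_mismatch} mismatching positions,
#' where a position matches if the template base lies in the IUPAC degeneracy
#' set of the primer character. For \code{strand = "reverse_complement"} the
#' reverse complement of the primer is matched instead (a reverse-primer
#' binding site reported in plus-strand coordinates).
#'
#' @param seq template DNA string (concrete bases A/C/G/T; IUPAC codes in the
#'   template count as mismatches unless the primer base set intersects them
#'   is not supported -- the template must be concrete).
#' @param primer IUPAC primer string, written 5'->3'.
#' @param max_mismatch non-negative mismatch budget.
#' @param strand \code{"forward"} or \code{"reverse_complement"}.
#' @return integer vector of 0-based window start positions, sorted ascending;
#'   empty when the primer is longer than the template.
#' @examples
#' find_binding_sites("TTACGAATTGCAGAACCTCGTT", "RCGAAYTGCAGAACCTCG", 0)
#' @export
find_binding_sites <- function(seq, primer, max_mismatch = 0L,
                               strand = c("forward", "reverse_complement")) {
  strand <- match.arg(strand)
  stopifnot(max_mismatch >= 0)
  seq <- toupper(seq)
  primer <- toupper(primer)
  .check_iupac(seq, "template")
  .check_iupac(primer, "primer")
  if (strand == "reverse_complement") primer <- reverse_complement(primer)
  k <- nchar(primer)
  n <- nchar(seq)
  if (k > n || k == 0L) return(integer(0))
  pc <- strsplit(primer, "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  # logical match matrix: rows = primer positions, one column per template pos
  ok <- vapply(seq_len(k), function(i) sc %in% IUPAC_SETS[[pc[i]]], logical(n))
  starts <- integer(0)
  for (p in 0:(n - k)) {
    mism <- sum(!ok[cbind(p + seq_len(k), seq_len(k))])
    if (mism <= max_mismatch) starts <- c(starts, p)
  }
  starts
}

#' In-silico prediction of ARISA amplicons
#'
#' Pairs each forward-primer binding site with the nearest downstream
#' reverse-primer site (matched as the reverse complement on the plus strand)
#' and keeps products whose full length -- both primer footprints included,
#' as sized on the capillary since the FAM label rides on the forward
#' primer -- falls inside \code{length_window}.
#'
#' @param ref a \code{reference_sequence} (see [read_fasta()]) or a list with
#'   elements \code{id}, \code{taxon_label}, \code{sequence}.
#' @param primers list with IUPAC strings \code{forward} and \code{reverse},
#'   both written 5'->3' (default: the ITS2 ARISA primer pair).
#' @param max_mismatch mismatch budget per primer (default 0).
#' @param length_window numeric length-2, inclusive amplicon length bounds.
#' @return data frame with one row per predicted amplicon: \code{reference_id},
#'   \code{taxon_label}, \code{start} (0-based inclusive), \code{end} (0-based
#'   exclusive), \code{length_bases}.
#' @export
predict_amplicons <- function(ref, primers = arisa_primers(),
                              max_mismatch = 0L,
                              length_window = c(320L, 420L)) {
  stopifnot(length_window[1] >= 1)
  seq <- toupper(ref$sequence)
  fwd <- find_binding_sites(seq, primers$forward, max_mismatch, "forward")
  rev <- find_binding_sites(seq, primers$reverse, max_mismatch,
                            "reverse_complement")
  rlen <- nchar(primers$reverse)
  out <- data.frame(reference_id = character(0), taxon_label = character(0),
                    start = integer(0), end = integer(0),
                    length_bases = integer(0), stringsAsFactors = FALSE)
  for (f in fwd) {
    # candidate reverse sites strictly downstream of the forward footprint
    cand <- rev[rev >= f + nchar(primers$forward)]
    if (!length(cand)) next
    ends <- cand + rlen
    lens <- ends - f
    keep <- which(lens >= length_window[1] & lens <= length_window[2])
    if (!length(keep)) next
    i <- keep[which.min(lens[keep])]   # shortest valid product per forward site
    out <- rbind(out, data.frame(
      reference_id = ref$id, taxon_label = ref$taxon_label %||% NA_character_,
      start = f, end = ends[i], length_bases = lens[i],
      stringsAsFactors = FALSE))
  }
  out
}

#' The degenerate ITS2 ARISA primer pair
#'
#' Forward 5'-RCGAAYTGCAGAACCTCG-3' (FAM-labelled in the assay) and reverse
#' 5'-TACTYAATCTGAGATYCA-3', designed to amplify the 5.8S-ITS2 region of
#' Thalassiosiroid diatoms.
#' @return list with elements \code{forward} and \code{reverse}.
#' @export
arisa_primers <- function() {
  list(forward = "RCGAAYTGCAGAACCTCG", reverse = "TACTYAATCTGAGATYCA")
}
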