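#' Shannon-Wiener diversity index
#'
#' \eqn{H' = -\sum_{p_i > 0} p_i \log_{10} p_i}. Base 10 by default, matching
#' the diversity convention of the reference assay; zero abundances contribute
#' zero.
#'
#' @param p relative-abundance vector summing to 1 (within 1e-6).
#' @param base logarithm base (default 10).
#' @return the index \eqn{H'}.
#' @examples
#' shannon_index(rep(0.1, 10))  # 1: log10 of richness at perfect evenness
#' @export
shannon_index <- function(p, base = 10) {
  if (any(p < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6)
    stop("abundance vector must sum to 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Richness: number of bins with positive abundance
#' @param p relative-abundance vector.
#' @return integer count of entries > 0.
#' @export
richness <- function(p) sum(p > 0)

#' Pielou evenness
#'
#' \eqn{J' = H' / \log_{10} S}; undefined (\code{NA}) for \eqn{S < 2}.
#' @param H Shannon-Wiener index (same log base as \code{base}).
#' @param S richness.
#' @param base logarithm base (default 10).
#' @return evenness in [0, 1], or \code{NA}.
#' @export
pielou_evenness <- function(H, S, base = 10) {
  ifelse(S >= 2, H / log(S, base = base), NA_real_)
}

#' Per-sample diversity table
#'
#' @param m an \code{abundance_matrix} (samples x bins).
#' @param base logarithm base (default 10).
#' @return data frame with columns \code{sample_id}, \code{H}, \code{S},
#'   \code{J}.
#' @export
diversity_table <- function(m, base = 10) {
  H <- apply(m, 1, shannon_index, base = base)
  S <- apply(m, 1, richness)
  data.frame(sample_id = rownames(m), H = H, S = as.integer(S),
             J = pielou_evenness(H, S, base = base),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a diversity table as TSV (4 decimal places)
#' @param d data frame from [diversity_table()].
#' @param path file path.
#' @export
write_diversity_table <- function(d, path) {
  d$H <- sprintf("%.4f", d$H)
  d$J <- ifelse(is.na(d$J), "NA", sprintf("%.4f", d$J))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
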