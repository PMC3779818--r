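#' Reference tables shipped with the package
#'
#' Returns the three reference tables of the assay as typed objects:
#' \describe{
#'   \item{table1_bins}{the 16 diagnostic fragment bins (a \code{bin_table}):
#'     2-base length ranges with their taxon and phylogenetic-branch labels.}
#'   \item{table3_diversity}{the published per-sample diversity statistics
#'     (27 samples: Shannon-Wiener H, base 10; richness S; Pielou J).}
#'   \item{table4_env}{surface environmental values for the 22 stations with
#'     complete measurements (temperature ITS-90, salinity PSS-78,
#'     fluorescence RFU, dissolved Fe nM, bottom depth m).}
#' }
#' File integrity is verified against recorded MD5 checksums at load time.
#'
#' @return named list with the three objects above.
#' @examples
#' fx <- arisa_fixtures()
#' nrow(fx$table1_bins)   # 16
#' @export
arisa_fixtures <- function() {
  files <- c(table1_bins = "table1_bins.tsv",
             table3_diversity = "table3_diversity.tsv",
             table4_env = "table4_env.tsv")
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "tarisa", mustWork = TRUE),
    character(1))
  sums <- tools::md5sum(paths)
  expected <- c(table1_bins = "3bea0d417df4d95ef7291ff2355f247d",
                table3_diversity = "bb36795528163f45058cf11d7d5bfa0d",
                table4_env = "213cbdc727bda4298688c6c32a68da85")
  bad <- names(files)[sums != expected[names(files)]]
  if (length(bad))
    stop(sprintf("packaging error: checksum mismatch for %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  list(table1_bins = read_bin_table(paths["table1_bins"]),
       table3_diversity = read.delim(
         paths["table3_diversity"], stringsAsFactors = FALSE,
         colClasses = c("character", "numeric", "integer", "numeric")),
       table4_env = read_env_table(paths["table4_env"]))
}
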