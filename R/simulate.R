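#' Configuration for the synthetic ARISA generator
#'
#' Defaults mirror the scale of the field study the assay was built for:
#' 27 surface samples typed against 16 diagnostic fragment bins, a handful
#' of bins dominating each profile, duplicate runs per sample, capillary
#' size jitter well below one base, and occasional spurious low peaks.
#'
#' @param n_samples number of samples/stations (default 27).
#' @param n_bins number of fragment bins (default 16).
#' @param concentration gamma shape of the baseline bin abundances; smaller
#'   values give profiles dominated by one or two bins (default 0.5).
#' @param gradient_strength log-linear effect of the driver variable on
#'   composition; 0 decouples community from environment (default 1.5).
#' @param env_correlation exchangeable correlation among the simulated
#'   environmental variables (default 0.3).
#' @param driver name of the designated driver variable (default
#'   \code{"temperature"}).
#' @param detection_floor relative abundance below which a bin is not
#'   detected in a sample (default 0.01).
#' @param size_jitter_sd Gaussian jitter of peak sizes around bin centres,
#'   bases (default 0.15).
#' @param noise_peak_rate Poisson rate of spurious low peaks per profile
#'   (default 0.5).
#' @param replicate_count ARISA runs per sample (default 2).
#' @param height_scale total profile height, RFU (default 20000).
#' @param height_cv multiplicative (lognormal) noise CV on peak heights
#'   (default 0.2).
#' @param seed mandatory RNG seed.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples = 27, n_bins = 16,
                              concentration = 0.5, gradient_strength = 1.5,
                              env_correlation = 0.3, driver = "temperature",
                              detection_floor = 0.01,
                              size_jitter_sd = 0.15, noise_peak_rate = 0.5,
                              replicate_count = 2, height_scale = 20000,
                              height_cv = 0.2, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- list(n_samples = n_samples, n_bins = n_bins,
              concentration = concentration,
              gradient_strength = gradient_strength,
              env_correlation = env_correlation, driver = driver,
              detection_floor = detection_floor,
              size_jitter_sd = size_jitter_sd,
              noise_peak_rate = noise_peak_rate,
              replicate_count = replicate_count,
              height_scale = height_scale, height_cv = height_cv,
              seed = as.integer(seed))
  stopifnot(cfg$size_jitter_sd >= 0, cfg$noise_peak_rate >= 0,
            cfg$height_cv >= 0, cfg$replicate_count >= 1,
            cfg$gradient_strength >= 0)
  class(cfg) <- "simulation_config"
  cfg
}

# derive one reproducible sub-seed per unit of work from the master seed,
# so each sample/run stream is independently replayable
.split_seeds <- function(seed, n, stream = 0L) {
  (as.double(seed) * 1000003 + stream * 7919 + seq_len(n)) %% 2147483647
}

#' Simulate a community along an environmental gradient
#'
#' Environmental variables (temperature, salinity, fluorescence,
#' dissolved_fe, bottom_depth) are drawn with exchangeable mutual correlation
#' \code{env_correlation} and rescaled to oceanographically plausible ranges.
#' Each bin gets a gamma baseline and a fixed loading spread over
#' \code{[-1, 1]}; sample composition is proportional to
#' \code{baseline * exp(gradient_strength * loading * z_driver)}, so
#' composition shifts monotonically along the standardized driver.
#' Abundances below \code{detection_floor} are zeroed (detection limit) and
#' rows renormalized.
#'
#' @param cfg a [simulation_config()].
#' @return list with \code{matrix} (an \code{abundance_matrix}),
#'   \code{env} (station table), \code{bin_table} (synthetic 2-base bins laid
#'   across the 320-420 window), and \code{ground_truth} (driver identity,
#'   effect size, loadings, standardized driver values).
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  n <- cfg$n_samples; k <- cfg$n_bins
  ids <- sprintf("S%02d", seq_len(n))
  vars <- c("temperature", "salinity", "fluorescence", "dissolved_fe",
            "bottom_depth")
  # exchangeable-correlation gaussians: shared factor + idiosyncratic part
  r <- cfg$env_correlation
  shared <- rnorm(n)
  z <- vapply(vars, function(v)
    sqrt(abs(r)) * sign(r) * shared + sqrt(1 - abs(r)) * rnorm(n),
    numeric(n))
  scales <- list(temperature = c(9, 1.2), salinity = c(31.8, 0.7),
                 fluorescence = c(1.2, 0.9), dissolved_fe = c(0.7, 0.6),
                 bottom_depth = c(2000, 1100))
  env <- data.frame(station_id = ids, stringsAsFactors = FALSE)
  for (v in vars) {
    val <- scales[[v]][1] + scales[[v]][2] * z[, v]
    if (v %in% c("fluorescence", "dissolved_fe")) val <- pmax(val, 0.01)
    if (v == "bottom_depth") val <- pmax(val, 50)
    env[[v]] <- round(val, 3)
  }
  zdrv <- as.numeric(scale(env[[cfg$driver]]))
  baseline <- rgamma(k, shape = cfg$concentration, rate = 1) + 1e-6
  loading <- seq(-1, 1, length.out = k)[sample.int(k)]
  m <- matrix(0, n, k, dimnames = list(ids, as.character(seq_len(k))))
  for (i in seq_len(n)) {
    w <- baseline * exp(cfg$gradient_strength * loading * zdrv[i]) *
      rlnorm(k, 0, 0.4)
    w <- w / sum(w)
    w[w < cfg$detection_floor] <- 0
    if (sum(w) == 0) w[which.max(baseline)] <- 1
    m[i, ] <- w / sum(w)
  }
  # synthetic 2-base bins tiled across the sizing window
  lows <- as.integer(seq(322, by = 6, length.out = k))
  bt <- as_bin_table(data.frame(bin_id = seq_len(k), low = lows,
                                high = lows + 1L,
                                taxon_labels = sprintf("sim_taxon_%02d",
                                                       seq_len(k)),
                                branch_labels = "",
                                stringsAsFactors = FALSE))
  list(matrix = as_abundance_matrix(m), env = env, bin_table = bt,
       ground_truth = list(driver = cfg$driver,
                           gradient_strength = cfg$gradient_strength,
                           loadings = setNames(loading, colnames(m)),
                           z_driver = setNames(zdrv, ids)))
}

#' Simulate per-run fragment peak tables from an abundance matrix
#'
#' For each replicate run of each sample, a peak is emitted at each detected
#' bin's centre plus Gaussian size jitter, with height proportional to
#' abundance times \code{height_scale} under multiplicative lognormal noise;
#' spurious low peaks (Poisson count, uniform sizes across the window,
#' heights 50-400 RFU) emulate instrument noise. With all noise parameters
#' zero the peak tables invert exactly through the peak-processing pipeline.
#'
#' @param m an \code{abundance_matrix} (rows sum to 1).
#' @param table the \code{bin_table} whose bin centres carry the peaks.
#' @param cfg a [simulation_config()].
#' @return data frame with columns \code{sample_id}, \code{run_id},
#'   \code{size}, \code{height}.
#' @export
simulate_peak_profiles <- function(m, table, cfg) {
  stopifnot(inherits(cfg, "simulation_config"),
            all(abs(rowSums(m) - 1) < 1e-9))
  centers <- setNames((table$low + table$high) / 2,
                      as.character(table$bin_id))
  wlo <- attr(table, "window_low"); whi <- attr(table, "window_high")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  seeds <- .split_seeds(cfg$seed, nrow(m) * cfg$replicate_count, stream = 1L)
  rows <- list()
  u <- 0L
  for (i in seq_len(nrow(m))) for (r in seq_len(cfg$replicate_count)) {
    u <- u + 1L
    set.seed(seeds[u])
    ab <- m[i, ]
    det <- which(ab > 0)
    size <- centers[names(ab)[det]] + rnorm(length(det), 0, cfg$size_jitter_sd)
    height <- ab[det] * cfg$height_scale *
      if (cfg$height_cv > 0)
        rlnorm(length(det), -cfg$height_cv^2 / 2, cfg$height_cv) else 1
    n_noise <- if (cfg$noise_peak_rate > 0) rpois(1, cfg$noise_peak_rate) else 0L
    if (n_noise > 0) {
      size <- c(size, runif(n_noise, wlo, whi))
      height <- c(height, runif(n_noise, 50, 400))
    }
    rows[[u]] <- data.frame(sample_id = rownames(m)[i],
                            run_id = sprintf("R%d", r),
                            size = as.numeric(size),
                            height = as.numeric(height),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a peak table as TSV
#' @param peaks data frame with sample_id, run_id, size, height.
#' @param path file path.
#' @export
write_peak_table <- function(peaks, path) {
  write.table(peaks, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
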