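#' Read a station environmental table
#'
#' TSV with header \code{station_id} followed by variable names; missing
#' values as empty cells or \code{NA}.
#'
#' @param path file path.
#' @return data frame with character \code{station_id} and numeric variables.
#' @export
read_env_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (names(df)[1] != "station_id")
    stop("first column must be station_id", call. = FALSE)
  df$station_id <- as.character(df$station_id)
  if (anyDuplicated(df$station_id))
    stop("duplicate station_id", call. = FALSE)
  for (v in names(df)[-1]) df[[v]] <- as.numeric(df[[v]])
  df
}

#' Tie-corrected Spearman rank correlation with a two-tailed p value
#'
#' Pearson correlation on mid-ranks; the p value uses
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} against Student's t with n-2
#' degrees of freedom, two-tailed. Incomplete pairs are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list with \code{rho}, \code{p}, \code{n} (complete pairs used);
#'   \code{rho} is \code{NA} when fewer than 3 complete pairs remain or a
#'   rank vector has zero variance.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Pairwise Spearman correlation matrix of environmental variables
#'
#' Applies [spearman_cor()] to every variable pair with pairwise-complete
#' deletion.
#'
#' @param env data frame from [read_env_table()] (or any data frame whose
#'   first column is \code{station_id}).
#' @param variables variables to include (default: all numeric columns).
#' @return object of class \code{env_correlation}: list of matrices
#'   \code{rho}, \code{p}, \code{n_used}.
#' @export
env_correlation_matrix <- function(env, variables = NULL) {
  vars <- variables %||% setdiff(names(env), "station_id")
  k <- length(vars)
  rho <- p <- nuse <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(rho) <- 1; diag(p) <- 0
  diag(nuse) <- colSums(!is.na(env[vars]))
  for (i in seq_len(k)) for (j in seq_len(k)) if (j > i) {
    s <- spearman_cor(env[[vars[i]]], env[[vars[j]]])
    rho[i, j] <- rho[j, i] <- s$rho
    p[i, j] <- p[j, i] <- s$p
    nuse[i, j] <- nuse[j, i] <- s$n
  }
  structure(list(rho = rho, p = p, n_used = nuse),
            class = "env_correlation")
}

#' @export
print.env_correlation <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix (tie-corrected, pairwise-complete)\n")
  cat("rho:\n"); print(round(x$rho, digits))
  cat("two-tailed p:\n"); print(signif(x$p, digits))
  invisible(x)
}

#' Normalized (z-scored) environmental matrix for a variable subset
#'
#' Each variable is standardized to mean 0, sd 1 over the included stations;
#' stations missing any subset variable are excluded (listwise within the
#' subset) and recorded in attribute \code{"excluded"}. Euclidean distance on
#' this matrix is the normalized-Euclidean resemblance used in BIOENV.
#'
#' @param env data frame with \code{station_id} + variables.
#' @param subset character vector of variable names (non-empty).
#' @return numeric matrix (stations x variables) with station ids as row
#'   names.
#' @export
normalize_env <- function(env, subset) {
  stopifnot(length(subset) >= 1)
  miss <- setdiff(subset, names(env))
  if (length(miss))
    stop(sprintf("unknown variable(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  sub <- env[, subset, drop = FALSE]
  ok <- stats::complete.cases(sub)
  m <- as.matrix(sub[ok, , drop = FALSE])
  rownames(m) <- env$station_id[ok]
  for (v in subset) {
    s <- stats::sd(m[, v])
    if (is.na(s) || s == 0)
      stop(sprintf("zero-variance variable: %s", v), call. = FALSE)
    m[, v] <- (m[, v] - mean(m[, v])) / s
  }
  attr(m, "excluded") <- env$station_id[!ok]
  m
}

# rank correlation between the strictly-lower triangles of a biotic
# dissimilarity matrix and a matched env distance matrix
.matrix_rank_cor <- function(biotic_m, env_m) {
  lt <- lower.tri(biotic_m)
  s <- spearman_cor(biotic_m[lt], env_m[lt])
  s$rho
}

#' BIOENV/BEST: which environmental subset best matches the biota?
#'
#' For every non-empty subset of the candidate variables (up to
#' \code{max_subset_size}), computes Euclidean distance on the z-scored
#' subset and ranks subsets by the tie-corrected Spearman correlation
#' \eqn{\rho_s} between the strictly-lower-triangle entries of the biotic
#' dissimilarity matrix and the environmental distance matrix. Stations are
#' dropped per subset only when a subset variable is missing for them
#' (listwise within the subset).
#'
#' @param biotic a \code{dist} of community dissimilarities (labels =
#'   station ids), or a percent-similarity matrix (converted by
#'   \eqn{d = 1 - s/100}).
#' @param env data frame with \code{station_id} + variables.
#' @param variables candidate variables (default: all numeric columns).
#' @param max_subset_size cap on subset size (default: all variables).
#' @param greedy use a forward/backward BVSTEP-style search instead of
#'   exhaustive enumeration. Only advisable for many variables; may miss the
#'   optimum (a warning says so).
#' @return object of class \code{bioenv_fit}: \code{results} data frame
#'   (subset, size, rho) sorted by decreasing \eqn{\rho_s}, \code{best}
#'   (variables of the top subset), \code{best_rho}, \code{n_subsets},
#'   \code{excluded} (stations dropped for the best subset), plus the call
#'   inputs needed for permutation testing.
#' @export
bioenv <- function(biotic, env, variables = NULL, max_subset_size = NULL,
                   greedy = FALSE) {
  biotic <- .as_dissimilarity(biotic)
  vars <- variables %||% setdiff(names(env), "station_id")
  ids <- intersect(attr(biotic, "Labels"), env$station_id)
  if (length(ids) < 3)
    stop("no usable overlap between biotic and environmental stations",
         call. = FALSE)
  bm_full <- as.matrix(biotic)[ids, ids]
  env <- env[match(ids, env$station_id), , drop = FALSE]
  kmax <- min(max_subset_size %||% length(vars), length(vars))
  if (greedy) {
    warning("greedy BVSTEP-style search may miss the optimal subset")
    subsets <- .bvstep_subsets(bm_full, env, vars, kmax)
  } else {
    subsets <- unlist(lapply(seq_len(kmax), function(k)
      combn(vars, k, simplify = FALSE)), recursive = FALSE)
  }
  score <- function(sub) {
    zm <- normalize_env(env, sub)
    keep <- rownames(zm)
    ed <- as.matrix(dist(zm))
    .matrix_rank_cor(bm_full[keep, keep], ed)
  }
  rho <- vapply(subsets, score, numeric(1))
  res <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = lengths(subsets), rho = rho, stringsAsFactors = FALSE)
  ord <- order(-res$rho, res$size, res$subset)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  best <- subsets[[ord[1]]]
  structure(list(results = res, best = best, best_rho = res$rho[1],
                 n_subsets = length(subsets),
                 excluded = attr(normalize_env(env, best), "excluded"),
                 variables = vars, max_subset_size = kmax,
                 biotic = stats::as.dist(bm_full), env = env),
            class = "bioenv_fit")
}

.as_dissimilarity <- function(x) {
  if (inherits(x, "dist")) return(x)
  m <- as.matrix(x)
  if (max(m) > 1) m <- 1 - m / 100       # percent-similarity input
  stats::as.dist(m)
}

# greedy forward addition / backward elimination over subset sizes
.bvstep_subsets <- function(bm, env, vars, kmax) {
  subsets <- list()
  current <- character(0)
  repeat {
    cand <- setdiff(vars, current)
    if (!length(cand) || length(current) >= kmax) break
    trial <- lapply(cand, function(v) c(current, v))
    rho <- vapply(trial, function(sub) {
      zm <- normalize_env(env, sub); keep <- rownames(zm)
      .matrix_rank_cor(bm[keep, keep], as.matrix(dist(zm)))
    }, numeric(1))
    subsets <- c(subsets, trial)
    current <- trial[[which.max(rho)]]
    if (length(current) > 1) {           # backward pass
      drop_trial <- lapply(seq_along(current), function(i) current[-i])
      rho_d <- vapply(drop_trial, function(sub) {
        zm <- normalize_env(env, sub); keep <- rownames(zm)
        .matrix_rank_cor(bm[keep, keep], as.matrix(dist(zm)))
      }, numeric(1))
      subsets <- c(subsets, drop_trial)
      if (max(rho_d) > max(rho)) current <- drop_trial[[which.max(rho_d)]]
    }
  }
  unique(subsets)
}

#' @export
print.bioenv_fit <- function(x, n = 10, ...) {
  cat(sprintf("BIOENV/BEST over %d variable subset(s)\n", x$n_subsets))
  cat(sprintf("best: %s (rho_s = %.3f)\n",
              paste(x$best, collapse = " + "), x$best_rho))
  if (!is.null(x$p_value))
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  if (length(x$excluded))
    cat("stations excluded for the best subset:",
        paste(x$excluded, collapse = ", "), "\n")
  print(head(x$results, n))
  invisible(x)
}

#' @export
summary.bioenv_fit <- function(object, ...) object$results

#' Permutation p value for the best BIOENV correlation
#'
#' Permutes the station labels of the environmental table \code{n_perm}
#' times, re-runs the full subset search each time, and reports
#' \eqn{p = (1 + \#\{\rho_{perm} \ge \rho_{obs}\}) / (1 + n_{perm})}.
#' Stations incomplete for any candidate variable are dropped first so that
#' every permutation searches matched matrices.
#'
#' @param fit a \code{bioenv_fit} from [bioenv()].
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed (required for reproducibility).
#' @return the \code{bioenv_fit} with \code{p_value}, \code{n_perm},
#'   \code{perm_rho} (null distribution of best \eqn{\rho_s}) added.
#' @export
bioenv_permutation_p <- function(fit, n_perm = 999, seed) {
  stopifnot(inherits(fit, "bioenv_fit"), n_perm >= 99)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  env <- fit$env
  vars <- fit$variables
  ok <- stats::complete.cases(env[, vars, drop = FALSE])
  env <- env[ok, , drop = FALSE]
  ids <- env$station_id
  bm <- as.matrix(fit$biotic)[ids, ids]
  lt <- lower.tri(bm)
  rb <- rank(bm[lt])
  kmax <- fit$max_subset_size
  subsets <- unlist(lapply(seq_len(kmax), function(k)
    combn(vars, k, simplify = FALSE)), recursive = FALSE)
  # precompute each subset's env distance matrix once; a permutation of
  # station labels is then just a symmetric reindexing
  edists <- lapply(subsets, function(sub)
    as.matrix(dist(scale(as.matrix(env[, sub, drop = FALSE])))))
  best_obs <- max(vapply(edists, function(ed)
    .rank_cor_fast(rb, ed[lt]), numeric(1)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(ids)
  perm_best <- vapply(seq_len(n_perm), function(rep) {
    idx <- sample.int(n)
    max(vapply(edists, function(ed)
      .rank_cor_fast(rb, ed[idx, idx][lt]), numeric(1)))
  }, numeric(1))
  fit$p_value <- (1 + sum(perm_best >= best_obs)) / (1 + n_perm)
  fit$n_perm <- n_perm
  fit$perm_rho <- perm_best
  fit$observed_best_rho_matched <- best_obs
  fit
}

# Pearson correlation between a fixed rank vector and rank(y)
.rank_cor_fast <- function(rank_x, y) {
  cor(rank_x, rank(y))
}

#' Leave-one-variable-out sensitivity of the BIOENV result
#'
#' Re-runs the full subset search once per left-out candidate variable and
#' reports the change in the best \eqn{\rho_s} -- the standard check that a
#' pair of mutually correlated variables is not carrying the result alone.
#'
#' @param biotic,env,variables,max_subset_size as in [bioenv()].
#' @return data frame with one row per dropped variable: \code{dropped},
#'   \code{best_subset}, \code{best_rho}, \code{delta_rho} (vs the
#'   full-variable best).
#' @export
sensitivity_drop <- function(biotic, env, variables = NULL,
                             max_subset_size = NULL) {
  vars <- variables %||% setdiff(names(env), "station_id")
  stopifnot(length(vars) >= 2)
  full <- bioenv(biotic, env, vars, max_subset_size)
  rows <- lapply(vars, function(v) {
    fit <- bioenv(biotic, env, setdiff(vars, v), max_subset_size)
    data.frame(dropped = v,
               best_subset = paste(fit$best, collapse = "+"),
               best_rho = fit$best_rho,
               delta_rho = fit$best_rho - full$best_rho,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_best_rho") <- full$best_rho
  attr(out, "full_best_subset") <- paste(full$best, collapse = "+")
  out
}
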