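# independent brute-force oracles and small fixture builders used across tests

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# exhaustive per-window primer scan
bf_find_sites <- function(seq, primer, max_mismatch) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  k <- length(pc); n <- length(sc)
  if (k > n) return(integer(0))
  hits <- integer(0)
  for (pos in 0:(n - k)) {
    mm <- sum(!mapply(function(b, p) b %in% iupac_sets[[p]],
                      sc[pos + seq_len(k)], pc))
    if (mm <= max_mismatch) hits <- c(hits, pos)
  }
  hits
}

# full average-linkage recomputation at every step (no Lance-Williams update)
bf_upgma <- function(dm) {
  labels <- rownames(dm)
  clusters <- as.list(seq_len(nrow(dm)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) if (b > a) {
      d <- mean(dm[clusters[[a]], clusters[[b]]])
      key <- sort(c(min(labels[clusters[[a]]]), min(labels[clusters[[b]]])))
      if (is.null(best) || d < best$d - 1e-15 ||
          (abs(d - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))))
        best <- list(a = a, b = b, d = d, key = key)
    }
    merges[[length(merges) + 1]] <- list(
      height = best$d,
      members = sort(labels[c(clusters[[best$a]], clusters[[best$b]])]))
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  merges
}

# merge membership sets of an hclust object, in merge order
hclust_merge_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    mem <- unlist(lapply(tree$merge[s, ], function(x)
      if (x < 0) tree$labels[-x] else sets[[x]]))
    sets[[s]] <- sort(mem)
  }
  sets
}

# double-loop Bray-Curtis
bf_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  as.dist(d)
}

# pick one concrete base per IUPAC code (first of each degeneracy set)
concretize <- function(s) chartr("RYSWKMBDHVN", "ACCAGACAAAA", s)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# template carrying one forward site and one reverse site, given insert size
make_template <- function(insert = 312, lead = "GG", trail = "AA") {
  p <- arisa_primers()
  paste0(lead, concretize(p$forward), random_dna(insert),
         concretize(reverse_complement(p$reverse)), trail)
}

random_profile <- function(sample_id = "s1", run_id = "r1", n = 6,
                           window = c(320, 420)) {
  peaks <- data.frame(size = runif(n, window[1], window[2]),
                      height = runif(n, 100, 5000))
  peaks <- peaks[order(peaks$size), ]
  tarisa::peak_profiles(data.frame(sample_id = sample_id, run_id = run_id,
                                   size = peaks$size,
                                   height = peaks$height))[[1]]
}

# abundance values + dimnames only, without the pipeline's qc metadata
strip_meta <- function(m) {
  attr(m, "qc") <- NULL
  attr(m, "unassigned") <- NULL
  unclass(m)
}

random_abundance <- function(n_samples, n_bins, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rgamma(n_samples * n_bins, 0.8), n_samples, n_bins,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              as.character(seq_len(n_bins))))
  as_abundance_matrix(m / rowSums(m))
}
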