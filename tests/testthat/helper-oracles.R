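# Independent oracles and small fixture builders used across the suite.

COMP <- c(A = "U", C = "G", G = "C", U = "A")

revcomp_chr <- function(x) {
  paste(rev(COMP[strsplit(x, "")[[1]]]), collapse = "")
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Exhaustive window-scan oracle for seed anchors: per-position base-by-base
# complementarity checks, written independently of the scanner.
seed_scan_oracle <- function(mirna, target) {
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(target, "")[[1]]
  len <- length(t)
  rows <- list()
  for (p in seq_len(max(0, len - 5))) {
    core_ok <- TRUE
    for (o in 0:5) {
      if (t[p + o] != COMP[[m[7 - o]]]) { core_ok <- FALSE; break }
    }
    if (!core_ok) next
    has_m8 <- p > 1 && t[p - 1] == COMP[[m[8]]]
    has_a1 <- (p + 6) <= len && t[p + 6] == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    rows[[length(rows) + 1]] <- data.frame(
      start = if (has_m8) p - 1L else p,
      end = if (has_a1) p + 6L else p + 5L,
      seed_class = cls, core_start = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      seed_class = character(0), core_start = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Conditional-binomial enumeration oracle for the exact test at alpha = 0.
cond_binom_oracle <- function(a, b, n_a = 1, n_b = 1) {
  total <- a + b
  x <- 0:total
  pr <- n_a / (n_a + n_b)
  probs <- choose(total, x) * pr^x * (1 - pr)^(total - x)
  obs <- probs[a + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Combinatorial enumeration of the upper-tail hypergeometric probability.
hyper_tail_oracle <- function(N, K, n, k) {
  x <- k:min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Minimal DE table for network tests.
de_stub <- function(features, directions) {
  data.frame(feature = features, log2fc = ifelse(directions == "up", 2,
                                                 ifelse(directions == "down", -2, 0)),
             p_raw = ifelse(directions == "ns", 0.5, 0.001),
             p_adj = ifelse(directions == "ns", 0.5, 0.01),
             direction = directions, stringsAsFactors = FALSE)
}

# Minimal binding-site row.
site_stub <- function(mirna, target, target_class, start = 10L) {
  data.frame(mirna = mirna, target = target, target_class = target_class,
             start = start, end = start + 7L, seed_class = "8mer",
             score = 150, energy = -20, stringsAsFactors = FALSE)
}
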