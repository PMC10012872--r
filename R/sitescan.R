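# miRanda-style miRNA binding-site prediction: seed anchors (8mer, 7mer-m8,
# 7mer-A1, 6mer), wobble-tolerant local hybrid alignment with 5' dominance,
# and a nearest-neighbor RNA:RNA duplex free energy.

# Nearest-neighbor stack free energies (kcal/mol, 37 C) in the style of the
# Turner rules: rows = 5' pair, cols = 3' pair along the miRNA (top) strand;
# pair labels are top-bottom. Watson-Crick values follow the published
# parameters; G:U-containing stacks are representative approximations.
NN_PAIRS <- c("AU", "CG", "GC", "GU", "UA", "UG")
NN_STACK <- matrix(c(
  # AU     CG     GC     GU     UA     UG
  -0.93, -2.24, -2.08, -0.55, -1.10, -1.36,  # AU
  -2.11, -3.26, -2.36, -1.41, -2.08, -2.11,  # CG
  -2.35, -3.42, -3.26, -1.53, -2.24, -2.51,  # GC
  -1.27, -2.51, -2.11, -0.50, -1.36,  1.29,  # GU
  -1.33, -2.35, -2.11, -1.00, -0.93, -1.27,  # UA
  -1.00, -2.11, -2.24,  0.30, -0.55, -0.50), # UG
  nrow = 6, byrow = TRUE, dimnames = list(NN_PAIRS, NN_PAIRS))

DUPLEX_INIT <- 4.09   # duplex initiation, kcal/mol
LOOP_OPEN <- 3.0      # internal loop / bulge opening penalty
LOOP_PER_NT <- 0.3    # per unpaired nucleotide within a loop

pair_label <- function(m, t) {
  p <- paste0(m, t)
  if (p %in% NN_PAIRS) p else NA_character_
}

#' Find seed anchors of a miRNA on a target
#'
#' Scans every target window for Watson-Crick complementarity to the miRNA
#' seed (no G:U inside the seed): positions 2-8 (7mer-m8), positions 2-7
#' with a target A opposite position 1 (7mer-A1), both (8mer), or positions
#' 2-7 alone (6mer). Coordinates are 1-based inclusive on the target's
#' 5'->3' strand; the best class is reported per anchor.
#'
#' @param mirna miRNA sequence 5'->3' (length >= 19).
#' @param target target sequence 5'->3'. T is converted to U with a warning.
#' @return data.frame(start, end, seed_class, core_start); `core_start` is
#'   the target position pairing miRNA position 7.
#' @export
find_seed_sites <- function(mirna, target) {
  mirna <- norm_rna(mirna, "miRNA")
  target <- norm_rna(target, "target")
  if (nchar(mirna) < 19) stop("miRNA length must be >= 19")
  len <- nchar(target)
  core <- rna_revcomp(substr(mirna, 2, 7))      # complements of m7..m2
  m8c <- rna_complement(substr(mirna, 8, 8))    # complement of m8

  # matchPattern reports overlapping matches (runs of complementarity)
  hits <- Biostrings::start(
    Biostrings::matchPattern(core, Biostrings::BString(target)))
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      seed_class = character(0), core_start = integer(0),
                      stringsAsFactors = FALSE))
  out <- lapply(as.integer(hits), function(p) {
    has_m8 <- p > 1 && substr(target, p - 1, p - 1) == m8c
    has_a1 <- p + 6 <= len && substr(target, p + 6, p + 6) == "A"
    if (has_m8 && has_a1) {
      data.frame(start = p - 1L, end = p + 6L, seed_class = "8mer",
                 core_start = p, stringsAsFactors = FALSE)
    } else if (has_m8) {
      data.frame(start = p - 1L, end = p + 5L, seed_class = "7mer-m8",
                 core_start = p, stringsAsFactors = FALSE)
    } else if (has_a1) {
      data.frame(start = p, end = p + 6L, seed_class = "7mer-A1",
                 core_start = p, stringsAsFactors = FALSE)
    } else {
      data.frame(start = p, end = p + 5L, seed_class = "6mer",
                 core_start = p, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Local hybrid alignment of a miRNA against a target window
#'
#' Smith-Waterman local alignment (affine gaps) of the full miRNA
#' (5'->3') against the reversed target window (+/- `flank` nt around the
#' anchor), so pairing is antiparallel. Scoring: Watson-Crick match +5,
#' G:U wobble +2, mismatch -3, gap open -9, gap extend -4; substitution
#' scores for miRNA positions 2-8 are doubled (5' dominance).
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param target target sequence 5'->3'.
#' @param anchor one row of [find_seed_sites()] output (needs start, end).
#' @param flank window half-width beyond the anchor (nt).
#' @return list(score, mirna_aln, target_aln, target_start, target_end);
#'   `target_aln` runs 3'->5' (antiparallel to `mirna_aln`), and
#'   target_start/target_end bound the aligned region on the 5'->3' strand.
#' @export
extend_alignment <- function(mirna, target, anchor, flank = 30L) {
  mirna <- norm_rna(mirna, "miRNA")
  target <- norm_rna(target, "target")
  w_start <- max(1L, anchor$start - flank)
  w_end <- min(nchar(target), anchor$end + flank)
  win_rev <- rev_string(substr(target, w_start, w_end))  # target 3'->5'
  m <- strsplit(mirna, "")[[1]]
  t <- strsplit(win_rev, "")[[1]]
  n <- length(m); k <- length(t)

  subs <- matrix(0, n, k)
  for (i in seq_len(n)) {
    mult <- if (i >= 2 && i <= 8) 2 else 1
    for (j in seq_len(k)) {
      pl <- paste0(m[i], t[j])
      s <- if (pl %in% c("AU", "UA", "CG", "GC")) 5
           else if (pl %in% c("GU", "UG")) 2 else -3
      subs[i, j] <- mult * s
    }
  }

  GO <- -9; GE <- -4
  NEG <- -1e9
  M <- matrix(0, n + 1, k + 1)
  X <- matrix(NEG, n + 1, k + 1)  # gap consuming miRNA (target gap)
  Y <- matrix(NEG, n + 1, k + 1)  # gap consuming target (miRNA gap)
  ptr <- array(0L, c(n + 1, k + 1, 3))
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      diag <- max(M[i, j], X[i, j], Y[i, j]) + subs[i, j]
      if (diag < 0) diag <- 0
      M[i + 1, j + 1] <- diag
      ptr[i + 1, j + 1, 1] <- which.max(c(M[i, j], X[i, j], Y[i, j]))
      xo <- M[i, j + 1] + GO; xe <- X[i, j + 1] + GE
      X[i + 1, j + 1] <- max(xo, xe)
      ptr[i + 1, j + 1, 2] <- if (xo >= xe) 1L else 2L
      yo <- M[i + 1, j] + GO; ye <- Y[i + 1, j] + GE
      Y[i + 1, j + 1] <- max(yo, ye)
      ptr[i + 1, j + 1, 3] <- if (yo >= ye) 1L else 3L
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i + 1L; bj <- j + 1L
      }
    }
  }

  if (best <= 0) {
    return(list(score = 0, mirna_aln = "", target_aln = "",
                target_start = NA_integer_, target_end = NA_integer_))
  }
  # traceback from the best M cell
  aln_m <- character(0); aln_t <- character(0)
  i <- bi; j <- bj; state <- 1L
  while (i > 1 || j > 1) {
    if (state == 1L) {
      if (M[i, j] <= 0) break
      prev <- ptr[i, j, 1]
      aln_m <- c(m[i - 1], aln_m); aln_t <- c(t[j - 1], aln_t)
      i <- i - 1L; j <- j - 1L
      state <- prev
    } else if (state == 2L) {
      prev <- ptr[i, j, 2]
      aln_m <- c(m[i - 1], aln_m); aln_t <- c("-", aln_t)
      i <- i - 1L
      state <- prev
    } else {
      prev <- ptr[i, j, 3]
      aln_m <- c("-", aln_m); aln_t <- c(t[j - 1], aln_t)
      j <- j - 1L
      state <- prev
    }
  }
  # reversed-window index jj (1-based) maps to target coordinate w_end-jj+1;
  # consumed columns span [j, bj-1] after traceback
  list(score = best,
       mirna_aln = paste(aln_m, collapse = ""),
       target_aln = paste(aln_t, collapse = ""),
       target_start = w_end - bj + 2L,
       target_end = w_end - j + 1L)
}

#' Nearest-neighbor duplex free energy of an aligned hybrid
#'
#' dG = initiation + sum of stack terms over consecutive base pairs + a
#' length-linear penalty (opening + per-nucleotide) for each internal
#' loop/bulge between helices. Watson-Crick and G:U pairs both stack;
#' terminal unpaired overhangs are ignored. Returns NA (site rejected)
#' when the duplex contains no helix of >= 2 consecutive pairs.
#'
#' @param mirna_aln aligned miRNA string 5'->3' (gaps as "-").
#' @param target_aln aligned target string 3'->5' (antiparallel).
#' @return free energy in kcal/mol (more negative = more stable), or NA.
#' @export
duplex_energy <- function(mirna_aln, target_aln) {
  m <- strsplit(mirna_aln, "")[[1]]
  t <- strsplit(target_aln, "")[[1]]
  if (length(m) != length(t)) stop("aligned strings must have equal length")
  pairs <- vapply(seq_along(m), function(i) {
    if (m[i] == "-" || t[i] == "-") NA_character_ else pair_label(m[i], t[i])
  }, character(1))
  paired <- !is.na(pairs)
  if (!any(paired)) return(NA_real_)
  first <- min(which(paired)); last <- max(which(paired))

  # helix runs of consecutive paired columns
  r <- rle(paired[first:last])
  if (!any(r$values & r$lengths >= 2)) return(NA_real_)

  e <- DUPLEX_INIT
  for (i in seq(first, last - 1)) {
    if (paired[i] && paired[i + 1]) {
      e <- e + NN_STACK[pairs[i], pairs[i + 1]]
    }
  }
  # internal loops/bulges: maximal unpaired stretches strictly inside
  in_loop <- FALSE; loop_nt <- 0
  for (i in seq(first, last)) {
    if (!paired[i]) {
      in_loop <- TRUE
      loop_nt <- loop_nt + (m[i] != "-") + (t[i] != "-")
    } else if (in_loop) {
      e <- e + LOOP_OPEN + LOOP_PER_NT * loop_nt
      in_loop <- FALSE; loop_nt <- 0
    }
  }
  e
}

#' Predict miRNA binding sites on a set of targets
#'
#' For every (miRNA, target) pair: seed anchors, local hybrid alignment,
#' duplex free energy; sites must reach `min_score` and be at most
#' `max_energy`. Overlapping sites for a pair are resolved by keeping the
#' best-scoring site and greedily adding non-overlapping ones (ties: lower
#' start wins). circRNA targets are scanned with the first L-1 nt appended
#' (L = miRNA length) so back-splice-spanning sites are findable;
#' coordinates are reported modulo the sequence length.
#'
#' @param mirnas named character vector of miRNA sequences 5'->3'.
#' @param targets named character vector of target sequences 5'->3'.
#' @param target_class one of "mRNA_3UTR", "circRNA", "lncRNA".
#' @param min_score minimum alignment score (default 140).
#' @param max_energy maximum (least negative) duplex dG, kcal/mol.
#' @param circular scan with wrap-around; defaults to TRUE for circRNA.
#' @return data.frame(mirna, target, target_class, start, end, seed_class,
#'   score, energy), ordered by (target, start, mirna). start/end are the
#'   seed-match span.
#' @export
predict_targets <- function(mirnas, targets,
                            target_class = c("mRNA_3UTR", "circRNA", "lncRNA"),
                            min_score = 140, max_energy = -10,
                            circular = NULL) {
  target_class <- match.arg(target_class)
  if (is.null(circular)) circular <- target_class == "circRNA"
  empty <- data.frame(mirna = character(0), target = character(0),
                      target_class = character(0), start = integer(0),
                      end = integer(0), seed_class = character(0),
                      score = numeric(0), energy = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(mirnas) == 0 || length(targets) == 0) {
    warning("empty input set; returning empty site table")
    return(empty)
  }
  rows <- list()
  for (tid in names(targets)) {
    tseq <- norm_rna(targets[[tid]], tid)
    tlen <- nchar(tseq)
    for (mid in names(mirnas)) {
      mseq <- norm_rna(mirnas[[mid]], mid)
      L <- nchar(mseq)
      scan_seq <- if (circular && tlen > L) {
        paste0(tseq, substr(tseq, 1, L - 1))
      } else tseq
      anchors <- find_seed_sites(mseq, scan_seq)
      if (nrow(anchors) == 0) next
      cand <- lapply(seq_len(nrow(anchors)), function(r) {
        a <- anchors[r, ]
        aln <- extend_alignment(mseq, scan_seq, a)
        en <- if (nzchar(aln$mirna_aln)) {
          duplex_energy(aln$mirna_aln, aln$target_aln)
        } else NA_real_
        st <- ((a$start - 1L) %% tlen) + 1L
        data.frame(mirna = mid, target = tid, target_class = target_class,
                   start = st, end = st + (a$end - a$start),
                   seed_class = a$seed_class, score = aln$score,
                   energy = en, stringsAsFactors = FALSE)
      })
      cand <- do.call(rbind, cand)
      cand <- cand[!is.na(cand$energy) & cand$score >= min_score &
                     cand$energy <= max_energy, , drop = FALSE]
      if (nrow(cand) == 0) next
      if (circular) {
        # wrapped duplicates map to the same seed position; keep the copy
        # with the better extension context (higher score)
        cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
        cand <- cand[!duplicated(cand$start), , drop = FALSE]
      }
      # greedy overlap resolution: best score first, then lower start
      cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
      kept <- integer(0)
      for (r in seq_len(nrow(cand))) {
        ov <- FALSE
        for (kk in kept) {
          if (cand$start[r] <= cand$end[kk] && cand$end[r] >= cand$start[kk]) {
            ov <- TRUE; break
          }
        }
        if (!ov) kept <- c(kept, r)
      }
      rows[[length(rows) + 1]] <- cand[kept, , drop = FALSE]
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$target, out$start, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
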