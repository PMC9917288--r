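# Independent oracles used to validate the package's alignment and Ka/Ks
# implementations on small inputs.

# exhaustive (no DP, no memoisation) enumeration of all global alignments of
# two short sequences under affine gaps costing open + extend * length
oracle_align_score <- function(a, b, open = 10, extend = 0.5, mat) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  rec <- function(i, j, state) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= length(A))
      best <- max(best, -(extend + if (state == 1L) 0 else open) +
                    rec(i + 1L, j, 1L))
    if (j <= length(B))
      best <- max(best, -(extend + if (state == 2L) 0 else open) +
                    rec(i, j + 1L, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

GC <- Biostrings::GENETIC_CODE

# brute-force Nei-Gojobori quantities for one codon pair: site fractions by
# direct enumeration of all nine single-base changes, difference counts by
# explicit enumeration of every pathway permutation
oracle_ng_sites <- function(codon) {
  aa <- GC[[codon]]
  S <- 0
  for (pos in 1:3) {
    n_syn <- 0; n_ok <- 0
    for (base in c("A", "C", "G", "T")) {
      if (base == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- base
      if (GC[[alt]] == "*") next
      n_ok <- n_ok + 1
      if (GC[[alt]] == aa) n_syn <- n_syn + 1
    }
    if (n_ok > 0) S <- S + n_syn / n_ok
  }
  S
}

oracle_ng_pair_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
  if (!length(pos)) return(c(0, 0))
  count_path <- function(ord) {
    cur <- ca; sy <- 0; ns <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (GC[[nxt]] == "*") return(NULL)
      if (GC[[nxt]] == GC[[cur]]) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    c(sy, ns)
  }
  res <- Filter(Negate(is.null), lapply(all_perms(pos), count_path))
  if (!length(res)) {
    count_all <- function(ord) {
      cur <- ca; sy <- 0; ns <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (GC[[nxt]] == GC[[cur]]) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      c(sy, ns)
    }
    res <- lapply(all_perms(pos), count_all)
  }
  Reduce(`+`, res) / length(res)
}

oracle_kaks_counts <- function(cds_a, cds_b) {
  idx <- seq_len(nchar(cds_a) %/% 3L)
  ca <- substring(cds_a, 3 * idx - 2, 3 * idx)
  cb <- substring(cds_b, 3 * idx - 2, 3 * idx)
  S <- (sum(vapply(ca, oracle_ng_sites, 0)) +
          sum(vapply(cb, oracle_ng_sites, 0))) / 2
  d <- Reduce(`+`, Map(oracle_ng_pair_diffs, ca, cb))
  list(S = S, N = 3 * length(ca) - S, Sd = d[1L], Nd = d[2L])
}

# random in-frame CDS without stop codons
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- names(GC)[GC != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
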