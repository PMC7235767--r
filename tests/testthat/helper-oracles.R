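# Independent brute-force oracles, deliberately naive.

# O(m^2) step-up BH: for each p_i, padj_i = min over {p_j >= p_i} of
# min(1, p_j * m / rank(p_j)).
oracle_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- vapply(which(p >= p[i]), function(j) p[j] * m / rk[j],
                   numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

oracle_bray_curtis <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_top_taxa <- function(props, n) {
  sums <- apply(props, 2, sum)
  df <- data.frame(id = colnames(props), s = sums)
  df <- df[order(-df$s, df$id), ]
  head(df$id, n)
}

oracle_counts <- function(S) {
  pos <- 0L; neg <- 0L; neu <- 0L
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    v <- S[i, j]
    if (v > 0) pos <- pos + 1L else if (v < 0) neg <- neg + 1L
    else neu <- neu + 1L
  }
  c(pos = pos, neg = neg, neu = neu)
}

oracle_shared <- function(a, b) {
  k <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] == b[i, j]) k <- k + 1L
  }
  k
}

oracle_unique <- function(target, others) {
  k <- 0L
  for (i in seq_len(nrow(target))) for (j in seq_len(ncol(target))) {
    if (all(vapply(others, function(o) target[i, j] != o[i, j],
                   logical(1)))) k <- k + 1L
  }
  k
}

# exhaustive Venn region/direction enumeration from raw membership
oracle_venn <- function(inc, dec, conds) {
  taxa <- sort(unique(c(unlist(inc), unlist(dec))))
  out <- data.frame(taxon = character(), region = character(),
                    direction = character())
  for (tx in taxa) {
    in_i <- vapply(conds, function(cn) tx %in% inc[[cn]], logical(1))
    in_d <- vapply(conds, function(cn) tx %in% dec[[cn]], logical(1))
    member <- in_i | in_d
    dir <- if (any(in_i) && any(in_d)) "conflict"
    else if (any(in_i)) "increase" else "decrease"
    out <- rbind(out, data.frame(
      taxon = tx, region = paste(conds[member], collapse = "&"),
      direction = dir))
  }
  out
}

random_sign_matrix <- function(n, seed) {
  set.seed(seed)
  structure(matrix(sample(c(-1L, 0L, 1L), n * n, replace = TRUE), n, n),
            class = c("sign_matrix", "matrix"), epsilon = 0, threshold = 0)
}
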