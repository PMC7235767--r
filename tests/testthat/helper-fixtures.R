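# Shared fixture builders (all generated in code; no data files).

# Weakly damped cycling community: off-diagonal pairs with opposite
# signs and magnitudes bounded away from zero, gentle self-limitation,
# growth rates anchored to an interior equilibrium.  `rate` scales the
# whole dynamics (cycles per unit time).  This is the model family on
# which single-trajectory gradient matching is identifiable; see the
# methods vignette.
cycling_model <- function(n, seed, rate = 1) {
  set.seed(seed)
  repeat {
    xs <- runif(n, 0.5, 1.5)
    A <- matrix(0, n, n)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          g <- runif(1, 0.25, 0.6) * sample(c(-1, 1), 1)
          A[i, j] <- g
          A[j, i] <- -g * runif(1, 0.7, 1.3)
        }
      }
    }
    diag(A) <- -runif(n, 0.15, 0.4)
    A <- A * rate
    r <- -drop(A %*% xs)
    m <- glv_model(r, A)
    ok <- tryCatch({
      tr <- glv_simulate(m, xs * runif(n, 0.4, 2),
                         seq(0, 20 / rate, length.out = 50))
      min(tr$X) > 1e-4 && max(tr$X) < 50
    }, error = function(e) FALSE)
    if (ok) return(m)
  }
}

# displaced-from-equilibrium start for round-trip experiments
displaced_x0 <- function(model, seed, lo = 0.7, hi = 1.4) {
  eq <- glv_equilibrium(model)
  set.seed(seed)
  (if (is.null(eq)) rep(1, model$n) else pmax(eq, 0.05)) *
    runif(model$n, lo, hi)
}

# multiplicative lognormal observation noise with unit mean
add_obs_noise <- function(X, cv, seed) {
  set.seed(seed)
  s <- sqrt(log(1 + cv^2))
  X * matrix(rlnorm(length(X), -s^2 / 2, s), nrow(X))
}

# small abundance table with a 3-level known taxonomy
toy_table <- function() {
  counts <- matrix(c(10, 20, 30, 40,
                     5, 0, 15, 80,
                     1, 2, 3, 4), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("otu1", "otu2", "otu3", "otu4")))
  taxonomy <- data.frame(
    domain = rep("Bacteria", 4),
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes", NA),
    genus = c("Trichococcus", "Sedimentibacter", NA, NA))
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        condition = c("control", "control", "GABA"),
                        day = c(0, 56, 56), replicate = c(1, 1, 1))
  abundance_table(counts, samples = samples, taxonomy = taxonomy)
}

# FASTQ writer for constructed reads (PHRED+33)
write_fastq_lines <- function(path, ids, seqs, quals) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(c(paste0("@", ids[i]), seqs[i], "+",
                 rawToChar(as.raw(quals[[i]] + 33L))), con)
  }
  path
}

make_read <- function(len, q) {
  list(seq = paste(rep("A", len), collapse = ""), qual = rep(q, len))
}
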