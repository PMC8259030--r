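# Small fixtures built in code.

tinyFeatureTable <- function(counts = NULL, nGroups = 2) {
  if (is.null(counts)) {
    set.seed(42)
    counts <- matrix(rpois(8 * 10, 40), nrow = 8,
                     dimnames = list(paste0("ASV", 1:8), paste0("S", 1:10)))
  }
  md <- data.frame(
    row.names = colnames(counts),
    group = rep_len(c("untreated", "model", "control", "test")[seq_len(nGroups)],
                    ncol(counts)),
    day = rep_len(c(1, 3), ncol(counts)),
    mouse = paste0("m", seq_len(ncol(counts))),
    cage = "c1")
  tx <- data.frame(
    row.names = rownames(counts),
    lineage = paste0("d__Bacteria;g__G", seq_len(nrow(counts))),
    class = rep_len(c("Bacteroidia", "Bacilli"), nrow(counts)),
    genus = rep_len(c("Bacteroides", "Lactobacillus"), nrow(counts)),
    confidence = 0.9)
  FeatureTable(counts, md, tx)
}

# Independent term-by-term evaluation of the sqrt-JSD definition
# (KLD with natural log), used as the brute-force oracle.
refSqrtJsd <- function(p, q) {
  m <- (p + q) / 2
  kld <- function(x, y) {
    s <- 0
    for (i in seq_along(x)) if (x[i] > 0) s <- s + x[i] * log(x[i] / y[i])
    s
  }
  sqrt(0.5 * kld(p, m) + 0.5 * kld(q, m))
}

randomProfile <- function(k) {
  x <- rgamma(k, 1)
  x / sum(x)
}

# Penalized log-likelihood maximized by the glasso
glassoObj <- function(Theta, S, lambda)
  determinant(Theta, logarithm = TRUE)$modulus[1] - sum(S * Theta) -
    2 * lambda * sum(abs(Theta[upper.tri(Theta)]))

# Independent brute-force maximizer: naive per-entry 1-D golden-section
# search on the raw precision entries (coordinate-wise minimization of a
# convex objective with a separable penalty converges to the optimum).
bruteForceGlasso <- function(S, lambda, iters = 80) {
  p <- nrow(S)
  Th <- diag(p)
  negobj <- function(Th) -glassoObj(Th, S, lambda)
  for (it in seq_len(iters)) {
    for (i in seq_len(p)) for (j in i:p) {
      f <- function(v) {
        T2 <- Th
        T2[i, j] <- T2[j, i] <- v
        if (min(eigen(T2, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
          return(1e10)
        negobj(T2)
      }
      o <- stats::optimize(f, c(Th[i, j] - 2, Th[i, j] + 2), tol = 1e-12)
      if (o$objective < negobj(Th)) Th[i, j] <- Th[j, i] <- o$minimum
      if (i != j && f(0) <= negobj(Th)) Th[i, j] <- Th[j, i] <- 0
    }
  }
  list(Theta = Th, objective = glassoObj(Th, S, lambda))
}
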