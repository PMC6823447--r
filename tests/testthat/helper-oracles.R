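# Independent reference implementations used to cross-check the package's
# vectorized/compiled paths. These stay deliberately naive.

# wPLI by explicit triple loop over samples, pairs and trials.
wpli_naive <- function(z) {
  d <- dim(z)
  K <- d[1]; R <- d[2]; Tn <- d[3]
  out <- array(0, c(Tn, R, R))
  for (t in seq_len(Tn)) {
    for (i in seq_len(R - 1)) {
      for (j in (i + 1):R) {
        im <- numeric(K)
        for (k in seq_len(K))
          im[k] <- Im(z[k, i, t] * Conj(z[k, j, t]))
        den <- sum(abs(im))
        w <- if (den > 0) abs(sum(im)) / den else 0
        out[t, i, j] <- w
        out[t, j, i] <- w
      }
    }
  }
  out
}

# Connected components by union-find on an explicit edge list.
uf_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp_of_edge <- if (nrow(edges)) roots[edges[, 1]] else integer(0)
  comps <- lapply(unique(comp_of_edge), function(r) {
    e <- edges[comp_of_edge == r, , drop = FALSE]
    list(edges = e[order(e[, 1], e[, 2]), , drop = FALSE],
         nodes = sort(unique(as.vector(e))))
  })
  # deterministic order: by smallest node
  comps[order(vapply(comps, function(cm) min(cm$nodes), integer(1)))]
}

# Fraction of periodogram power inside a frequency band.
band_power_fraction <- function(x, fs, f_low, f_high) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  in_band <- half & freq >= f_low & freq <= f_high
  sum(p[in_band]) / sum(p[half])
}
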